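test_that("gram-unit detection accepts the gram dialects and nothing else", {
  expect_true(all(is_gram_unit(c("g", "gr", "gram", "grams", " Grams ", "G"))))
  expect_false(any(is_gram_unit(c("oz", "slice", "piece", "package",
                                  "breast", "cup", "", "kg", "mg"))))
})

test_that("dish density averages calories per gram over gram records only", {
  one <- data.frame(calories = 230, serving_qty = 100, serving_unit = "g")
  expect_equal(dish_density(one), 2.30)
  mixed <- data.frame(calories = c(200, 300, 500),
                      serving_qty = c(100, 100, 1),
                      serving_unit = c("g", "grams", "piece"))
  expect_equal(dish_density(mixed), 2.50)  # piece record ignored
  expect_true(is.na(dish_density(data.frame(calories = 100, serving_qty = 1,
                                            serving_unit = "oz"))))
  bad <- data.frame(calories = c(200, 300), serving_qty = c(100, 0),
                    serving_unit = c("g", "g"))
  expect_warning(d <- dish_density(bad), "non-positive")
  expect_equal(d, 2.0)
})

test_that("category density is the unweighted mean over distinct dishes with densities", {
  nutrition <- data.frame(
    dish = c("a", "a", "b", "c"), calories = c(150, 250, 400, 100),
    serving_qty = c(100, 100, 100, 1),
    serving_unit = c("g", "g", "g", "piece"), stringsAsFactors = FALSE)
  # dish a: mean(1.5, 2.5) = 2; dish b: 4; dish c: no gram record
  popular <- data.frame(category = rep("cat1", 4), rank = 1:4,
                        dish = c("a", "b", "b", "c"),  # b listed twice
                        stringsAsFactors = FALSE)
  reg <- build_density_registry(nutrition, popular)
  expect_equal(reg$dishes$density[reg$dishes$dish == "a"], 2)
  expect_equal(reg$categories$density, 3)            # mean of {2, 4}, b once
  expect_equal(reg$categories$n_dishes, 2L)
  expect_equal(reg$categories$n_dishes_missing, 1L)  # dish c excluded

  # single-dish category: density passes through
  pop1 <- data.frame(category = "solo", rank = 1, dish = "b")
  expect_equal(build_density_registry(nutrition, pop1)$categories$density, 4)

  # category with no measurable dish is dropped with a warning
  pop2 <- data.frame(category = c("cat1", "ghost"), rank = c(1, 1),
                     dish = c("a", "c"))
  expect_warning(reg2 <- build_density_registry(nutrition, pop2), "ghost")
  expect_equal(reg2$categories$category, "cat1")
})

test_that("the weighted score is the availability-normalized mean of category densities", {
  av <- make_availability(
    data.frame(region = c("CO", "CO"), category = c("c1", "c2"),
               count = c(2L, 1L), stringsAsFactors = FALSE),
    c(CO = 4L))  # availabilities 0.5 and 0.25
  reg <- make_registry(c("c1", "c2"), c(2, 6))
  sc <- state_weighted_score(av, reg)
  expect_equal(sc$weighted_score, (0.5 * 2 + 0.25 * 6) / 0.75)

  # constant density: score equals it whatever the availability profile
  regc <- make_registry(c("c1", "c2"), c(3.3, 3.3))
  expect_equal(state_weighted_score(av, regc)$weighted_score, 3.3)

  # scaling all availabilities leaves the normalized score unchanged
  av2 <- make_availability(
    data.frame(region = c("CO", "CO"), category = c("c1", "c2"),
               count = c(4L, 2L), stringsAsFactors = FALSE),
    c(CO = 4L))  # both availabilities doubled
  expect_equal(state_weighted_score(av2, reg)$weighted_score,
               sc$weighted_score)

  # categories without a density drop out of numerator and denominator
  av3 <- make_availability(
    data.frame(region = c("CO", "CO", "CO"),
               category = c("c1", "c2", "mystery"),
               count = c(2L, 1L, 3L), stringsAsFactors = FALSE),
    c(CO = 4L))
  expect_equal(state_weighted_score(av3, reg)$weighted_score,
               sc$weighted_score)

  # no usable category at all is an error naming the region
  avz <- make_availability(
    data.frame(region = "WY", category = "mystery", count = 1L,
               stringsAsFactors = FALSE), c(WY = 2L))
  expect_error(state_weighted_score(avz, reg), "WY")
})

test_that("region scores stay within the range of contributing category densities", {
  w <- generate_world(small_config(seed = 21L))
  reg <- build_density_registry(w$nutrition, w$popular_dishes)
  sc <- state_weighted_score(compute_availability(w$businesses), reg)
  expect_true(all(sc$weighted_score >= min(reg$categories$density) &
                    sc$weighted_score <= max(reg$categories$density)))
})

test_that("noiseless worlds are recovered exactly: categories and region scores equal planted truth", {
  cfg <- small_config(calorie_noise_cv = 0, nongram_fraction = 0, seed = 13L)
  w <- generate_world(cfg)
  reg <- build_density_registry(w$nutrition, w$popular_dishes)
  planted <- cfg$categories$true_density[
    match(reg$categories$category, cfg$categories$label)]
  expect_equal(reg$categories$density, planted, tolerance = 1e-12)
  sc <- state_weighted_score(compute_availability(w$businesses), reg)
  expect_equal(sc$weighted_score,
               w$truth$E[match(sc$region, w$truth$region)],
               tolerance = 1e-12)
})

test_that("score-obesity correlation is Pearson on aligned regions with sane errors", {
  sc <- structure(data.frame(region = c("A", "B", "C", "D"),
                             weighted_score = c(1, 2, 3, 4)),
                  class = c("state_scores", "data.frame"))
  ob <- data.frame(region = c("A", "B", "C", "D"),
                   obesity_rate = c(10, 20, 30, 40))
  expect_equal(score_obesity_correlation(sc, ob)$r, 1)
  # hand-computed closed form on a non-trivial 4-point set
  ob2 <- data.frame(region = c("A", "B", "C", "D"),
                    obesity_rate = c(2, 4, 6, -6))
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, -6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(score_obesity_correlation(sc, ob2)$r, r_hand)
  # affine invariance
  ob3 <- transform(ob2, obesity_rate = 0.5 * obesity_rate + 7)
  expect_equal(score_obesity_correlation(sc, ob3)$r, r_hand)
  # degenerate inputs are errors, not NaN
  obc <- data.frame(region = c("A", "B", "C"), obesity_rate = c(1, 1, 1))
  expect_error(score_obesity_correlation(sc, obc), "zero variance")
  expect_error(score_obesity_correlation(sc, ob[1:2, ]), ">= 3")
})

test_that("the between-region density z-test works on business-level samples", {
  reg <- make_registry(c("lo", "hi"), c(2, 3))
  b <- rbind(make_businesses("CO", rep(list("lo"), 4)),
             make_businesses("MS", rep(list("hi"), 4)))
  zt <- compare_regions_ztest(b, "CO", "CO", reg)
  expect_equal(zt$z, 0)  # identical samples
  zt2 <- compare_regions_ztest(b, "MS", "CO", reg)
  expect_true(zt2$z > 0 && !is.finite(zt2$z) || zt2$z > 10)  # full separation
  expect_equal(sign(compare_regions_ztest(b, "CO", "MS", reg)$z), -1)

  # oracle recomputation on a 10+10 fixture with mixed categories
  set.seed(4)
  cats_a <- replicate(10, sample(c("lo", "hi"), sample(1:2, 1)),
                      simplify = FALSE)
  cats_b <- replicate(10, sample(c("lo", "hi"), sample(1:2, 1)),
                      simplify = FALSE)
  bb <- rbind(make_businesses("CO", cats_a), make_businesses("MS", cats_b))
  dens <- c(lo = 2, hi = 3)
  sa <- vapply(cats_a, function(cc) mean(dens[cc]), 0)
  sb <- vapply(cats_b, function(cc) mean(dens[cc]), 0)
  z_hand <- (mean(sa) - mean(sb)) /
    sqrt(var(sa) / length(sa) + var(sb) / length(sb))
  zt3 <- compare_regions_ztest(bb, "CO", "MS", reg)
  expect_equal(zt3$z, z_hand)
  expect_equal(zt3$p.value, 2 * pnorm(-abs(z_hand)))
})
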
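test_that("pearson matches the closed form and rejects degenerate input", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 5, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), r_hand)
  expect_error(pearson(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson(1:2, 1:2))
})

lin_fixture <- function(n = 10, p = 3, seed = 8) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("R%02d", 1:n), paste0("f", 1:p)))
  y <- drop(2 + x %*% c(1, -2, 0.5) + rnorm(n, 0, 0.3))
  names(y) <- rownames(x)
  list(fm = make_feature_matrix(x), y = y,
       ob = data.frame(region = rownames(x), obesity_rate = y))
}

test_that("linear LOOCV equals the closed-form leave-one-out identity", {
  f <- lin_fixture()
  fit <- loocv_predict(f$fm, f$ob, model_spec("linear"))
  expect_equal(fit$predictions$predicted,
               unname(loo_closed_form(f$fm$x, f$y)), tolerance = 1e-8)
  expect_equal(fit$predictions$actual, unname(f$y))
  expect_equal(fit$pearson_r,
               pearson(f$y, loo_closed_form(f$fm$x, f$y)))
})

test_that("an exactly realizable linear outcome is predicted with r near 1", {
  set.seed(1)
  x <- matrix(rnorm(12), 12, 1, dimnames = list(sprintf("R%02d", 1:12), "f"))
  ob <- data.frame(region = rownames(x), obesity_rate = 3 + 2 * x[, 1])
  fit <- loocv_predict(make_feature_matrix(x), ob, model_spec("linear"))
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  expect_equal(fit$predictions$predicted, ob$obesity_rate, tolerance = 1e-9)
})

test_that("per-region predictions are invariant to region row order for all families", {
  f <- lin_fixture(n = 12)
  for (family in c("linear", "random_forest", "svm",
                   "gradient_boosted_trees")) {
    spec <- model_spec(family, seed = 3L)
    fit1 <- loocv_predict(f$fm, f$ob, spec)
    perm <- sample(nrow(f$fm$x))
    fm2 <- make_feature_matrix(f$fm$x[perm, , drop = FALSE])
    fit2 <- loocv_predict(fm2, f$ob, spec)
    m <- match(fit1$predictions$region, fit2$predictions$region)
    expect_equal(fit2$predictions$predicted[m], fit1$predictions$predicted,
                 tolerance = 1e-10, label = family)
  }
})

test_that("no leakage: corrupting a held-out outcome never changes its own prediction", {
  f <- lin_fixture(n = 10)
  for (family in c("linear", "random_forest")) {
    spec <- model_spec(family, seed = 2L)
    fit1 <- loocv_predict(f$fm, f$ob, spec)
    ob2 <- f$ob
    ob2$obesity_rate[4] <- ob2$obesity_rate[4] + 50  # corrupt region 4
    fit2 <- loocv_predict(f$fm, ob2, spec)
    expect_equal(fit2$predictions$predicted[4], fit1$predictions$predicted[4],
                 tolerance = 1e-10, label = family)
  }
})

test_that("LOOCV is reproducible under a fixed spec for stochastic families", {
  f <- lin_fixture(n = 10)
  for (family in c("random_forest", "gradient_boosted_trees")) {
    spec <- model_spec(family, seed = 7L)
    expect_identical(loocv_predict(f$fm, f$ob, spec)$predictions,
                     loocv_predict(f$fm, f$ob, spec)$predictions,
                     label = family)
  }
})

test_that("a rank-deficient linear fit warns once and falls back to the pseudo-inverse", {
  set.seed(5)
  x <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(sprintf("R%02d", 1:8), paste0("f", 1:20)))
  ob <- data.frame(region = rownames(x), obesity_rate = rnorm(8, 30, 3))
  expect_warning(fit <- loocv_predict(make_feature_matrix(x), ob,
                                      model_spec("linear")),
                 "pseudo-inverse")
  expect_true(all(is.finite(fit$predictions$predicted)))
})

test_that("constant outcomes and tiny samples are rejected", {
  x <- matrix(1:9, 3, 3, dimnames = list(c("A", "B", "C"), NULL))
  ob <- data.frame(region = c("A", "B", "C"), obesity_rate = c(5, 5, 5))
  expect_error(loocv_predict(make_feature_matrix(x), ob), "constant outcome")
  ob2 <- data.frame(region = c("A", "B"), obesity_rate = c(5, 6))
  expect_error(suppressWarnings(
    loocv_predict(make_feature_matrix(x[1:2, , drop = FALSE]), ob2)),
    ">= 3 regions")
})

test_that("the evaluation grid covers families x combinations and marks the score-only row", {
  w <- generate_world(world_config(n_regions = 8L,
                                   businesses_per_region = 60L,
                                   dishes_per_category = 2L,
                                   records_per_dish = 3L, seed = 12L))
  av <- compute_availability(w$businesses)
  reg <- build_density_registry(w$nutrition, w$popular_dishes)
  sc <- state_weighted_score(av, reg)
  grid <- suppressWarnings(evaluate_grid(
    w$businesses, w$obesity, sc, av,
    families = c("linear", "random_forest", "svm"),
    set_combinations = list("weighted_score",
                            c("availability", "weighted_score")),
    seed = 4L))
  expect_equal(nrow(grid), 6L)
  score_only <- grid$combination == "weighted_score"
  expect_false(grid$applicable[score_only & grid$family == "random_forest"])
  expect_true(is.na(grid$pearson_r[score_only & grid$family == "svm"]))
  expect_true(grid$applicable[score_only & grid$family == "linear"])
  expect_equal(sum(grid$applicable), 4L)
  best <- attr(grid, "best")
  expect_equal(grid$pearson_r[best],
               max(grid$pearson_r[grid$applicable]))
})
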
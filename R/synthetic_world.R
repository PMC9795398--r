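# Synthetic-world generator: complete business/nutrition/dish/obesity tables
# with a planted, tunable link between a region's caloric environment and its
# obesity rate, so every downstream stage is testable without any download.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Built-in food-category table with planted caloric densities
#'
#' Sixty common listing categories with a plausible true caloric density
#' (kcal/gram of a typical popular dish; dish-level densities in nutrition
#' databases run from under 1 for soups and salads to about 4 for bakery
#' goods) and an obesogenic weight (standardized density) that steers how
#' strongly a region's category mix tilts with its latent obesogenicity.
#'
#' @return data frame with columns `label`, `true_density`, `obesogenic_weight`.
#' @export
default_categories <- function() {
  d <- c(
    "fast food" = 2.9, "burgers" = 2.8, "pizza" = 2.7, "fried chicken" = 2.9,
    "chicken wings" = 2.6, "donuts" = 3.9, "bakeries" = 3.6, "desserts" = 3.4,
    "ice cream and frozen yogurt" = 2.2, "candy stores" = 4.3,
    "barbeque" = 2.4, "southern" = 2.7, "soul food" = 2.5,
    "cajun or creole" = 2.4, "steakhouses" = 2.5, "seafood" = 1.8,
    "sushi bars" = 1.5, "poke" = 1.4, "salad" = 0.9,
    "juice bars and smoothies" = 0.6, "vegan" = 1.3, "vegetarian" = 1.4,
    "mediterranean" = 1.7, "greek" = 1.9, "italian" = 2.3, "mexican" = 2.1,
    "tex-mex" = 2.3, "chinese" = 1.9, "thai" = 1.7, "vietnamese" = 1.3,
    "ramen" = 1.5, "japanese" = 1.6, "korean" = 1.8, "indian" = 2.0,
    "middle eastern" = 1.9, "american (new)" = 2.0,
    "american (traditional)" = 2.4, "diners" = 2.4,
    "breakfast and brunch" = 2.2, "cafes" = 2.1, "coffee and tea" = 1.8,
    "sandwiches" = 2.3, "delis" = 2.2, "buffets" = 2.5, "food trucks" = 2.2,
    "hot dogs" = 2.7, "cheesesteaks" = 2.8, "waffles" = 3.0,
    "pancakes" = 2.8, "creperies" = 2.6, "bagels" = 2.7, "soup" = 0.8,
    "noodles" = 1.6, "dim sum" = 2.0, "tapas bars" = 2.1, "wine bars" = 1.6,
    "breweries" = 1.7, "pubs" = 2.2, "cocktail bars" = 1.5,
    "gastropubs" = 2.3)
  data.frame(label = names(d), true_density = unname(d),
             obesogenic_weight = as.numeric(scale(unname(d))),
             stringsAsFactors = FALSE)
}

default_unit_dialects <- function() {
  data.frame(
    unit = c("g", "gram", "grams", "gr", "G", " Grams ",
             "oz", "piece", "slice", "serving", "cup", "package", "breast"),
    is_gram = c(rep(TRUE, 6), rep(FALSE, 7)),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic food-environment world
#'
#' Defaults describe the study-scale desk configuration: 50 regions (49
#' states + DC), 60 food categories, 2000 businesses per region, heavy-tailed
#' review counts (log-normal, matched to a listing-wide mean of about 99
#' reviews with SD about 260), price tiers with mean near 1.6, mixed
#' serving-unit dialects with 30% non-gram records, and a planted linear
#' obesity link calibrated so the generated rates span roughly 20-42% with a
#' signal-to-noise ratio (slope times SD of the true environment score over
#' the outcome noise SD) comfortably above 5.
#'
#' @param n_regions number of regions (>= 3; <= 50 unless `regions` given).
#' @param regions region codes; default first `n_regions` of
#'   [default_regions()].
#' @param categories data frame `label`/`true_density`/`obesogenic_weight`.
#' @param businesses_per_region businesses generated per region.
#' @param region_mix_skew >= 0; how strongly region category mixes tilt
#'   toward high- or low-density categories (0 = exchangeable regions).
#' @param price_tier_probs probabilities of price tiers 1-4 (sum to 1).
#' @param price_missing_prob share of listings without a price tier.
#' @param rating_noise_sd SD of the rating noise around 4.0 stars.
#' @param review_count_log_mean,review_count_log_sd log-normal parameters of
#'   review counts (rounded to integers).
#' @param dishes_per_category popular dishes listed per category.
#' @param records_per_dish nutrition records generated per dish.
#' @param unit_dialects data frame `unit`/`is_gram` of serving-unit spellings.
#' @param nongram_fraction share of nutrition records using non-gram units.
#' @param calorie_noise_cv coefficient of variation of the multiplicative
#'   per-record calorie noise (0 = noiseless).
#' @param obesity_intercept,obesity_slope,obesity_noise_sd linear link from
#'   the true environment score E (kcal/gram) to obesity (%):
#'   `obesity = intercept + slope * E + Normal(0, noise_sd)`, clamped to
#'   (5, 60).
#' @param seed default RNG seed used by [generate_world()].
#' @return object of class `world_config`.
#' @export
world_config <- function(n_regions = 50L,
                         regions = NULL,
                         categories = default_categories(),
                         businesses_per_region = 2000L,
                         region_mix_skew = 1,
                         price_tier_probs = c(0.50, 0.42, 0.06, 0.02),
                         price_missing_prob = 0.10,
                         rating_noise_sd = 0.75,
                         review_count_log_mean = 3.56,
                         review_count_log_sd = 1.44,
                         dishes_per_category = 20L,
                         records_per_dish = 8L,
                         unit_dialects = default_unit_dialects(),
                         nongram_fraction = 0.30,
                         calorie_noise_cv = 0.15,
                         obesity_intercept = -3,
                         obesity_slope = 15,
                         obesity_noise_sd = 0.7,
                         seed = 1L) {
  if (is.null(regions)) {
    if (n_regions > length(default_regions())) {
      stop("n_regions > 50 requires an explicit `regions` vector")
    }
    regions <- head(default_regions(), n_regions)
  }
  n_regions <- length(regions)
  stopifnot(n_regions >= 3L,
            all(c("label", "true_density", "obesogenic_weight") %in%
                  names(categories)),
            nrow(categories) >= 2L, all(categories$true_density > 0),
            !anyDuplicated(categories$label),
            length(price_tier_probs) == 4L, all(price_tier_probs >= 0),
            abs(sum(price_tier_probs) - 1) < 1e-8,
            region_mix_skew >= 0, rating_noise_sd >= 0,
            review_count_log_sd >= 0, calorie_noise_cv >= 0,
            obesity_noise_sd >= 0,
            nongram_fraction >= 0, nongram_fraction <= 1,
            price_missing_prob >= 0, price_missing_prob < 1,
            businesses_per_region >= 1L, dishes_per_category >= 1L,
            records_per_dish >= 1L,
            any(unit_dialects$is_gram))
  structure(list(
    regions = regions, n_regions = n_regions, categories = categories,
    businesses_per_region = as.integer(businesses_per_region),
    region_mix_skew = region_mix_skew, price_tier_probs = price_tier_probs,
    price_missing_prob = price_missing_prob, rating_noise_sd = rating_noise_sd,
    review_count_log_mean = review_count_log_mean,
    review_count_log_sd = review_count_log_sd,
    dishes_per_category = as.integer(dishes_per_category),
    records_per_dish = as.integer(records_per_dish),
    unit_dialects = unit_dialects, nongram_fraction = nongram_fraction,
    calorie_noise_cv = calorie_noise_cv,
    obesity_intercept = obesity_intercept, obesity_slope = obesity_slope,
    obesity_noise_sd = obesity_noise_sd, seed = as.integer(seed)),
    class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf("world_config: %d regions x %d businesses, %d categories\n",
              x$n_regions, x$businesses_per_region, nrow(x$categories)))
  cat(sprintf("  dishes/category %d, records/dish %d, non-gram share %.2f, calorie CV %.2f\n",
              x$dishes_per_category, x$records_per_dish, x$nongram_fraction,
              x$calorie_noise_cv))
  cat(sprintf("  obesity = %.2f + %.2f * E + N(0, %.2f), seed %d\n",
              x$obesity_intercept, x$obesity_slope, x$obesity_noise_sd,
              x$seed))
  invisible(x)
}

#' Generate a synthetic food-environment world
#'
#' Draws, deterministically given the seed: per-region category mixes
#' (Dirichlet base sharpened by `region_mix_skew` toward high- or low-density
#' categories via a latent region obesogenicity in \[-1, 1\]); businesses with
#' 1-3 distinct categories, ordinal price tiers, half-step ratings and
#' log-normal review counts; ranked popular dishes per category; nutrition
#' records per dish whose gram-unit entries have mean calories/gram equal to
#' the category's planted density under multiplicative noise of coefficient
#' of variation `calorie_noise_cv` (a configurable fraction of records uses
#' non-gram unit dialects); and region obesity rates from the planted linear
#' link. The per-region truth `E` is the realized availability-weighted mean
#' of the planted category densities, so in the noiseless all-gram limit the
#' estimation pipeline recovers it exactly.
#'
#' @param config a [world_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return object of class `synthetic_world`: list with `businesses`,
#'   `nutrition`, `popular_dishes`, `obesity`, `registry`, `truth`
#'   (region, `E`), and `config`.
#' @export
generate_world <- function(config = world_config(), seed = NULL) {
  stopifnot(inherits(config, "world_config"))
  seed <- as.integer(seed %||% config$seed)
  with_seed(seed, {
    K <- nrow(config$categories)
    labels <- config$categories$label
    dens <- config$categories$true_density
    w <- config$categories$obesogenic_weight
    R <- config$n_regions
    bpr <- config$businesses_per_region

    # region category mixes: Dirichlet(2) base, tilted by latent obesogenicity
    u <- runif(R, -1, 1)
    base <- matrix(rgamma(R * K, shape = 2, rate = 1), nrow = R)
    tilt <- exp(config$region_mix_skew * outer(u, w))
    mix <- base * tilt
    mix <- mix / rowSums(mix)

    # businesses: 3 iid category draws per business, deduplicated -> 1-3 labels
    n <- R * bpr
    region <- rep(config$regions, each = bpr)
    draws <- matrix(0L, nrow = n, ncol = 3)
    for (r in seq_len(R)) {
      idx <- ((r - 1L) * bpr + 1L):(r * bpr)
      draws[idx, ] <- matrix(sample.int(K, 3L * bpr, replace = TRUE,
                                        prob = mix[r, ]), ncol = 3)
    }
    cats <- apply(draws, 1L, function(z) labels[unique(z)], simplify = FALSE)
    price <- sample.int(4L, n, replace = TRUE, prob = config$price_tier_probs)
    price[runif(n) < config$price_missing_prob] <- NA_integer_
    rating <- pmin(5, pmax(0.5, round(2 * rnorm(n, 4.0,
                                                config$rating_noise_sd)) / 2))
    reviews <- as.integer(round(rlnorm(n, config$review_count_log_mean,
                                       config$review_count_log_sd)))
    businesses <- data.frame(business_id = sprintf("b%06d", seq_len(n)),
                             region = region, stringsAsFactors = FALSE)
    businesses$categories <- cats
    businesses$price_tier <- price
    businesses$rating <- rating
    businesses$review_count <- reviews

    # ranked popular dishes per category (dish names unique across categories)
    dpc <- config$dishes_per_category
    popular <- data.frame(
      category = rep(labels, each = dpc),
      rank = rep(seq_len(dpc), times = K),
      dish = normalize_dish(paste(rep(labels, each = dpc), "dish",
                                  sprintf("%02d", rep(seq_len(dpc), K)))),
      stringsAsFactors = FALSE)

    # nutrition records: gram entries have E[calories/qty] = planted density
    rpd <- config$records_per_dish
    m <- nrow(popular) * rpd
    dish <- rep(popular$dish, each = rpd)
    ddens <- rep(dens[match(popular$category, labels)], each = rpd)
    cv <- config$calorie_noise_cv
    noise <- if (cv > 0) {
      s2 <- log(1 + cv^2)
      rlnorm(m, meanlog = -s2 / 2, sdlog = sqrt(s2))
    } else rep(1, m)
    gram <- runif(m) >= config$nongram_fraction
    gram_units <- config$unit_dialects$unit[config$unit_dialects$is_gram]
    other_units <- config$unit_dialects$unit[!config$unit_dialects$is_gram]
    if (!length(other_units)) gram[] <- TRUE
    unit <- character(m)
    unit[gram] <- sample(gram_units, sum(gram), replace = TRUE)
    unit[!gram] <- sample(other_units, sum(!gram), replace = TRUE)
    qty <- numeric(m)
    qty[gram] <- sample(c(50, 85, 100, 113, 150, 170, 200, 227, 250, 340),
                        sum(gram), replace = TRUE)
    qty[!gram] <- sample(1:3, sum(!gram), replace = TRUE)
    calories <- numeric(m)
    calories[gram] <- ddens[gram] * qty[gram] * noise[gram]
    calories[!gram] <- ddens[!gram] * runif(sum(!gram), 80, 450) *
      noise[!gram]
    nutrition <- data.frame(dish = dish, calories = calories,
                            serving_qty = qty, serving_unit = unit,
                            stringsAsFactors = FALSE)

    # truth: realized availability-weighted mean of planted densities
    avail <- compute_availability(businesses)
    d_by_cat <- dens[match(avail$category, labels)]
    truth <- vapply(split(seq_len(nrow(avail)), avail$region), function(i) {
      sum(avail$availability[i] * d_by_cat[i]) / sum(avail$availability[i])
    }, 0)
    truth <- data.frame(region = names(truth), E = unname(truth),
                        stringsAsFactors = FALSE)
    truth <- truth[match(config$regions, truth$region), , drop = FALSE]
    rownames(truth) <- NULL

    if (config$obesity_slope * diff(range(truth$E)) < config$obesity_noise_sd) {
      warning("degenerate configuration: planted obesity signal (slope x range of E) is weaker than the outcome noise")
    }
    rate <- config$obesity_intercept + config$obesity_slope * truth$E +
      rnorm(R, 0, config$obesity_noise_sd)
    obesity <- data.frame(region = config$regions,
                          obesity_rate = pmin(60, pmax(5, rate)),
                          stringsAsFactors = FALSE)

    registry <- data.frame(
      category = c(labels, "hardware stores", "car wash", "nail salons",
                   "gyms"),
      is_food = c(rep(TRUE, K), rep(FALSE, 4)), stringsAsFactors = FALSE)

    structure(list(businesses = businesses, nutrition = nutrition,
                   popular_dishes = popular, obesity = obesity,
                   registry = registry, truth = truth, config = config,
                   seed = seed),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world (seed %d): %d businesses in %d regions, %d nutrition records, %d popular dishes\n",
              x$seed, nrow(x$businesses), x$config$n_regions,
              nrow(x$nutrition), nrow(x$popular_dishes)))
  cat(sprintf("  obesity range %.1f-%.1f%%, truth E range %.3f-%.3f kcal/g\n",
              min(x$obesity$obesity_rate), max(x$obesity$obesity_rate),
              min(x$truth$E), max(x$truth$E)))
  invisible(x)
}

#' Write the five input tables of a synthetic world to a directory
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_businesses(world$businesses, file.path(dir, "businesses.csv"))
  write_nutrition(world$nutrition, file.path(dir, "nutrition.csv"))
  write_popular_dishes(world$popular_dishes,
                       file.path(dir, "popular_dishes.csv"))
  write_obesity(world$obesity, file.path(dir, "obesity.csv"))
  write_category_registry(world$registry,
                          file.path(dir, "category_registry.csv"))
  invisible(dir)
}
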
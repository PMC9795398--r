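# Fixture builders and independent oracles shared across test files.
# All fixtures are constructed in code; nothing is read from disk except
# files the tests themselves write to tempdir().

# business table with one row per element of cats (a list of character
# vectors); other fields cycled
make_businesses <- function(regions, cats, price = NA_integer_, rating = 4,
                            reviews = 10L) {
  n <- length(cats)
  out <- data.frame(business_id = sprintf("x%04d", seq_len(n)),
                    region = rep_len(regions, n), stringsAsFactors = FALSE)
  out$categories <- cats
  out$price_tier <- rep_len(as.integer(price), n)
  out$rating <- rep_len(rating, n)
  out$review_count <- rep_len(as.integer(reviews), n)
  out
}

# two-region count fixture: x carriers of `category` among n businesses
make_count_world <- function(region, n, x, category = "fast food",
                             filler = "other") {
  cats <- c(rep(list(category), x), rep(list(filler), n - x))
  make_businesses(region, cats)
}

# availability table assembled directly from count data (bypasses business
# generation; used for algebraic property checks)
make_availability <- function(df_counts, region_totals) {
  df_counts$n_region <- region_totals[df_counts$region]
  df_counts$availability <- df_counts$count / df_counts$n_region
  structure(df_counts[order(df_counts$region, df_counts$category), ],
            region_totals = region_totals, zero_regions = character(),
            class = c("availability_table", "data.frame"))
}

make_registry <- function(categories, densities) {
  structure(list(
    dishes = data.frame(dish = character(), density = numeric(),
                        n_gram_records = integer(), stringsAsFactors = FALSE),
    categories = data.frame(category = categories, density = densities,
                            n_dishes = 1L, n_dishes_missing = 0L,
                            stringsAsFactors = FALSE)),
    class = "density_registry")
}

make_feature_matrix <- function(x, regions = rownames(x),
                                sets = "availability") {
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x,
                 meta = data.frame(name = colnames(x), set = sets[1],
                                   category = colnames(x), metric = "value",
                                   stringsAsFactors = FALSE),
                 regions = regions, sets = sets,
                 n_zero_filled = 0L, n_cells = length(x)),
            class = "feature_matrix")
}

# small-world default used where the full study-scale configuration would be
# wastefully large for the property under test
small_config <- function(...) {
  world_config(n_regions = 6L, businesses_per_region = 120L,
               dishes_per_category = 4L, records_per_dish = 4L, ...)
}

# Monte-Carlo permutation oracle for the two-proportion test: shuffles the
# pooled 0/1 outcomes over the two groups; mid-p convention (half weight on
# ties with the observed |difference|) to match a continuous reference.
perm_two_prop_p <- function(x1, n1, x2, n2, B = 1e5, seed = 42) {
  obs <- abs(x1 / n1 - x2 / n2)
  y <- c(rep(1L, x1 + x2), rep(0L, n1 + n2 - x1 - x2))
  set.seed(seed)
  d <- replicate(B, {
    g <- sample(length(y), n1)
    abs(sum(y[g]) / n1 - sum(y[-g]) / n2)
  })
  (sum(d > obs + 1e-12) + 0.5 * sum(abs(d - obs) <= 1e-12)) / B
}

# exact enumeration of the same permutation null (hypergeometric), mid-p
perm_two_prop_exact <- function(x1, n1, x2, n2) {
  K <- x1 + x2; N <- n1 + n2
  k <- max(0, K - n2):min(n1, K)
  pr <- dhyper(k, K, N - K, n1)
  d <- abs(k / n1 - (K - k) / n2)
  obs <- abs(x1 / n1 - x2 / n2)
  sum(pr[d > obs + 1e-12]) + 0.5 * sum(pr[abs(d - obs) <= 1e-12])
}

# truncate (not round) a percentage at `digits` decimals; printed report
# percentages of the form 13.49 for 0.134980 are truncations
pct_trunc <- function(prop, digits = 2) {
  floor(100 * prop * 10^digits) / 10^digits
}

# closed-form leave-one-out predictions for least squares with intercept:
# pred_i = y_i - e_i / (1 - h_ii)
loo_closed_form <- function(x, y) {
  X <- cbind(1, x)
  H <- X %*% solve(crossprod(X), t(X))
  e <- y - drop(H %*% y)
  y - e / (1 - diag(H))
}
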
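# Caloric density estimation: dishes -> categories -> availability-weighted
# region score. Only records denominated in grams enter a dish's density;
# everything else (oz, piece, slice, ...) is discarded, since mixed serving
# units cannot be compared without a unit model.

#' Is a serving unit a gram variant?
#'
#' True iff the trimmed, lowercased unit string is one of `g`, `gr`, `gram`,
#' `grams`.
#'
#' @param unit character vector of raw serving-unit strings.
#' @return logical vector.
#' @export
#' @examples
#' is_gram_unit(c("g", " Grams ", "oz", "slice"))  # TRUE TRUE FALSE FALSE
is_gram_unit <- function(unit) {
  tolower(trimws(as.character(unit))) %in% c("g", "gr", "gram", "grams")
}

#' Caloric density of one dish (kcal/gram)
#'
#' Mean of calories / serving_qty over the dish's gram-denominated records.
#' Records in other units are ignored; a gram record with non-positive
#' quantity is rejected with a warning. Returns `NA` when no gram record
#' survives.
#'
#' @param records data frame of nutrition records for a single dish
#'   (`calories`, `serving_qty`, `serving_unit`).
#' @return kcal/gram, or `NA_real_`.
#' @export
#' @examples
#' recs <- data.frame(calories = c(230, 500), serving_qty = c(100, 1),
#'                    serving_unit = c("g", "piece"))
#' dish_density(recs)  # 2.3
dish_density <- function(records) {
  gram <- is_gram_unit(records$serving_unit)
  bad <- gram & records$serving_qty <= 0
  if (any(bad)) {
    warning(sprintf("rejected %d gram record(s) with non-positive serving quantity",
                    sum(bad)))
    gram <- gram & !bad
  }
  if (!any(gram)) return(NA_real_)
  mean(records$calories[gram] / records$serving_qty[gram])
}

#' Build the dish- and category-density registry
#'
#' Dish densities are means of calories-per-gram over gram-denominated
#' records ([dish_density()]). A category's density is the unweighted mean
#' over its popular dishes' densities; a dish listed twice under one
#' category counts once, and dishes lacking any gram record are excluded and
#' counted. Categories with no dish density at all are dropped with a
#' warning.
#'
#' @param nutrition nutrition-record data frame (dish names already
#'   normalized; [read_nutrition()] does this).
#' @param popular_dishes data frame `category`/`rank`/`dish`.
#' @return object of class `density_registry`: list with `dishes`
#'   (`dish`, `density`, `n_gram_records`) and `categories`
#'   (`category`, `density`, `n_dishes`, `n_dishes_missing`).
#' @export
build_density_registry <- function(nutrition, popular_dishes) {
  nutrition$dish <- normalize_dish(nutrition$dish)
  popular_dishes$dish <- normalize_dish(popular_dishes$dish)
  gram <- is_gram_unit(nutrition$serving_unit)
  bad <- gram & nutrition$serving_qty <= 0
  if (any(bad)) {
    warning(sprintf("rejected %d gram record(s) with non-positive serving quantity",
                    sum(bad)))
    gram <- gram & !bad
  }
  g <- nutrition[gram, , drop = FALSE]
  if (nrow(g)) {
    ratio <- g$calories / g$serving_qty
    dens <- vapply(split(ratio, g$dish), mean, 0)
    dishes <- data.frame(dish = names(dens), density = unname(dens),
                         n_gram_records = as.integer(table(g$dish)[names(dens)]),
                         stringsAsFactors = FALSE)
  } else {
    dishes <- data.frame(dish = character(), density = numeric(),
                         n_gram_records = integer(), stringsAsFactors = FALSE)
  }
  rownames(dishes) <- NULL

  cat_rows <- lapply(split(popular_dishes$dish, popular_dishes$category),
                     unique)
  cats <- data.frame(category = names(cat_rows), stringsAsFactors = FALSE)
  d <- lapply(cat_rows, function(dd) dishes$density[match(dd, dishes$dish)])
  cats$density <- vapply(d, function(x) mean(x[!is.na(x)]), 0)
  cats$n_dishes <- vapply(d, function(x) sum(!is.na(x)), 0L)
  cats$n_dishes_missing <- vapply(d, function(x) sum(is.na(x)), 0L)
  dropped <- cats$category[cats$n_dishes == 0L]
  if (length(dropped)) {
    warning("categories with no dish density dropped from registry: ",
            paste(dropped, collapse = ", "))
    cats <- cats[cats$n_dishes > 0L, , drop = FALSE]
  }
  rownames(cats) <- NULL
  structure(list(dishes = dishes, categories = cats),
            class = "density_registry")
}

#' @export
print.density_registry <- function(x, ...) {
  cat(sprintf("density_registry: %d dishes (kcal/g %.3f-%.3f), %d categories (kcal/g %.3f-%.3f)\n",
              nrow(x$dishes), min(x$dishes$density), max(x$dishes$density),
              nrow(x$categories), min(x$categories$density),
              max(x$categories$density)))
  invisible(x)
}

#' Availability-weighted caloric-density score per region
#'
#' For each region, the normalized weighted mean
#' `sum(a_c * d_c) / sum(a_c)` over categories with availability > 0 in the
#' region *and* a density in the registry; categories lacking a density drop
#' out of numerator and denominator. Normalizing by the summed availability
#' keeps the score inside the range of the contributing category densities
#' (availabilities of multi-category businesses do not sum to 1).
#'
#' @param availability an `availability_table`.
#' @param registry a `density_registry`.
#' @return data frame of class `state_scores`: `region`, `weighted_score`,
#'   `n_categories`.
#' @export
state_weighted_score <- function(availability, registry) {
  stopifnot(inherits(registry, "density_registry"))
  d <- registry$categories$density[match(availability$category,
                                         registry$categories$category)]
  ok <- !is.na(d) & availability$availability > 0
  rows <- split(seq_len(nrow(availability))[ok],
                availability$region[ok])
  all_regions <- unique(availability$region)
  empty <- setdiff(all_regions, names(rows))
  if (length(empty)) {
    stop("no category with both availability and density in region(s): ",
         paste(empty, collapse = ", "))
  }
  score <- vapply(rows, function(i) {
    a <- availability$availability[i]
    sum(a * d[i]) / sum(a)
  }, 0)
  out <- data.frame(region = names(score), weighted_score = unname(score),
                    n_categories = as.integer(lengths(rows)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$region), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("state_scores", "data.frame"))
}

#' Pearson correlation between region scores and obesity rates
#'
#' @param scores a `state_scores` data frame (`region`, `weighted_score`).
#' @param obesity data frame `region`/`obesity_rate`.
#' @return list with `r`, `p.value`, `n` (regions used).
#' @export
score_obesity_correlation <- function(scores, obesity) {
  m <- merge(as.data.frame(scores), obesity, by = "region")
  if (nrow(m) < 3L) stop("need >= 3 common regions, got ", nrow(m))
  if (sd(m$weighted_score) == 0 || sd(m$obesity_rate) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- cor.test(m$weighted_score, m$obesity_rate, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = nrow(m))
}

#' Two-sample z-test of business-level caloric density between two regions
#'
#' Each business is scored with the mean registry density of its categories
#' (categories without a density are skipped; businesses with none are
#' dropped). The unpooled (Welch-type) z statistic
#' `(m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` compares the two per-business
#' samples; the two-sided p-value comes from the standard normal.
#'
#' @param businesses business data frame.
#' @param region_a,region_b region codes.
#' @param registry a `density_registry`.
#' @return list with `z`, `p.value`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
compare_regions_ztest <- function(businesses, region_a, region_b, registry) {
  stopifnot(inherits(registry, "density_registry"))
  dens <- function(region) {
    b <- businesses[businesses$region == region, , drop = FALSE]
    v <- vapply(b$categories, function(cc) {
      d <- registry$categories$density[match(cc, registry$categories$category)]
      if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
    }, 0)
    v[!is.na(v)]
  }
  a <- dens(region_a); b <- dens(region_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need >= 2 businesses with defined density per region (",
         region_a, ": ", length(a), ", ", region_b, ": ", length(b), ")")
  }
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  if (se == 0 && mean(a) == mean(b)) {
    z <- 0
  } else if (se == 0) {
    z <- sign(mean(a) - mean(b)) * Inf
  } else {
    z <- (mean(a) - mean(b)) / se
  }
  list(z = z, p.value = 2 * pnorm(-abs(z)), n_a = length(a), n_b = length(b),
       mean_a = mean(a), mean_b = mean(b))
}
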
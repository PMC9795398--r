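# Region x feature matrix assembly for the obesity regression: per-category
# availability, affordability (mean price tier) and acceptability (mean
# rating, mean review count), plus the one weighted caloric score column.
# Category-region combinations without data are zero-filled, and the share
# of zero-filled cells is tracked.

#' Convert a dollar-sign price symbol to its ordinal tier
#'
#' `"$"` is 1, `"$$$$"` is 4: the count of dollar signs. Anything else is an
#' error.
#'
#' @param symbol character vector of 1-4 dollar signs.
#' @return integer vector of tiers in 1..4.
#' @export
#' @examples
#' price_to_numeric(c("$", "$$$$"))  # 1 4
price_to_numeric <- function(symbol) {
  symbol <- as.character(symbol)
  ok <- grepl("^\\${1,4}$", symbol)
  if (any(!ok)) {
    stop("not a price symbol of 1-4 dollar signs: '",
         symbol[which(!ok)[1]], "'")
  }
  nchar(symbol)
}

per_category_metrics <- c("availability", "price", "rating", "reviews")

#' Assemble the region-by-feature matrix
#'
#' Builds up to three feature sets: `"availability"` (one column per
#' category), `"afford_accept"` (mean price tier, mean rating, mean review
#' count per category; businesses without a price tier are excluded from the
#' price mean but kept for ratings and reviews), and `"weighted_score"` (the
#' single caloric-score column). Per-category cells for category-region
#' combinations without supporting data are filled with 0 and counted.
#' Columns are ordered by category label, then metric
#' (availability, price, rating, reviews), with the weighted score last, so
#' the layout is deterministic and invariant to business row order.
#'
#' @param businesses business data frame (needed for `afford_accept`).
#' @param availability an `availability_table`; computed from `businesses`
#'   when `NULL`.
#' @param scores a `state_scores` data frame (needed for `weighted_score`).
#' @param sets subset of `c("availability", "afford_accept",
#'   "weighted_score")`.
#' @param regions row universe; defaults to regions present in the
#'   availability table.
#' @param categories column universe; defaults to categories present
#'   anywhere in the availability table.
#' @return object of class `feature_matrix`: list with `x` (numeric matrix,
#'   regions x features), `meta` (data frame `name`/`set`/`category`/
#'   `metric`), `regions`, `sets`, `n_zero_filled`, `n_cells` (per-category
#'   cells only).
#' @export
build_features <- function(businesses = NULL, availability = NULL,
                           scores = NULL,
                           sets = c("availability", "afford_accept",
                                    "weighted_score"),
                           regions = NULL, categories = NULL) {
  sets_default <- missing(sets)
  sets <- match.arg(sets, several.ok = TRUE)
  if (sets_default && is.null(scores)) sets <- setdiff(sets, "weighted_score")
  if (is.null(availability)) {
    if (is.null(businesses)) stop("need businesses or an availability table")
    availability <- compute_availability(businesses)
  }
  if ("afford_accept" %in% sets && is.null(businesses)) {
    stop("the afford_accept feature set requires business-level data")
  }
  if ("weighted_score" %in% sets && is.null(scores)) {
    stop("the weighted_score feature set requires a state_scores table")
  }
  regions <- regions %||% sort(unique(availability$region))
  categories <- categories %||% sort(unique(availability$category))
  metrics <- c(if ("availability" %in% sets) "availability",
               if ("afford_accept" %in% sets) c("price", "rating", "reviews"))

  blocks <- list()
  for (m in metrics) {
    blocks[[m]] <- matrix(NA_real_, length(regions), length(categories),
                          dimnames = list(regions, categories))
  }
  av <- availability[availability$region %in% regions &
                       availability$category %in% categories, , drop = FALSE]
  if ("availability" %in% sets) {
    # combinations without a row (count 0) stay NA here and are zero-filled
    # below, so they enter the zero-fill bookkeeping like the other metrics
    blocks$availability[cbind(av$region, av$category)] <- av$availability
  }
  if ("afford_accept" %in% sets) {
    k <- lengths(businesses$categories)
    long <- data.frame(region = rep(businesses$region, k),
                       category = unlist(businesses$categories),
                       price = rep(as.numeric(businesses$price_tier), k),
                       rating = rep(businesses$rating, k),
                       reviews = rep(as.numeric(businesses$review_count), k),
                       stringsAsFactors = FALSE)
    long <- long[long$region %in% regions & long$category %in% categories, ,
                 drop = FALSE]
    key <- split(seq_len(nrow(long)), paste(long$region, long$category,
                                            sep = "\r"))
    for (kk in names(key)) {
      i <- key[[kk]]
      rc <- strsplit(kk, "\r", fixed = TRUE)[[1]]
      p <- long$price[i]
      blocks$price[rc[1], rc[2]] <-
        if (any(!is.na(p))) mean(p[!is.na(p)]) else NA_real_
      blocks$rating[rc[1], rc[2]] <- mean(long$rating[i], na.rm = TRUE)
      blocks$reviews[rc[1], rc[2]] <- mean(long$reviews[i])
    }
  }

  # interleave columns category-major: cat1 metrics..., cat2 metrics...
  cols <- list()
  meta <- list()
  for (cat in categories) {
    for (m in metrics) {
      cols[[length(cols) + 1L]] <- blocks[[m]][, cat]
      meta[[length(meta) + 1L]] <- data.frame(
        name = paste0(cat, "::", m),
        set = if (m == "availability") "availability" else "afford_accept",
        category = cat, metric = m, stringsAsFactors = FALSE)
    }
  }
  x <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(), length(regions), 0)
  n_cells <- length(x)
  n_zero_filled <- sum(is.na(x))
  x[is.na(x)] <- 0

  if ("weighted_score" %in% sets) {
    s <- scores$weighted_score[match(regions, scores$region)]
    if (any(is.na(s))) {
      stop("weighted score missing for region(s): ",
           paste(regions[is.na(s)], collapse = ", "))
    }
    x <- cbind(x, s)
    meta[[length(meta) + 1L]] <- data.frame(
      name = "weighted_score", set = "weighted_score", category = NA,
      metric = "weighted_score", stringsAsFactors = FALSE)
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(name = character(), set = character(), category = character(),
               metric = character(), stringsAsFactors = FALSE)
  dimnames(x) <- list(regions, meta$name)
  structure(list(x = x, meta = meta, regions = regions, sets = sets,
                 n_zero_filled = n_zero_filled, n_cells = n_cells),
            class = "feature_matrix")
}

#' Share of zero-filled per-category feature cells
#'
#' Zero-filled cells (category-region combinations that had no supporting
#' data) over all per-category cells; the weighted-score column is not a
#' per-category feature and is excluded from both counts.
#'
#' @param fm a `feature_matrix`.
#' @return proportion in \[0, 1\].
#' @export
zero_fill_fraction <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$n_cells == 0L) return(0)
  fm$n_zero_filled / fm$n_cells
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d regions x %d features (sets: %s)\n",
              nrow(x$x), ncol(x$x), paste(x$sets, collapse = ", ")))
  if (x$n_cells > 0) {
    cat(sprintf("  zero-filled per-category cells: %d / %d (%.1f%%)\n",
                x$n_zero_filled, x$n_cells,
                100 * zero_fill_fraction(x)))
  }
  invisible(x)
}

#' Restrict a feature matrix to regions with an outcome
#'
#' Regions missing from the obesity table are dropped with a warning
#' (mirroring exclusion of regions without surveillance estimates).
#'
#' @param fm a `feature_matrix`.
#' @param obesity data frame `region`/`obesity_rate`.
#' @return list with the restricted `feature_matrix` and the aligned
#'   `outcome` vector (named by region).
#' @export
align_outcome <- function(fm, obesity) {
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- fm$regions %in% obesity$region
  if (any(!keep)) {
    warning("dropping region(s) without obesity outcome: ",
            paste(fm$regions[!keep], collapse = ", "))
  }
  fm$x <- fm$x[keep, , drop = FALSE]
  fm$regions <- fm$regions[keep]
  y <- obesity$obesity_rate[match(fm$regions, obesity$region)]
  names(y) <- fm$regions
  list(features = fm, outcome = y)
}
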
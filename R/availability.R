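# Category availability per region and between-region contrasts. Availability
# of a category in a region is the share of that region's food businesses
# carrying the category; a business with k categories contributes to k
# category counts but to the region denominator once, so availabilities need
# not sum to 1.

#' Compute category availability per region
#'
#' @param businesses business data frame (list column `categories`).
#' @param regions optional region universe; regions listed here but holding
#'   zero businesses are flagged in attribute `zero_regions` (their
#'   availabilities are undefined, not 0).
#' @return long data frame of class `availability_table` with columns
#'   `region`, `category`, `count`, `n_region`, `availability`, and
#'   attributes `region_totals` (named vector) and `zero_regions`.
#' @export
#' @examples
#' b <- data.frame(business_id = c("a", "b"), region = c("CO", "CO"))
#' b$categories <- list(c("pizza", "cafes"), "pizza")
#' compute_availability(b)
compute_availability <- function(businesses, regions = NULL) {
  stopifnot(nrow(businesses) >= 1L)
  k <- lengths(businesses$categories)
  long <- data.frame(region = rep(businesses$region, k),
                     category = unlist(businesses$categories),
                     stringsAsFactors = FALSE)
  counts <- aggregate(cnt ~ region + category,
                      data = transform(long, cnt = 1L), FUN = sum)
  totals <- table(businesses$region)
  region_totals <- as.integer(totals)
  names(region_totals) <- names(totals)
  out <- data.frame(region = counts$region, category = counts$category,
                    count = as.integer(counts$cnt),
                    n_region = region_totals[counts$region],
                    stringsAsFactors = FALSE)
  out$availability <- out$count / out$n_region
  out <- out[order(out$region, out$category), , drop = FALSE]
  rownames(out) <- NULL
  zero_regions <- character()
  if (!is.null(regions)) {
    zero_regions <- setdiff(regions, names(region_totals))
  }
  structure(out, region_totals = region_totals, zero_regions = zero_regions,
            class = c("availability_table", "data.frame"))
}

#' Availability of one category in one region
#'
#' @param table an `availability_table`.
#' @param region,category scalars.
#' @return proportion in \[0, 1\]; 0 when the category is absent from the
#'   region; `NA` when the region holds no businesses.
#' @export
availability_of <- function(table, region, category) {
  totals <- attr(table, "region_totals")
  if (!(region %in% names(totals))) return(NA_real_)
  i <- table$region == region & table$category == category
  if (!any(i)) return(0)
  table$availability[i][1]
}

#' Pooled two-proportion z-test
#'
#' z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2)) with the pooled estimate
#' p = (x1 + x2) / (n1 + n2); the two-sided p-value comes from the standard
#' normal. A pooled estimate of exactly 0 or 1 carries no information and
#' returns z = 0, p = 1.
#'
#' @param x1,n1,x2,n2 successes and trials in the two groups.
#' @return list with `z` and `p.value`.
#' @export
#' @examples
#' two_proportion_ztest(519, 3845, 358, 7109)
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) return(list(z = 0, p.value = 1))
  z <- (x1 / n1 - x2 / n2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p.value = 2 * pnorm(-abs(z)))
}

sig_tier <- function(p) {
  ifelse(p <= 0.001, "<=.001",
         ifelse(p <= 0.01, "<=.01", ifelse(p <= 0.05, "<=.05", "")))
}

#' Rank between-region availability differences (net values)
#'
#' One row per category present in either region (a category absent from a
#' region counts 0 there). The net value is the absolute availability
#' difference; rows are sorted by descending net value, ties broken by
#' category label. Each contrast carries the pooled two-proportion z-test on
#' the underlying counts and a significance-tier annotation
#' (<=.001 / <=.01 / <=.05).
#'
#' @param table an `availability_table`.
#' @param region_a,region_b region codes, both present in the table.
#' @param adjust `"none"` (default; raw p-values, as reported) or `"BH"` to
#'   add a Benjamini-Hochberg adjusted column `p_adj`.
#' @return data frame of class `region_comparison`: `category`,
#'   `availability_a`, `availability_b`, `net_value`, `direction`, `z`,
#'   `p.value`, `sig` (and `p_adj` if requested).
#' @export
rank_net_differences <- function(table, region_a, region_b,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  totals <- attr(table, "region_totals")
  if (!all(c(region_a, region_b) %in% names(totals))) {
    stop("both regions must hold businesses: ",
         paste(setdiff(c(region_a, region_b), names(totals)), collapse = ", "))
  }
  sub <- table[table$region %in% c(region_a, region_b), , drop = FALSE]
  cats <- sort(unique(sub$category))
  cnt <- function(region) {
    x <- integer(length(cats))
    i <- sub$region == region
    x[match(sub$category[i], cats)] <- sub$count[i]
    x
  }
  xa <- cnt(region_a); xb <- cnt(region_b)
  na <- totals[[region_a]]; nb <- totals[[region_b]]
  pa <- xa / na; pb <- xb / nb
  zt <- mapply(function(x1, x2) unlist(two_proportion_ztest(x1, na, x2, nb)),
               xa, xb)
  out <- data.frame(category = cats, availability_a = pa, availability_b = pb,
                    net_value = abs(pa - pb),
                    direction = ifelse(pa > pb, region_a,
                                       ifelse(pb > pa, region_b, "tie")),
                    z = zt["z", ], p.value = zt["p.value", ],
                    stringsAsFactors = FALSE)
  out$sig <- sig_tier(out$p.value)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p.value, "BH")
  out <- out[order(-out$net_value, out$category), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, region_a = region_a, region_b = region_b,
            n_a = na, n_b = nb,
            class = c("region_comparison", "data.frame"))
}

#' Share of categories with a significant availability difference
#'
#' Mirrors the summary "k of n categories differ significantly between the
#' two regions"; the denominator is the number of categories present in
#' either region.
#'
#' @param comparison a `region_comparison` from [rank_net_differences()].
#' @param alpha significance level (default 0.05).
#' @param use_adjusted use the BH-adjusted column if present.
#' @return list with `n_significant`, `n_categories`, `fraction`.
#' @export
significant_fraction <- function(comparison, alpha = 0.05,
                                 use_adjusted = FALSE) {
  p <- if (use_adjusted && !is.null(comparison$p_adj)) comparison$p_adj
       else comparison$p.value
  list(n_significant = sum(p <= alpha), n_categories = length(p),
       fraction = sum(p <= alpha) / length(p))
}

#' @export
print.region_comparison <- function(x, n = 10L, ...) {
  cat(sprintf("availability contrast %s (n=%d) vs %s (n=%d); %d categories\n",
              attr(x, "region_a"), attr(x, "n_a"), attr(x, "region_b"),
              attr(x, "n_b"), nrow(x)))
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... %d more categories\n", nrow(x) - n))
  invisible(x)
}
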
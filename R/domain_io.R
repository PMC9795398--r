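# Typed readers/writers for the five input tables. On-disk format is UTF-8
# CSV; the multi-valued `categories` column is a JSON-encoded string array so
# fixtures stay human-inspectable and diffable.

stop_io <- function(fmt, ..., class = "foodscape_io_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

read_table_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop_io("input file not found: %s", path, class = "foodscape_missing_file")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop_io("%s: missing required column(s): %s", path,
            paste(missing, collapse = ", "))
  }
  df
}

as_num <- function(x, what, path, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(allow_na & (is.na(x) | x == "")))
  if (length(bad)) {
    stop_io("%s: line %d: malformed %s value '%s'", path, bad[1] + 1L, what,
            x[bad[1]])
  }
  out
}

#' Read a business-listing table
#'
#' Expected columns: `business_id`, `region`, `categories` (JSON string
#' array, 1-3 labels), `price_tier` (1-4 or empty), `rating` (half steps in
#' 0.5-5, or empty), `review_count`. If a category registry is supplied,
#' non-food categories are dropped from each record and records left with no
#' category are excluded (the count of exclusions is reported via `message()`
#' and attached as attribute `n_excluded`).
#'
#' @param path CSV file path.
#' @param registry optional data frame `category`/`is_food` (see
#'   [read_category_registry()]).
#' @param regions allowed region codes; a row with any other code is an error.
#' @return data frame with one row per business; `categories` is a list
#'   column of character vectors.
#' @export
read_businesses <- function(path, registry = NULL, regions = default_regions()) {
  cols <- c("business_id", "region", "categories", "price_tier", "rating",
            "review_count")
  df <- read_table_checked(path, cols)
  if (nrow(df) == 0L) {
    warning("empty business table: ", path)
    out <- data.frame(business_id = character(), region = character(),
                      price_tier = integer(), rating = numeric(),
                      review_count = integer(), stringsAsFactors = FALSE)
    out$categories <- list()
    return(out)
  }
  cats <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    parsed <- tryCatch(jsonlite::fromJSON(df$categories[i]),
                       error = function(e) NULL)
    if (is.null(parsed) || !is.character(parsed) || length(parsed) < 1L) {
      stop_io("%s: line %d: malformed categories field '%s'", path, i + 1L,
              df$categories[i])
    }
    cats[[i]] <- parsed
  }
  bad_region <- which(!(df$region %in% regions))
  if (length(bad_region)) {
    stop_io("%s: line %d: unknown region code '%s'", path, bad_region[1] + 1L,
            df$region[bad_region[1]])
  }
  out <- data.frame(business_id = df$business_id, region = df$region,
                    stringsAsFactors = FALSE)
  out$categories <- cats
  out$price_tier <- as.integer(as_num(df$price_tier, "price_tier", path,
                                      allow_na = TRUE))
  out$rating <- as_num(df$rating, "rating", path, allow_na = TRUE)
  out$review_count <- as.integer(as_num(df$review_count, "review_count", path))
  validate_businesses(out, path)
  if (!is.null(registry)) out <- filter_food_categories(out, registry)
  out
}

validate_businesses <- function(b, path = "<businesses>") {
  nlab <- lengths(b$categories)
  bad <- which(nlab < 1L | nlab > 3L)
  if (length(bad)) {
    stop_io("%s: line %d: business must carry 1-3 categories, got %d", path,
            bad[1] + 1L, nlab[bad[1]])
  }
  dup <- which(vapply(b$categories, anyDuplicated, 1L) > 0L)
  if (length(dup)) {
    stop_io("%s: line %d: duplicate category label within one business", path,
            dup[1] + 1L)
  }
  r <- b$rating
  bad <- which(!is.na(r) & (r < 0.5 | r > 5 | abs(r * 2 - round(r * 2)) > 1e-9))
  if (length(bad)) {
    stop_io("%s: line %d: rating %s is not a half-step value in [0.5, 5]",
            path, bad[1] + 1L, r[bad[1]])
  }
  bad <- which(is.na(b$review_count) | b$review_count < 0L)
  if (length(bad)) {
    stop_io("%s: line %d: review_count must be a non-negative integer", path,
            bad[1] + 1L)
  }
  bad <- which(!is.na(b$price_tier) & !(b$price_tier %in% 1:4))
  if (length(bad)) {
    stop_io("%s: line %d: price_tier must be 1-4 or missing", path,
            bad[1] + 1L)
  }
  invisible(b)
}

#' Drop non-food categories from business records
#'
#' Labels not flagged food-related in the registry are removed from each
#' record's category list; records whose list becomes empty are excluded.
#' Idempotent: filtering an already-filtered table changes nothing.
#'
#' @param businesses business data frame (see [read_businesses()]).
#' @param registry data frame with columns `category`, `is_food`.
#' @return filtered business data frame, with attribute `n_excluded`.
#' @export
filter_food_categories <- function(businesses, registry) {
  stopifnot(all(c("category", "is_food") %in% names(registry)))
  food <- registry$category[as.logical(registry$is_food)]
  kept <- lapply(businesses$categories, function(x) x[x %in% food])
  keep_row <- lengths(kept) > 0L
  n_excluded <- sum(!keep_row)
  out <- businesses[keep_row, , drop = FALSE]
  out$categories <- kept[keep_row]
  rownames(out) <- NULL
  if (n_excluded > 0L) {
    message(sprintf("filter_food_categories: excluded %d business(es) with no food-related category",
                    n_excluded))
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a business-listing table
#' @param businesses business data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_businesses <- function(businesses, path) {
  df <- businesses
  df$categories <- vapply(businesses$categories,
                          function(x) as.character(jsonlite::toJSON(x)), "")
  df <- df[, c("business_id", "region", "categories", "price_tier", "rating",
               "review_count")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read crowd-sourced nutrition records
#'
#' Columns: `dish`, `calories` (kcal per stated serving, > 0), `serving_qty`
#' (> 0), `serving_unit` (free text, mixed dialects such as "g", "gram",
#' "oz", "slice"). Dish names are normalized with [normalize_dish()].
#'
#' @param path CSV file path.
#' @return data frame of nutrition records.
#' @export
read_nutrition <- function(path) {
  df <- read_table_checked(path, c("dish", "calories", "serving_qty",
                                   "serving_unit"))
  if (nrow(df) == 0L) {
    warning("empty nutrition table: ", path)
    return(data.frame(dish = character(), calories = numeric(),
                      serving_qty = numeric(), serving_unit = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(dish = normalize_dish(df$dish),
                    calories = as_num(df$calories, "calories", path),
                    serving_qty = as_num(df$serving_qty, "serving_qty", path),
                    serving_unit = df$serving_unit,
                    stringsAsFactors = FALSE)
  bad <- which(out$calories <= 0)
  if (length(bad)) {
    stop_io("%s: line %d: calories must be > 0, got %s", path, bad[1] + 1L,
            out$calories[bad[1]])
  }
  bad <- which(out$serving_qty <= 0)
  if (length(bad)) {
    stop_io("%s: line %d: serving_qty must be > 0, got %s", path, bad[1] + 1L,
            out$serving_qty[bad[1]])
  }
  out
}

#' @rdname read_nutrition
#' @param nutrition nutrition data frame.
#' @export
write_nutrition <- function(nutrition, path) {
  utils::write.csv(nutrition[, c("dish", "calories", "serving_qty",
                                 "serving_unit")], path, row.names = FALSE)
  invisible(path)
}

#' Read a region obesity-prevalence table
#'
#' Columns: `region`, `obesity_rate` (percentage in (0, 100)). One row per
#' region; duplicates are an error.
#'
#' @param path CSV file path.
#' @param regions allowed region codes.
#' @return data frame `region`/`obesity_rate`.
#' @export
read_obesity <- function(path, regions = default_regions()) {
  df <- read_table_checked(path, c("region", "obesity_rate"))
  if (nrow(df) == 0L) {
    warning("empty obesity table: ", path)
    return(data.frame(region = character(), obesity_rate = numeric(),
                      stringsAsFactors = FALSE))
  }
  dup <- which(duplicated(df$region))
  if (length(dup)) {
    stop_io("%s: line %d: duplicate region '%s' in obesity table", path,
            dup[1] + 1L, df$region[dup[1]])
  }
  bad <- which(!(df$region %in% regions))
  if (length(bad)) {
    stop_io("%s: line %d: unknown region code '%s'", path, bad[1] + 1L,
            df$region[bad[1]])
  }
  rate <- as_num(df$obesity_rate, "obesity_rate", path)
  bad <- which(rate <= 0 | rate >= 100)
  if (length(bad)) {
    stop_io("%s: line %d: obesity_rate must be in (0, 100), got %s", path,
            bad[1] + 1L, rate[bad[1]])
  }
  data.frame(region = df$region, obesity_rate = rate, stringsAsFactors = FALSE)
}

#' @rdname read_obesity
#' @param obesity obesity data frame.
#' @export
write_obesity <- function(obesity, path) {
  utils::write.csv(obesity[, c("region", "obesity_rate")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a ranked popular-dish table
#'
#' Columns: `category`, `rank`, `dish`. Each listed category must carry at
#' least one dish. Dish names are normalized.
#'
#' @param path CSV file path.
#' @return data frame `category`/`rank`/`dish`, ordered by category then rank.
#' @export
read_popular_dishes <- function(path) {
  df <- read_table_checked(path, c("category", "rank", "dish"))
  if (nrow(df) == 0L) {
    warning("empty popular-dish table: ", path)
    return(data.frame(category = character(), rank = integer(),
                      dish = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(category = df$category,
                    rank = as.integer(as_num(df$rank, "rank", path)),
                    dish = normalize_dish(df$dish), stringsAsFactors = FALSE)
  bad <- which(is.na(out$dish) | out$dish == "")
  if (length(bad)) {
    stop_io("%s: line %d: empty dish name", path, bad[1] + 1L)
  }
  out[order(out$category, out$rank), , drop = FALSE]
}

#' @rdname read_popular_dishes
#' @param popular_dishes popular-dish data frame.
#' @export
write_popular_dishes <- function(popular_dishes, path) {
  utils::write.csv(popular_dishes[, c("category", "rank", "dish")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a category registry (food-related flags)
#'
#' Columns: `category`, `is_food` (logical / "TRUE"/"FALSE"/0/1). Filtering
#' with [filter_food_categories()] retains only flagged categories.
#'
#' @param path CSV file path.
#' @return data frame `category`/`is_food`.
#' @export
read_category_registry <- function(path) {
  df <- read_table_checked(path, c("category", "is_food"))
  flag <- toupper(trimws(df$is_food)) %in% c("TRUE", "T", "1")
  data.frame(category = df$category, is_food = flag, stringsAsFactors = FALSE)
}

#' @rdname read_category_registry
#' @param registry registry data frame.
#' @export
write_category_registry <- function(registry, path) {
  utils::write.csv(registry[, c("category", "is_food")], path,
                   row.names = FALSE)
  invisible(path)
}
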
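# Leave-one-out cross-validated obesity regression over feature-set
# combinations, evaluated by Pearson correlation between actual and
# predicted rates. Each fold refits from scratch; stochastic learners are
# re-seeded per fold from the spec seed plus the held-out region's rank in
# the sorted region universe (rank, not row position, so predictions are
# invariant to region order).

#' Pearson product-moment correlation
#'
#' @param actual,predicted numeric vectors of equal length >= 3; an error if
#'   either is constant.
#' @return correlation coefficient.
#' @export
pearson <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 3L)
  if (sd(actual) == 0 || sd(predicted) == 0) {
    stop("constant input: Pearson correlation undefined")
  }
  cor(actual, predicted, method = "pearson")
}

#' Specify a regression family for obesity prediction
#'
#' @param family one of `"linear"`, `"random_forest"`, `"svm"`,
#'   `"gradient_boosted_trees"`.
#' @param hyperparameters named list overriding library defaults
#'   (`ntree` = 100 for the random forest; `cost`, `epsilon`, `gamma` for the
#'   radial-basis support-vector machine; `nrounds` = 100, `max_depth`,
#'   `eta` for the gradient-boosted trees).
#' @param seed base seed for stochastic families.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("linear", "random_forest", "svm",
                                  "gradient_boosted_trees"),
                       hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, hyperparameters = hyperparameters,
                 seed = as.integer(seed)), class = "model_spec")
}

# train-fold standardization; constant columns get scale 1 so they map to 0
std_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(ctr = ctr, scl = scl)
}
std_apply <- function(x, s) scale(x, center = s$ctr, scale = s$scl)

fe_train <- function(family, x, y, hp, seed) {
  switch(family,
    linear = {
      s <- std_fit(x)
      X <- cbind(1, std_apply(x, s))
      qx <- qr(X)
      singular <- qx$rank < ncol(X)
      beta <- if (singular) MASS::ginv(X) %*% y else qr.coef(qx, y)
      beta[is.na(beta)] <- 0
      list(singular = singular,
           predict = function(newx)
             drop(cbind(1, std_apply(newx, s)) %*% beta))
    },
    random_forest = {
      set.seed(seed)
      fit <- randomForest::randomForest(x = x, y = y,
                                        ntree = hp$ntree %||% 100L)
      list(singular = FALSE,
           predict = function(newx) unname(predict(fit, newx)))
    },
    svm = {
      s <- std_fit(x)
      fit <- e1071::svm(x = std_apply(x, s), y = y, type = "eps-regression",
                        kernel = "radial", scale = FALSE,
                        cost = hp$cost %||% 1,
                        epsilon = hp$epsilon %||% 0.1,
                        gamma = hp$gamma %||% (1 / ncol(x)))
      list(singular = FALSE,
           predict = function(newx)
             unname(predict(fit, std_apply(newx, s))))
    },
    gradient_boosted_trees = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", nthread = 1,
                      max_depth = hp$max_depth %||% 6,
                      eta = hp$eta %||% 0.3),
        data = dtrain, nrounds = hp$nrounds %||% 100L, verbose = 0)
      list(singular = FALSE,
           predict = function(newx)
             unname(predict(fit, xgboost::xgb.DMatrix(newx))))
    },
    stop("unknown family: ", family))
}

#' Leave-one-out cross-validated obesity prediction
#'
#' For each region, a model of the requested family is refitted on all other
#' regions and the held-out region's obesity rate is predicted; no fold sees
#' its own outcome. Features are standardized with train-fold statistics for
#' the linear and support-vector families and left raw for the tree
#' families. A rank-deficient linear fit (more features than training
#' regions) falls back to the minimum-norm pseudo-inverse solution with one
#' warning.
#'
#' @param features a `feature_matrix`.
#' @param obesity data frame `region`/`obesity_rate` (regions missing from
#'   it are dropped with a warning) or a named numeric vector.
#' @param spec a [model_spec()].
#' @return object of class `fe_loocv`: list with `predictions`
#'   (`region`, `actual`, `predicted`), `pearson_r`, `spec`, `sets`.
#' @export
loocv_predict <- function(features, obesity, spec = model_spec("linear")) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(spec, "model_spec"))
  if (is.data.frame(obesity)) {
    al <- align_outcome(features, obesity)
    features <- al$features
    y <- al$outcome
  } else {
    stopifnot(!is.null(names(obesity)),
              all(features$regions %in% names(obesity)))
    y <- obesity[features$regions]
  }
  # canonical row order: fold composition (and hence bootstrap/optimizer
  # behaviour in order-sensitive learners) must not depend on input order
  ord <- order(features$regions)
  features$x <- features$x[ord, , drop = FALSE]
  features$regions <- features$regions[ord]
  y <- y[ord]
  x <- features$x
  n <- nrow(x)
  if (n < 3L) stop("need >= 3 regions for leave-one-out prediction")
  if (sd(y) == 0) stop("constant outcome: evaluation undefined")
  fold_seed <- spec$seed + match(features$regions, sort(features$regions))
  pred <- numeric(n)
  any_singular <- FALSE
  for (i in seq_len(n)) {
    fit <- fe_train(spec$family, x[-i, , drop = FALSE], y[-i],
                    spec$hyperparameters, fold_seed[i])
    any_singular <- any_singular || fit$singular
    pred[i] <- fit$predict(x[i, , drop = FALSE])
  }
  if (any_singular) {
    warning("rank-deficient linear fit in at least one fold; minimum-norm pseudo-inverse used")
  }
  predictions <- data.frame(region = features$regions, actual = unname(y),
                            predicted = pred, stringsAsFactors = FALSE)
  structure(list(predictions = predictions,
                 pearson_r = pearson(predictions$actual,
                                     predictions$predicted),
                 spec = spec, sets = features$sets),
            class = "fe_loocv")
}

#' @export
print.fe_loocv <- function(x, ...) {
  cat(sprintf("leave-one-out obesity prediction (%s; sets: %s)\n",
              x$spec$family, paste(x$sets, collapse = "+")))
  cat(sprintf("  %d regions, Pearson r (actual vs predicted) = %.3f\n",
              nrow(x$predictions), x$pearson_r))
  invisible(x)
}

#' @export
summary.fe_loocv <- function(object, ...) {
  e <- object$predictions$actual - object$predictions$predicted
  out <- list(family = object$spec$family, sets = object$sets,
              n = nrow(object$predictions), pearson_r = object$pearson_r,
              rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
  class(out) <- "summary.fe_loocv"
  out
}

#' @export
print.summary.fe_loocv <- function(x, ...) {
  cat(sprintf("LOOCV %s on %s: n = %d regions\n", x$family,
              paste(x$sets, collapse = "+"), x$n))
  cat(sprintf("  Pearson r = %.3f, RMSE = %.2f, MAE = %.2f (percentage points)\n",
              x$pearson_r, x$rmse, x$mae))
  invisible(x)
}

#' @export
residuals.fe_loocv <- function(object, ...) {
  r <- object$predictions$actual - object$predictions$predicted
  names(r) <- object$predictions$region
  r
}

#' @export
plot.fe_loocv <- function(x, ...) {
  p <- x$predictions
  plot(p$actual, p$predicted,
       xlab = "actual obesity rate (%)", ylab = "predicted obesity rate (%)",
       main = sprintf("LOOCV %s: r = %.3f", x$spec$family, x$pearson_r), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Default feature-set combinations for the evaluation grid
#'
#' The six combinations evaluated: each single set, availability +
#' affordability/acceptability, availability + weighted score, and all
#' three.
#'
#' @return list of character vectors.
#' @export
default_set_combinations <- function() {
  list("availability",
       "afford_accept",
       "weighted_score",
       c("availability", "afford_accept"),
       c("availability", "weighted_score"),
       c("availability", "afford_accept", "weighted_score"))
}

#' Evaluate the LOOCV grid over families and feature-set combinations
#'
#' One row per (combination, family). The weighted-score-only combination is
#' a single-feature input for which only the linear family applies; other
#' families are marked not applicable (`pearson_r = NA`).
#'
#' @param businesses business data frame.
#' @param obesity data frame `region`/`obesity_rate`.
#' @param scores a `state_scores` data frame (required when any combination
#'   uses the weighted score).
#' @param availability optional precomputed `availability_table`.
#' @param families regression families to run.
#' @param set_combinations list of feature-set vectors
#'   (default [default_set_combinations()]).
#' @param seed base seed passed to each [model_spec()].
#' @param hyperparameters shared hyperparameter list.
#' @return data frame of class `fe_grid`: `combination`, `family`,
#'   `pearson_r`, `applicable`; the best cell is flagged by attribute
#'   `best` and in `print()`.
#' @export
evaluate_grid <- function(businesses, obesity, scores = NULL,
                          availability = NULL,
                          families = c("linear", "random_forest", "svm",
                                       "gradient_boosted_trees"),
                          set_combinations = default_set_combinations(),
                          seed = 1L, hyperparameters = list()) {
  families <- match.arg(families, several.ok = TRUE)
  availability <- availability %||% compute_availability(businesses)
  rows <- list()
  for (sets in set_combinations) {
    fm <- build_features(businesses = businesses, availability = availability,
                         scores = scores, sets = sets)
    label <- paste(sets, collapse = "+")
    for (family in families) {
      applicable <- !(identical(sort(sets), "weighted_score") &&
                        family != "linear")
      r <- NA_real_
      if (applicable) {
        fit <- loocv_predict(fm, obesity,
                             model_spec(family, hyperparameters, seed))
        r <- fit$pearson_r
      }
      rows[[length(rows) + 1L]] <- data.frame(
        combination = label, family = family, pearson_r = r,
        applicable = applicable, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- which.max(ifelse(out$applicable, out$pearson_r, -Inf))
  structure(out, best = best, class = c("fe_grid", "data.frame"))
}

#' @export
print.fe_grid <- function(x, ...) {
  df <- as.data.frame(x)
  df$pearson_r <- ifelse(df$applicable, sprintf("%.3f", df$pearson_r), "-")
  df$applicable <- NULL
  best <- attr(x, "best")
  df$best <- ""
  df$best[best] <- "*"
  cat("LOOCV Pearson r by feature-set combination and family\n")
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("best: %s / %s (r = %.3f)\n", x$combination[best],
              x$family[best], x$pearson_r[best]))
  invisible(x)
}
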
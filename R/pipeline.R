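# End-to-end orchestration: ingest (or generate) -> availability ->
# caloric score -> features -> LOOCV grid -> report, driven by one YAML
# config, with a manifest recording seeds and row counts. Reruns with an
# identical config and seed reproduce identical artifacts.

write_artifact <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  name
}

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

#' Run the full food-environment pipeline
#'
#' Stages: load the five tables from `config$inputs` (or generate a
#' synthetic world from `config$generate`), apply the food-category filter,
#' compute availability, contrast the configured (or lowest- vs
#' highest-obesity) region pair, build the density registry and weighted
#' scores, correlate score with obesity, assemble features, and run the
#' LOOCV evaluation grid. All tabular artifacts are CSV; `manifest.json`
#' records the config hash, seeds, versions and row counts. On error a
#' `FAILED` marker naming the failure is left in the output directory and
#' the error is re-signalled.
#'
#' @param config path to a YAML file or an equivalent nested list. Keys:
#'   `inputs` (paths `businesses`, `nutrition`, `popular_dishes`, `obesity`,
#'   optional `category_registry`) *or* `generate` (arguments to
#'   [world_config()]); optional `regions`; optional `analysis`
#'   (`compare_regions`, `adjust`, `families`, `set_combinations`, `seed`);
#'   `output` directory.
#' @param out_dir overrides `config$output`.
#' @param seed overrides the generation and analysis seeds.
#' @return invisibly, a list with `dir`, `artifacts`, `availability`,
#'   `comparison`, `registry`, `scores`, `score_obesity`, `features`,
#'   `grid`, `best`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$output
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  tryCatch(
    run_pipeline_stages(cfg, out_dir, seed),
    error = function(e) {
      writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
      stop(e)
    })
}

run_pipeline_stages <- function(cfg, out_dir, seed) {
  regions <- cfg$regions %||% default_regions()
  artifacts <- character()

  if (!is.null(cfg$generate)) {
    gargs <- cfg$generate
    gseed <- as.integer(seed %||% gargs$seed %||% 1L)
    gargs$seed <- gseed
    if (!is.null(gargs$regions)) regions <- gargs$regions
    wc <- do.call(world_config, gargs)
    message(sprintf("generating synthetic world (seed %d)", gseed))
    world <- generate_world(wc)
    businesses <- world$businesses
    nutrition <- world$nutrition
    popular <- world$popular_dishes
    obesity <- world$obesity
    registry <- world$registry
    regions <- wc$regions
  } else if (!is.null(cfg$inputs)) {
    registry <- NULL
    if (!is.null(cfg$inputs$category_registry)) {
      registry <- read_category_registry(cfg$inputs$category_registry)
    }
    businesses <- read_businesses(cfg$inputs$businesses, registry, regions)
    nutrition <- read_nutrition(cfg$inputs$nutrition)
    popular <- read_popular_dishes(cfg$inputs$popular_dishes)
    obesity <- read_obesity(cfg$inputs$obesity, regions)
  } else {
    stop("config must provide either `inputs` paths or a `generate` block")
  }

  availability <- compute_availability(businesses, regions)
  artifacts <- c(artifacts,
                 write_artifact(as.data.frame(availability), out_dir,
                                "availability.csv"))

  an <- cfg$analysis %||% list()
  pair <- unlist(an$compare_regions) %||% {
    with_b <- obesity$region %in% unique(businesses$region)
    o <- obesity[with_b, , drop = FALSE]
    c(o$region[which.min(o$obesity_rate)], o$region[which.max(o$obesity_rate)])
  }
  comparison <- rank_net_differences(availability, pair[1], pair[2],
                                     adjust = an$adjust %||% "none")
  artifacts <- c(artifacts,
                 write_artifact(as.data.frame(comparison), out_dir,
                                sprintf("comparisons_%s_vs_%s.csv",
                                        pair[1], pair[2])))

  dreg <- build_density_registry(nutrition, popular)
  artifacts <- c(artifacts,
                 write_artifact(dreg$dishes, out_dir, "dish_density.csv"),
                 write_artifact(dreg$categories, out_dir,
                                "category_density.csv"))
  scores <- state_weighted_score(availability, dreg)
  artifacts <- c(artifacts,
                 write_artifact(as.data.frame(scores), out_dir,
                                "state_scores.csv"))
  score_obesity <- score_obesity_correlation(scores, obesity)
  pair_z <- compare_regions_ztest(businesses, pair[2], pair[1], dreg)

  fm <- build_features(businesses, availability, scores)
  al <- align_outcome(fm, obesity)
  fdf <- data.frame(region = al$features$regions, al$features$x,
                    check.names = FALSE)
  artifacts <- c(artifacts,
                 write_artifact(fdf, out_dir, "features.csv"),
                 write_artifact(fm$meta, out_dir, "feature_meta.csv"))

  aseed <- as.integer(seed %||% an$seed %||% 1L)
  combos <- an$set_combinations
  combos <- if (is.null(combos)) default_set_combinations() else
    lapply(combos, as.character)
  families <- unlist(an$families) %||%
    c("linear", "random_forest", "svm", "gradient_boosted_trees")
  grid <- evaluate_grid(businesses, obesity, scores, availability,
                        families = families, set_combinations = combos,
                        seed = aseed)
  artifacts <- c(artifacts,
                 write_artifact(as.data.frame(grid), out_dir, "grid.csv"))
  b <- attr(grid, "best")
  best_fm <- build_features(businesses, availability, scores,
                            sets = strsplit(grid$combination[b],
                                            "+", fixed = TRUE)[[1]])
  best_fit <- loocv_predict(best_fm, obesity,
                            model_spec(grid$family[b], seed = aseed))
  artifacts <- c(artifacts,
                 write_artifact(best_fit$predictions, out_dir,
                                "predictions.csv"))

  report <- pipeline_report(businesses, availability, comparison, dreg,
                            scores, score_obesity, pair, pair_z, fm, grid,
                            best_fit)
  writeLines(report, file.path(out_dir, "report.md"))
  artifacts <- c(artifacts, "report.md")

  manifest <- list(
    package = "foodscape",
    package_version = as.character(utils::packageVersion("foodscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = config_hash(cfg),
    seed = as.integer(seed %||% an$seed %||% cfg$generate$seed %||% 1L),
    counts = list(businesses = nrow(businesses),
                  nutrition_records = nrow(nutrition),
                  popular_dishes = nrow(popular),
                  regions = length(unique(businesses$region)),
                  categories = length(unique(availability$category))),
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  artifacts <- c(artifacts, "manifest.json")

  message(sprintf("pipeline complete: %d artifacts in %s", length(artifacts),
                  out_dir))
  invisible(list(dir = out_dir, artifacts = artifacts,
                 availability = availability, comparison = comparison,
                 registry = dreg, scores = scores,
                 score_obesity = score_obesity, pair = pair, pair_z = pair_z,
                 features = fm, grid = grid, best = best_fit))
}

pipeline_report <- function(businesses, availability, comparison, dreg,
                            scores, score_obesity, pair, pair_z, fm, grid,
                            best_fit) {
  sf <- significant_fraction(comparison)
  b <- attr(grid, "best")
  c(
    "# Food-environment pipeline report", "",
    sprintf("- businesses: %d in %d regions, %d categories",
            nrow(businesses), length(unique(businesses$region)),
            length(unique(availability$category))),
    sprintf("- availability contrast %s vs %s: %d/%d categories significant at 0.05 (%.1f%%)",
            attr(comparison, "region_a"), attr(comparison, "region_b"),
            sf$n_significant, sf$n_categories, 100 * sf$fraction),
    sprintf("- top net-value category: %s (net %.4f, higher in %s)",
            comparison$category[1], comparison$net_value[1],
            comparison$direction[1]),
    sprintf("- category densities: %d categories, %.3f-%.3f kcal/g",
            nrow(dreg$categories), min(dreg$categories$density),
            max(dreg$categories$density)),
    sprintf("- weighted scores: %.3f-%.3f kcal/g across %d regions",
            min(scores$weighted_score), max(scores$weighted_score),
            nrow(scores)),
    sprintf("- business-level density z (%s vs %s): %.3f (p = %.3g)",
            pair[2], pair[1], pair_z$z, pair_z$p.value),
    sprintf("- score vs obesity: Pearson r = %.3f (p = %.3g, n = %d)",
            score_obesity$r, score_obesity$p.value, score_obesity$n),
    sprintf("- zero-filled per-category feature cells: %d/%d (%.1f%%)",
            fm$n_zero_filled, fm$n_cells, 100 * zero_fill_fraction(fm)),
    "",
    "## LOOCV Pearson r grid", "",
    paste0("| combination | family | r |"),
    paste0("|---|---|---|"),
    sprintf("| %s | %s | %s |", grid$combination, grid$family,
            ifelse(grid$applicable, sprintf("%.3f", grid$pearson_r), "-")),
    "",
    sprintf("best: %s / %s (r = %.3f)", grid$combination[b], grid$family[b],
            grid$pearson_r[b]),
    "",
    "## Actual vs predicted (best model)", "",
    "| region | actual | predicted |",
    "|---|---|---|",
    sprintf("| %s | %.2f | %.2f |", best_fit$predictions$region,
            best_fit$predictions$actual, best_fit$predictions$predicted))
}
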
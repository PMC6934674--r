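# Full analysis orchestration: validation -> exclusions -> HWI strata ->
# six networks + metrics -> estimated forest networks -> Spearman validation
# -> permutation regression -> randomization comparisons -> clustering ->
# class summaries.

#' Pipeline configuration
#'
#' @param n_subsamples monthly-matched forest samples for the estimated
#'   networks (default 100).
#' @param n_resamples simulated difference sets per randomization test
#'   (default 10000).
#' @param max_iter permutation cap for the regression (default 5000).
#' @param rand_mode randomization null: \code{"sign_flip"} (default) or
#'   \code{"centered_bootstrap"}.
#' @param compare_to forest network used in the road comparisons:
#'   \code{"estimated"} (default; the sampling-effort-matched choice) or
#'   \code{"comprehensive"}.
#' @param estimated build the estimated forest networks (default TRUE; when
#'   FALSE only four networks are built and comparisons are skipped).
#' @param weighted use HWI weights in nodal metrics (default TRUE).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_subsamples = 100, n_resamples = 10000,
                            max_iter = 5000,
                            rand_mode = c("sign_flip", "centered_bootstrap"),
                            compare_to = c("estimated", "comprehensive"),
                            estimated = TRUE, weighted = TRUE, seed = 1) {
  structure(list(n_subsamples = n_subsamples, n_resamples = n_resamples,
                 max_iter = max_iter, rand_mode = match.arg(rand_mode),
                 compare_to = match.arg(compare_to), estimated = estimated,
                 weighted = weighted, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Builds the six social networks (road / comprehensive forest / estimated
#' forest, each for proximity and affiliative data), their metric tables and
#' clusterings, the Spearman validation of estimated against comprehensive
#' forest metrics, the permutation regression of road presence on
#' life-history and forest-proximity network predictors, the eight
#' randomization comparisons of road vs forest metrics (4 nodal metrics x 2
#' data types), and the age-sex class summaries. The pipeline is a pure
#' function of (inputs, config).
#'
#' @param scans,interactions,roster validated collections (pre-exclusion).
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{result_bundle}.
#' @export
run_pipeline <- function(scans, interactions, roster,
                         config = pipeline_config()) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[socioscan] %-22s %6.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  stage("validate", {
    validate_roster(roster)
    validate_scans(scans, roster)
    validate_interactions(interactions, roster)
  })
  excl <- stage("exclusions", apply_exclusions(scans, interactions, roster))
  ascans <- excl$scans; ainter <- excl$interactions; aroster <- excl$roster

  matrices <- stage("hwi", {
    out <- list()
    for (ctx in c("road", "forest")) {
      sight <- tally_sightings(ascans, aroster, ctx)
      out[[paste0(ctx, "_proximity")]] <-
        hwi(joint_counts(ascans, aroster, ctx, "proximity"), sight)
      out[[paste0(ctx, "_affiliative")]] <-
        hwi(joint_counts(ainter, aroster, ctx, "affiliative"), sight)
    }
    out
  })

  if (config$estimated) {
    plan <- stage("subsample_plan",
                  subsample_plan(ascans, config$n_subsamples, config$seed))
    samples <- monthly_matched_subsamples(plan)
    matrices$estimated_forest_proximity <- stage("estimated_proximity",
      estimated_network(samples, ascans, aroster, "proximity"))
    matrices$estimated_forest_affiliative <- stage("estimated_affiliative",
      estimated_network(samples, ascans, aroster, "affiliative",
                        interactions = ainter))
  } else {
    warning("estimated networks disabled: road-vs-forest comparisons skipped")
    plan <- NULL
  }

  networks <- stage("networks", lapply(matrices, build_network))
  metric_tables <- stage("metrics", {
    out <- list()
    for (tag in names(networks))
      out[[tag]] <- metric_table(networks[[tag]], tag,
                                 weighted = config$weighted)
    out
  })

  spearman <- NULL
  if (config$estimated) {
    spearman <- stage("spearman_validation", {
      rows <- list()
      for (dt in c("proximity", "affiliative")) {
        comp <- metric_tables[[paste0("forest_", dt)]]
        est <- metric_tables[[paste0("estimated_forest_", dt)]]
        for (m in NETWORK_METRICS) {
          sv <- spearman_validate(comp, est, m)
          rows[[paste(dt, m)]] <- data.frame(data_type = dt, metric = m,
                                             rho = sv$rho, p = sv$p, n = sv$n,
                                             stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, c(rows, make.row.names = FALSE))
    })
  }

  regression <- stage("perm_regression", {
    props <- road_proportion(ascans, aroster)
    design <- build_design(aroster, metric_tables$forest_proximity,
                           matrices$forest_proximity, props)
    perm_lm(design, max_iter = config$max_iter, seed = config$seed + 1L)
  })

  comparisons <- NULL
  comparison_results <- list()
  diffs_list <- list()
  if (config$estimated || config$compare_to == "comprehensive") {
    forest_key <- if (config$compare_to == "estimated")
      "estimated_forest" else "forest"
    comparisons <- stage("randomization_tests", {
      rows <- list()
      k <- 0L
      for (dt in c("proximity", "affiliative")) {
        road_mt <- metric_tables[[paste0("road_", dt)]]
        forest_mt <- metric_tables[[paste0(forest_key, "_", dt)]]
        for (m in NETWORK_METRICS) {
          k <- k + 1L
          d <- metric_differences(road_mt, forest_mt, m)
          res <- randomization_test(d, n_resamples = config$n_resamples,
                                    mode = config$rand_mode,
                                    seed = config$seed + 100L + k)
          key <- paste(dt, m, sep = "_")
          diffs_list[[key]] <- d
          comparison_results[[key]] <- res
          rows[[key]] <- data.frame(
            data_type = dt, metric = m, direction = res$direction,
            observed_mean_diff = res$observed_mean,
            observed_sd = res$observed_sd,
            null_mean = res$null_mean, null_sd = res$null_sd, p = res$p,
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, c(rows, make.row.names = FALSE))
    })
  }

  class_summaries <- stage("class_summaries", {
    counts <- neighbour_counts(ascans, aroster)
    out <- list(neighbour_summary = neighbour_summary(counts),
                risk_perception = risk_perception_tests(counts))
    if (length(diffs_list) > 0) {
      rows <- lapply(names(diffs_list), function(key) {
        cd <- class_metric_differences(diffs_list[[key]], aroster)
        cd$comparison <- key
        cd
      })
      out$class_metric_differences <- do.call(rbind, c(rows, make.row.names = FALSE))
    }
    out
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("socioscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    n_individuals_analysis = nrow(aroster),
    n_scans = length(unique(ascans$scan_id)),
    n_scan_records = nrow(ascans),
    n_interactions = nrow(ainter)
  )

  structure(list(networks = networks,
                 networks_matrices = matrices,
                 metric_tables = metric_tables,
                 spearman = spearman,
                 regression = regression,
                 comparisons = comparisons,
                 comparison_results = comparison_results,
                 differences = diffs_list,
                 class_summaries = class_summaries,
                 subsample_plan = plan,
                 roster = aroster,
                 manifest = manifest),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>\n")
  cat("  networks:", paste(names(x$networks), collapse = ", "), "\n")
  cat(sprintf("  %d individuals, %d scans, %d interaction records\n",
              x$manifest$n_individuals_analysis, x$manifest$n_scans,
              x$manifest$n_interactions))
  if (!is.null(x$comparisons))
    cat(sprintf("  %d randomization comparisons; regression adjusted R^2 = %.3f\n",
                nrow(x$comparisons), x$regression$adjusted_r2))
  invisible(x)
}

#' Write a result bundle to a directory
#'
#' Writes per-network edge lists and GraphML, tidy metric tables, the
#' Spearman validation table, the regression table, the comparison table, the
#' class summaries, and a JSON manifest.
#'
#' @param bundle a \code{result_bundle}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tag in names(bundle$networks)) {
    write_network_edgelist(bundle$networks[[tag]],
                           file.path(dir, paste0("network_", tag, ".csv")))
    write_graphml(bundle$networks[[tag]],
                  file.path(dir, paste0("network_", tag, ".graphml")))
    write_metric_table(bundle$metric_tables[[tag]],
                       file.path(dir, paste0("metrics_", tag, ".csv")))
  }
  if (!is.null(bundle$spearman))
    utils::write.csv(bundle$spearman, file.path(dir, "spearman_validation.csv"),
                     row.names = FALSE, quote = FALSE)
  write_perm_reg(bundle$regression, file.path(dir, "regression.csv"))
  if (!is.null(bundle$comparisons))
    utils::write.csv(bundle$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE, quote = FALSE)
  cs <- bundle$class_summaries
  utils::write.csv(cs$neighbour_summary, file.path(dir, "neighbour_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cs$risk_perception, file.path(dir, "risk_perception.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cs$class_metric_differences))
    utils::write.csv(cs$class_metric_differences,
                     file.path(dir, "class_metric_differences.csv"),
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
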
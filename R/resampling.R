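# Monthly-matched subsampling of forest scans, the estimated forest network,
# Spearman validation against the comprehensive network, and the
# randomization test on paired per-individual metric differences.

#' Plan monthly-matched forest subsamples
#'
#' The group's road time follows a monthly pattern, so each random sample of
#' forest scans contains, per month, exactly as many forest scans as road
#' scans were observed in that month.
#'
#' @param scans validated scan records.
#' @param n_samples number of random samples (default 100).
#' @param seed integer seed for the draws.
#' @return object of class \code{subsample_plan}: list with
#'   \code{per_month_quota} (named integer vector, road scans per month),
#'   \code{forest_pool} (list of sorted forest scan ids per month),
#'   \code{n_samples}, \code{seed}.
#' @export
subsample_plan <- function(scans, n_samples = 100, seed = 1) {
  ctx <- scan_contexts(scans)
  mon <- scan_months(scans)
  road_ids <- names(ctx)[ctx == "road"]
  forest_ids <- names(ctx)[ctx == "forest"]
  months <- sort(unique(mon))
  quota <- vapply(months, function(m) sum(mon[road_ids] == m), integer(1))
  pool <- lapply(months, function(m) {
    sort(as.integer(forest_ids[mon[forest_ids] == m]))
  })
  names(pool) <- months
  structure(list(per_month_quota = quota, forest_pool = pool,
                 n_samples = n_samples, seed = seed),
            class = "subsample_plan")
}

#' Draw monthly-matched random samples of forest scans
#'
#' Each sample draws, without replacement and independently per month, the
#' planned number of forest scan ids. Draws are seeded and invariant to input
#' row order (pools are sorted before sampling).
#'
#' @param plan a \code{subsample_plan}.
#' @return list of \code{n_samples} integer vectors of scan ids.
#' @export
monthly_matched_subsamples <- function(plan) {
  stopifnot(inherits(plan, "subsample_plan"))
  quota <- plan$per_month_quota
  pool <- plan$forest_pool
  avail <- lengths(pool)
  short <- names(quota)[quota > avail[names(quota)]]
  if (length(short) > 0)
    stop("monthly quota exceeds available forest scans in month(s): ",
         paste(short, collapse = ", "))
  set.seed(plan$seed)
  lapply(seq_len(plan$n_samples), function(s) {
    sort(unlist(lapply(names(quota), function(m) {
      k <- quota[[m]]
      if (k == 0) return(integer(0))
      p <- pool[[m]]
      p[sample.int(length(p), k)]
    }), use.names = FALSE))
  })
}

#' Estimated association matrix from repeated subsamples
#'
#' For each sample, sighting and joint counts are recomputed restricted to
#' the sample's scans and an HWI matrix formed; the estimated matrix is the
#' arithmetic mean of the per-sample HWI matrices.
#'
#' @param samples list of scan-id vectors from
#'   \code{\link{monthly_matched_subsamples}}.
#' @param scans scan records (sighting source; proximity source too).
#' @param roster analysis roster.
#' @param data_type \code{"proximity"} or \code{"affiliative"}.
#' @param interactions interaction records (required for affiliative).
#' @param context record-level context to count within (default "forest").
#' @return an \code{association_matrix} (mean HWI over samples).
#' @export
estimated_network <- function(samples, scans, roster,
                              data_type = c("proximity", "affiliative"),
                              interactions = NULL, context = "forest") {
  data_type <- match.arg(data_type)
  if (length(samples) == 0) stop("at least one sample is required")
  if (data_type == "affiliative" && is.null(interactions))
    stop("interaction records are required for the affiliative estimated network")
  ids <- roster$id
  n <- length(ids)
  acc <- matrix(0, n, n, dimnames = list(ids, ids))
  for (s in samples) {
    sub_scans <- scans[scans$scan_id %in% s, , drop = FALSE]
    sight <- tally_sightings(sub_scans, roster, context)
    src <- if (data_type == "proximity") sub_scans else
      interactions[interactions$scan_id %in% s, , drop = FALSE]
    jc <- joint_counts(src, roster, context, data_type)
    acc <- acc + hwi(jc, sight)$hwi
  }
  h <- acc / length(samples)
  structure(list(ids = ids, context = context, data_type = data_type,
                 directed = data_type == "affiliative", hwi = h),
            class = "association_matrix")
}

#' Spearman validation of metrics across two networks
#'
#' Rank correlation (average ranks on ties) of one metric between the
#' comprehensive and estimated networks over the same individuals. The
#' p-value is exact (permutation distribution) for n <= 9 with no ties, and
#' the t-approximation otherwise. A constant vector leaves rho undefined and
#' is flagged.
#'
#' @param metrics_a,metrics_b \code{metric_table}s (or data.frames with an
#'   \code{id} column) over the same node set.
#' @param metric metric name (see \code{NETWORK_METRICS}).
#' @return list with \code{rho}, \code{p}, \code{n}, \code{metric}.
#' @export
spearman_validate <- function(metrics_a, metrics_b, metric) {
  x <- metric_vector(metrics_a, metric)
  y <- metric_vector(metrics_b, metric)
  if (!setequal(names(x), names(y)))
    stop("metric tables cover different node sets")
  y <- y[names(x)]
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant metric vector: Spearman rho undefined for ", metric)
    return(list(rho = NA_real_, p = NA_real_, n = length(x), metric = metric))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- length(x) <= 9 && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x), metric = metric)
}

#' Per-individual metric differences between contexts
#'
#' d_i = (road value) - (estimated forest value); positive differences mean
#' the metric is greater along the road.
#'
#' @param road,est_forest \code{metric_table}s over the same node set.
#' @param metric metric name.
#' @return named numeric vector of differences.
#' @export
metric_differences <- function(road, est_forest, metric) {
  x <- metric_vector(road, metric)
  y <- metric_vector(est_forest, metric)
  if (!setequal(names(x), names(y)))
    stop("road and estimated forest tables cover different node sets")
  x - y[names(x)]
}

#' Randomization test on paired metric differences
#'
#' Tests whether the observed mean per-individual difference departs from a
#' null of no context effect. The default null ("sign_flip", the standard
#' paired randomization test) multiplies each difference by an independent
#' random sign and compares |mean*| to |mean_obs|; the Monte-Carlo p-value
#' carries the add-one correction p = (1 + #exceedances) / (1 + n_resamples),
#' so p > 0 always. The literal resampling variant ("centered_bootstrap")
#' resamples with replacement from the mean-centred differences. With
#' \code{exhaustive = TRUE} (sign_flip, n <= 20) all 2^n sign assignments are
#' enumerated and p is exact (the identity assignment counts, so p >= 2^-n).
#'
#' @param diffs numeric vector of per-individual differences (length >= 2).
#' @param n_resamples number of simulated difference sets (default 10000).
#' @param mode \code{"sign_flip"} (default) or \code{"centered_bootstrap"}.
#' @param seed integer seed (ignored when exhaustive).
#' @param exhaustive enumerate all sign assignments instead of sampling.
#' @return object of class \code{comparison_result}: list with
#'   \code{observed_mean}, \code{observed_sd}, \code{null_mean},
#'   \code{null_sd}, \code{p}, \code{direction}, \code{mode},
#'   \code{n_resamples}.
#' @export
randomization_test <- function(diffs, n_resamples = 10000,
                               mode = c("sign_flip", "centered_bootstrap"),
                               seed = NULL, exhaustive = FALSE) {
  mode <- match.arg(mode)
  n <- length(diffs)
  if (n < 2) stop("at least two differences are required")
  obs <- mean(diffs)
  tol <- 1e-12 * (1 + abs(obs))
  if (all(diffs == 0)) {
    warning("all differences are zero: p = 1")
    return(structure(list(observed_mean = 0, observed_sd = 0, null_mean = 0,
                          null_sd = 0, p = 1, direction = "none", mode = mode,
                          n_resamples = if (exhaustive) 2^n else n_resamples),
                     class = "comparison_result"))
  }
  if (exhaustive) {
    if (mode != "sign_flip")
      stop("exhaustive enumeration is defined for the sign_flip mode only")
    if (n > 20) stop("exhaustive enumeration limited to n <= 20")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_means <- drop(signs %*% diffs) / n
    p <- mean(abs(null_means) >= abs(obs) - tol)
    nres <- nrow(signs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    if (mode == "sign_flip") {
      flips <- matrix(sample(c(-1, 1), n * n_resamples, replace = TRUE),
                      nrow = n_resamples)
      null_means <- drop(flips %*% diffs) / n
    } else {
      centred <- diffs - obs
      idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                    nrow = n_resamples)
      null_means <- rowMeans(matrix(centred[idx], nrow = n_resamples))
    }
    p <- (1 + sum(abs(null_means) >= abs(obs) - tol)) / (1 + n_resamples)
    nres <- n_resamples
  }
  structure(list(observed_mean = obs,
                 observed_sd = stats::sd(diffs),
                 null_mean = mean(null_means),
                 null_sd = stats::sd(null_means),
                 p = p,
                 direction = if (obs > 0) "greater along road" else
                   if (obs < 0) "greater in forest" else "none",
                 mode = mode,
                 n_resamples = nres),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> observed mean diff %.4f +/- %.4f (%s)\n",
              x$observed_mean, x$observed_sd, x$direction))
  cat(sprintf("  null: %.4f +/- %.4f over %d resamples (%s); p = %.4g\n",
              x$null_mean, x$null_sd, x$n_resamples, x$mode, x$p))
  invisible(x)
}
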
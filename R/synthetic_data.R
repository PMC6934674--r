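# Synthetic scan-data generator with known ground truth.
#
# Emulates the sampling design the analysis assumes: a ~35-member macaque
# group observed by instantaneous scans over six months, ~20% of scans at a
# roadside context with a monthly pattern, proximity events driven by latent
# block-structured dyadic affinities, directed affiliative events thinned by
# the same affinities, and a planted sex effect on individual road presence.

#' Simulation configuration
#'
#' Defaults mirror the study conditions the analysis is designed for: age-sex
#' class counts 9/11/2/6/5 plus two infants (one adult male present for only
#' part of the study), 1,219 scans over the six months 2016-08 to 2017-01,
#' and a monthly road probability averaging 19.8%.
#'
#' @param class_counts named integer vector of individuals per age-sex class.
#' @param n_part_time number of adult males present for only part of the
#'   study (their records stop after \code{part_time_months} months).
#' @param part_time_months months of presence for part-time individuals.
#' @param scans_per_month named integer vector ("YYYY-MM" = scans).
#' @param p_road_by_month named numeric vector of group-level road
#'   probabilities per month.
#' @param affinity list with \code{within} and \code{between} block mean
#'   dyadic proximity rates, multiplicative lognormal spread \code{sigma},
#'   and \code{blocks} ("age" splits juveniles from adults/subadults).
#' @param road_model named numeric vector \code{b0}, \code{b_sex},
#'   \code{b_btw}: logit-scale coefficients of individual road-presence
#'   propensity (per road-context scan) on sex (male = 1) and z-scored
#'   planted betweenness.
#' @param interaction_rate scaling from dyadic affinity to the per-scan
#'   probability of a directed affiliative event.
#' @param detectability named numeric vector \code{road}, \code{forest}:
#'   probability an individual (on the road / in the forest) is recorded in a
#'   scan.
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the config.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(class_counts = c(adult_male = 9, adult_female = 11,
                                        subadult_male = 2, juvenile_male = 6,
                                        juvenile_female = 5, infant = 2),
                       n_part_time = 1,
                       part_time_months = 3,
                       scans_per_month = c("2016-08" = 204, "2016-09" = 203,
                                           "2016-10" = 203, "2016-11" = 203,
                                           "2016-12" = 203, "2017-01" = 203),
                       p_road_by_month = c("2016-08" = 0.16, "2016-09" = 0.18,
                                           "2016-10" = 0.21, "2016-11" = 0.24,
                                           "2016-12" = 0.22, "2017-01" = 0.18),
                       affinity = list(within = 0.12, between = 0.05,
                                       sigma = 0.4, blocks = "age"),
                       road_model = c(b0 = -0.5, b_sex = 0.95, b_btw = 0.3),
                       interaction_rate = 0.05,
                       detectability = c(road = 0.9, forest = 0.6),
                       seed = 42) {
  cfg <- list(class_counts = class_counts, n_part_time = n_part_time,
              part_time_months = part_time_months,
              scans_per_month = scans_per_month,
              p_road_by_month = p_road_by_month, affinity = affinity,
              road_model = road_model, interaction_rate = interaction_rate,
              detectability = detectability, seed = seed)
  if (!setequal(names(scans_per_month), names(p_road_by_month)))
    stop("scans_per_month and p_road_by_month must cover the same months")
  if (any(p_road_by_month < 0 | p_road_by_month > 1))
    stop("road probabilities must lie in [0, 1]")
  if (any(detectability < 0 | detectability > 1))
    stop("detectability must lie in [0, 1]")
  if (affinity$within < 0 || affinity$between < 0)
    stop("affinity rates must be non-negative")
  if (max(affinity$within, affinity$between) > 1)
    stop("infeasible config: block affinity rates must not exceed 1")
  if (interaction_rate < 0) stop("interaction_rate must be non-negative")
  structure(cfg, class = "sim_config")
}

sim_roster <- function(config) {
  cc <- config$class_counts
  mk <- function(prefix, k) if (k > 0) sprintf("%s%02d", prefix, seq_len(k)) else character(0)
  classes <- list(
    adult_male = c("adult", "male"), adult_female = c("adult", "female"),
    subadult_male = c("subadult", "male"), subadult_female = c("subadult", "female"),
    juvenile_male = c("juvenile", "male"), juvenile_female = c("juvenile", "female")
  )
  prefixes <- c(adult_male = "AM", adult_female = "AF", subadult_male = "SM",
                subadult_female = "SF", juvenile_male = "JM", juvenile_female = "JF")
  rows <- list()
  for (cl in names(cc)) {
    k <- cc[[cl]]
    if (k == 0) next
    if (cl == "infant") {
      sexes <- rep(c("female", "male"), length.out = k)
      rows[[cl]] <- data.frame(id = mk("IN", k), age_class = "infant",
                               sex = sexes, stringsAsFactors = FALSE)
    } else {
      rows[[cl]] <- data.frame(id = mk(prefixes[[cl]], k),
                               age_class = classes[[cl]][1],
                               sex = classes[[cl]][2], stringsAsFactors = FALSE)
    }
  }
  roster <- do.call(rbind, rows)
  rownames(roster) <- NULL
  roster$present_full_study <- TRUE
  # part-time adult males: the last n_part_time of them
  am <- which(roster$age_class == "adult" & roster$sex == "male")
  if (config$n_part_time > 0)
    roster$present_full_study[utils::tail(am, config$n_part_time)] <- FALSE
  roster
}

#' Generate a synthetic scan dataset
#'
#' Produces a roster, scan records, directed interaction records, and a
#' ground-truth list recording every planted parameter. For each scan the
#' group-level context is drawn by month; individuals are recorded with the
#' context-specific detectability (during road-context scans, an individual
#' is on the road with its logistic propensity and is recorded only there);
#' each co-recorded dyad is within 1 m with probability equal to its latent
#' affinity; directed affiliative events occur with probability
#' \code{interaction_rate * affinity} per direction.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{roster}, \code{scans}, \code{interactions},
#'   \code{truth}.
#' @export
generate_scan_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  roster <- sim_roster(config)
  n <- nrow(roster)
  ids <- roster$id

  # latent structure -----------------------------------------------------
  blocks <- ifelse(roster$age_class == "juvenile", 2L, 1L)
  blocks[roster$age_class == "infant"] <- NA_integer_
  base <- matrix(config$affinity$between, n, n, dimnames = list(ids, ids))
  same <- outer(blocks, blocks, function(a, b) !is.na(a) & !is.na(b) & a == b)
  base[same] <- config$affinity$within
  noise <- matrix(0, n, n)
  noise[upper.tri(noise)] <- stats::rnorm(n * (n - 1) / 2, 0, config$affinity$sigma)
  noise <- noise + t(noise)
  aff <- pmin(base * exp(noise), 1)
  diag(aff) <- 0
  dimnames(aff) <- list(ids, ids)

  # planted betweenness (z-scored) drives part of road propensity --------
  analyzable <- roster$age_class != "infant" & roster$present_full_study
  g <- igraph::graph_from_adjacency_matrix(aff[analyzable, analyzable],
                                           mode = "undirected", weighted = TRUE)
  btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  z <- if (stats::sd(btw) > 0) (btw - mean(btw)) / stats::sd(btw) else btw * 0
  z_btw <- rep(0, n)
  z_btw[analyzable] <- z
  rm_ <- config$road_model
  p_road_ind <- stats::plogis(rm_[["b0"]] + rm_[["b_sex"]] * (roster$sex == "male") +
                                rm_[["b_btw"]] * z_btw)

  # scan skeleton --------------------------------------------------------
  months <- names(config$scans_per_month)
  S <- sum(config$scans_per_month)
  scan_month <- rep(months, config$scans_per_month)
  within_idx <- sequence(config$scans_per_month)
  day <- pmin((within_idx - 1L) %/% 12L + 1L, 28L)
  slot <- (within_idx - 1L) %% 12L
  date <- as.Date(paste0(scan_month, "-", sprintf("%02d", day)))
  period <- ifelse(slot < 6L, "morning", "afternoon")
  road_scan <- stats::runif(S) < config$p_road_by_month[scan_month]

  # detection ------------------------------------------------------------
  d <- config$detectability
  P <- matrix(rep(ifelse(road_scan, 1, 0), n), S, n)
  P <- P * rep(p_road_ind * d[["road"]], each = S) +
    matrix(rep(ifelse(road_scan, 0, d[["forest"]]), n), S, n)
  part_time <- which(!roster$present_full_study)
  if (length(part_time) > 0) {
    gone <- !(scan_month %in% months[seq_len(min(config$part_time_months,
                                                 length(months)))])
    P[gone, part_time] <- 0
  }
  M <- matrix(stats::runif(S * n), S, n) < P

  # scan records ----------------------------------------------------------
  rec <- which(M, arr.ind = TRUE)
  rec <- rec[order(rec[, 1], rec[, 2]), , drop = FALSE]
  rec_scan <- rec[, 1]
  rec_ind <- rec[, 2]
  state_probs <- c(rest = 0.25, feeding = 0.15, foraging = 0.15,
                   locomote = 0.15, grooming = 0.08, affiliative = 0.05,
                   play = 0.05, following = 0.04, aggressive = 0.03,
                   sexual = 0.03, greeting = 0.02)
  states <- sample(names(state_probs), length(rec_scan), replace = TRUE,
                   prob = state_probs)

  # proximity co-occurrence ----------------------------------------------
  pair <- which(upper.tri(aff), arr.ind = TRUE)
  iv <- pair[, 1]; jv <- pair[, 2]
  aff_d <- aff[pair]
  both <- M[, iv, drop = FALSE] & M[, jv, drop = FALSE]
  co <- both & (matrix(stats::runif(S * length(iv)), S) <
                  matrix(aff_d, S, length(iv), byrow = TRUE))
  ed <- which(co, arr.ind = TRUE)
  e_scan <- ed[, 1]; e_i <- iv[ed[, 2]]; e_j <- jv[ed[, 2]]
  nb_key <- c(paste(e_scan, e_i), paste(e_scan, e_j))
  nb_val <- c(ids[e_j], ids[e_i])
  nb_map <- split(nb_val, nb_key)
  rec_key <- paste(rec_scan, rec_ind)
  neighbours <- nb_map[rec_key]
  neighbours[vapply(neighbours, is.null, logical(1))] <- list(character(0))
  neighbours <- lapply(neighbours, function(x) sort(unname(x)))

  scans <- data.frame(scan_id = rec_scan, date = date[rec_scan],
                      period = period[rec_scan],
                      individual_id = ids[rec_ind],
                      context = ifelse(road_scan[rec_scan], "road", "forest"),
                      state = states, stringsAsFactors = FALSE)
  scans$neighbours <- unname(neighbours)

  # directed affiliative events ------------------------------------------
  p_int <- pmin(1, config$interaction_rate * aff_d)
  Pint <- matrix(p_int, S, length(iv), byrow = TRUE)
  ev_fwd <- both & (matrix(stats::runif(S * length(iv)), S) < Pint)
  ev_rev <- both & (matrix(stats::runif(S * length(iv)), S) < Pint)
  f_id <- which(ev_fwd, arr.ind = TRUE)
  r_id <- which(ev_rev, arr.ind = TRUE)
  interactions <- data.frame(
    scan_id = c(f_id[, 1], r_id[, 1]),
    actor = c(ids[iv[f_id[, 2]]], ids[jv[r_id[, 2]]]),
    recipient = c(ids[jv[f_id[, 2]]], ids[iv[r_id[, 2]]]),
    stringsAsFactors = FALSE
  )
  interactions$context <- ifelse(road_scan[interactions$scan_id], "road", "forest")
  interactions <- interactions[order(interactions$scan_id, interactions$actor,
                                     interactions$recipient), , drop = FALSE]
  rownames(interactions) <- NULL

  fr <- sum(config$scans_per_month * config$p_road_by_month[months]) /
    sum(config$scans_per_month)
  exp_prop <- 100 * (fr * p_road_ind * d[["road"]]) /
    (fr * p_road_ind * d[["road"]] + (1 - fr) * d[["forest"]])
  males <- analyzable & roster$sex == "male"
  females <- analyzable & roster$sex == "female"
  truth <- list(
    seed = config$seed,
    road_model = as.list(config$road_model),
    p_road_by_month = as.list(config$p_road_by_month),
    expected_road_scan_fraction = fr,
    detectability = as.list(config$detectability),
    affinity_params = config$affinity[c("within", "between", "sigma")],
    blocks = stats::setNames(as.list(blocks), ids),
    affinity = aff,
    z_betweenness = stats::setNames(as.list(z_btw), ids),
    expected_road_proportion_pct = stats::setNames(as.list(exp_prop), ids),
    expected_sex_gap_pp = mean(exp_prop[males]) - mean(exp_prop[females])
  )
  list(roster = roster, scans = scans, interactions = interactions,
       truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits roster.csv, scans.csv, interactions.csv and truth.json into a
#' directory; byte-identical across runs for a fixed config.
#'
#' @param sim list from \code{\link{generate_scan_data}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_roster(sim$roster, file.path(dir, "roster.csv"))
  write_scans(sim$scans, file.path(dir, "scans.csv"))
  write_interactions(sim$interactions, file.path(dir, "interactions.csv"))
  truth <- sim$truth
  truth$affinity <- NULL  # matrix kept in-memory; JSON stores parameters
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Check pipeline results against planted ground truth
#'
#' Reports sign agreement and significance for the planted sex effect,
#' cluster-recovery agreement (adjusted Rand index between planted blocks and
#' the walktrap partition of the forest proximity network), and the Spearman
#' correlation between planted dyadic affinity and estimated forest-proximity
#' HWI.
#'
#' @param bundle a \code{result_bundle} from \code{\link{run_pipeline}}.
#' @param truth ground-truth list from \code{\link{generate_scan_data}}.
#' @return list of class \code{recovery_report}.
#' @export
truth_check <- function(bundle, truth) {
  if (is.null(truth)) stop("missing ground truth")
  reg <- bundle$regression$terms
  sex_row <- reg[reg$term == "sex", ]
  b_sex_true <- truth$road_model$b_sex
  sex_sign_ok <- if (b_sex_true == 0) NA else
    sign(sex_row$coefficient) == sign(b_sex_true)
  flags <- character(0)
  if (b_sex_true == 0 && sex_row$p > 0.05)
    flags <- c(flags, "no effect recovered")

  mt <- bundle$metric_tables$forest_proximity
  ids <- mt$nodes$id
  planted <- unlist(truth$blocks[ids])
  recovered <- mt$membership[ids]
  ari <- if (length(unique(planted)) < 2 || length(unique(recovered)) < 2)
    NA_real_
  else igraph::compare(as.integer(factor(planted)),
                       as.integer(factor(recovered)), method = "adjusted.rand")

  rho <- NA_real_
  if (!is.null(truth$affinity)) {
    h <- bundle$networks_matrices$forest_proximity$hwi[ids, ids]
    a <- truth$affinity[ids, ids]
    lt <- lower.tri(h)
    rho <- stats::cor(a[lt], h[lt], method = "spearman")
  }
  structure(list(sex_coefficient = sex_row$coefficient,
                 sex_p = sex_row$p,
                 sex_sign_agrees = sex_sign_ok,
                 planted_sex_effect = b_sex_true,
                 cluster_agreement_ari = ari,
                 affinity_hwi_spearman = rho,
                 flags = flags),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  sex coefficient %.3f (p = %.4g), sign agrees: %s\n",
              x$sex_coefficient, x$sex_p, format(x$sex_sign_agrees)))
  cat(sprintf("  cluster ARI: %s; affinity~HWI Spearman: %s\n",
              format(signif(x$cluster_agreement_ari, 3)),
              format(signif(x$affinity_hwi_spearman, 3))))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
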
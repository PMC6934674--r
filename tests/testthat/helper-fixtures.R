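# Shared fixtures and independent oracles for the test suite.

# Build scan records in code (recycles scalar arguments).
make_scans <- function(scan_id, individual_id, context = "forest",
                       neighbours = list(character(0)),
                       date = as.Date("2016-08-01"), period = "morning",
                       state = "rest") {
  k <- max(length(scan_id), length(individual_id))
  df <- data.frame(scan_id = rep_len(as.integer(scan_id), k),
                   date = rep_len(date, k),
                   period = rep_len(period, k),
                   individual_id = rep_len(individual_id, k),
                   context = rep_len(context, k),
                   state = rep_len(state, k),
                   stringsAsFactors = FALSE)
  df$neighbours <- rep_len(neighbours, k)
  df
}

make_roster <- function(ids, age_class = "adult", sex = "female",
                        present = TRUE) {
  data.frame(id = ids,
             age_class = rep_len(age_class, length(ids)),
             sex = rep_len(sex, length(ids)),
             present_full_study = rep_len(present, length(ids)),
             stringsAsFactors = FALSE)
}

# Wrap a plain matrix as an association_matrix object.
make_assoc <- function(m, directed = FALSE, context = "forest",
                       data_type = if (directed) "affiliative" else "proximity") {
  ids <- rownames(m)
  structure(list(ids = ids, context = context, data_type = data_type,
                 directed = directed, hwi = m),
            class = "association_matrix")
}

# Small simulated dataset for fast tests: three months, 80 scans each.
small_sim <- function(seed = 11, ...) {
  cfg <- sim_config(
    scans_per_month = c("2016-08" = 80, "2016-09" = 80, "2016-10" = 80),
    p_road_by_month = c("2016-08" = 0.2, "2016-09" = 0.2, "2016-10" = 0.2),
    seed = seed, ...)
  generate_scan_data(cfg)
}

small_pipeline_config <- function(seed = 3) {
  pipeline_config(n_subsamples = 20, n_resamples = 2000, max_iter = 1000,
                  seed = seed)
}

# Brute-force HWI recount straight from raw records (independent of the
# tabulation in joint_counts/hwi).
oracle_hwi <- function(scans, ids, ctx) {
  sub <- scans[scans$context == ctx, , drop = FALSE]
  n_of <- function(i) length(unique(sub$scan_id[sub$individual_id == i]))
  H <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in ids) for (b in ids) {
    if (a >= b) next
    joint <- 0
    for (s in unique(sub$scan_id)) {
      rows <- sub[sub$scan_id == s, , drop = FALSE]
      a_lists_b <- any(rows$individual_id == a &
                         vapply(rows$neighbours, function(nb) b %in% nb, logical(1)))
      b_lists_a <- any(rows$individual_id == b &
                         vapply(rows$neighbours, function(nb) a %in% nb, logical(1)))
      if (a_lists_b || b_lists_a) joint <- joint + 1
    }
    denom <- n_of(a) + n_of(b)
    H[a, b] <- H[b, a] <- if (denom > 0) 2 * joint / denom else 0
  }
  H
}

# Random tiny scan dataset for property tests.
random_tiny_scans <- function(n_ids = 5, n_scans = 15) {
  ids <- LETTERS[seq_len(n_ids)]
  rows <- list()
  for (s in seq_len(n_scans)) {
    present <- ids[runif(n_ids) < 0.7]
    for (i in present) {
      others <- setdiff(present, i)
      nb <- others[runif(length(others)) < 0.3]
      rows[[length(rows) + 1]] <- make_scans(s, i,
        context = sample(c("road", "forest"), 1), neighbours = list(nb))
    }
  }
  do.call(rbind, rows)
}

# Exact two-tailed Mann-Whitney p by enumeration of all labelings.
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  labelings <- utils::combn(nx + ny, nx)
  us <- apply(labelings, 2, u_of)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}
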
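# Reading, validating and tallying behavioural scan records.
#
# File dialect: UTF-8 CSV, ISO-8601 dates, neighbour ids ";"-separated within
# one cell. One row of scans.csv is one individual's record within one scan.

#' Read an individual roster
#'
#' The roster lists every group member with its age class, sex and whether it
#' was present for the full study period.
#'
#' @param path path to a CSV with columns \code{id}, \code{age_class},
#'   \code{sex}, \code{present_full_study}.
#' @return data.frame with one row per individual.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "age_class", "sex", "present_full_study")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("roster file is missing required column(s): ", paste(miss, collapse = ", "))
  df$present_full_study <- as.logical(df$present_full_study)
  validate_roster(df)
  df[need]
}

validate_roster <- function(roster) {
  if (anyDuplicated(roster$id))
    stop("duplicated roster id(s): ",
         paste(unique(roster$id[duplicated(roster$id)]), collapse = ", "))
  bad_age <- setdiff(unique(roster$age_class), AGE_CLASSES)
  if (length(bad_age) > 0)
    stop("unknown age_class value(s): ", paste(bad_age, collapse = ", "))
  bad_sex <- setdiff(unique(roster$sex), SEXES)
  if (length(bad_sex) > 0)
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "))
  if (anyNA(roster$present_full_study))
    stop("present_full_study must be TRUE/FALSE for every individual")
  invisible(roster)
}

#' Read scan records
#'
#' Each row is one individual's observation within one scan: its context
#' (road/forest), behavioural state, and the ids of all conspecifics recorded
#' within 1 m (";"-separated in the \code{neighbours} cell, empty for none).
#'
#' @param path path to scans.csv with columns \code{scan_id}, \code{date},
#'   \code{period}, \code{individual_id}, \code{context}, \code{state},
#'   \code{neighbours}.
#' @param roster roster data.frame from \code{\link{read_roster}}.
#' @return data.frame of validated scan records; \code{neighbours} is a
#'   list-column of character vectors.
#' @export
read_scans <- function(path, roster) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("scan_id", "date", "period", "individual_id", "context", "state",
            "neighbours")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("scan file is missing required column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  errs <- character(0)
  scan_id <- suppressWarnings(as.integer(df$scan_id))
  bad <- which(is.na(scan_id))
  if (length(bad) > 0)
    errs <- c(errs, sprintf("line %d: malformed scan_id '%s'", bad + 1L, df$scan_id[bad]))
  date <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(date))
  if (length(bad) > 0)
    errs <- c(errs, sprintf("line %d: malformed date '%s'", bad + 1L, df$date[bad]))
  for (col in c("period", "context", "state")) {
    vocab <- switch(col, period = PERIODS, context = CONTEXTS, state = STATES)
    bad <- which(!(df[[col]] %in% vocab))
    if (length(bad) > 0)
      errs <- c(errs, sprintf("line %d: invalid %s '%s'", bad + 1L, col, df[[col]][bad]))
  }
  if (length(errs) > 0)
    stop("scan file failed row-level validation:\n", paste(errs, collapse = "\n"))
  scans <- data.frame(scan_id = scan_id, date = date, period = df$period,
                      individual_id = df$individual_id, context = df$context,
                      state = df$state, stringsAsFactors = FALSE)
  scans$neighbours <- lapply(df$neighbours, function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
  })
  validate_scans(scans, roster)
  scans
}

validate_scans <- function(scans, roster) {
  errs <- character(0)
  unknown <- setdiff(scans$individual_id, roster$id)
  if (length(unknown) > 0)
    errs <- c(errs, paste("unknown individual id(s):", paste(sort(unknown), collapse = ", ")))
  nb_unknown <- setdiff(unique(unlist(scans$neighbours)), roster$id)
  if (length(nb_unknown) > 0)
    errs <- c(errs, paste("unknown neighbour id(s):", paste(sort(nb_unknown), collapse = ", ")))
  self <- mapply(function(i, nb) i %in% nb, scans$individual_id, scans$neighbours)
  if (any(self))
    errs <- c(errs, paste("individual listed as its own neighbour in scan(s):",
                          paste(unique(scans$scan_id[self]), collapse = ", ")))
  key <- paste(scans$scan_id, scans$individual_id)
  if (anyDuplicated(key))
    errs <- c(errs, paste("duplicated (scan_id, individual) record(s):",
                          paste(unique(key[duplicated(key)]), collapse = "; ")))
  if (length(errs) > 0)
    stop("scan records failed validation:\n", paste(errs, collapse = "\n"))
  invisible(scans)
}

#' Read directed affiliative interaction records
#'
#' @param path path to interactions.csv with columns \code{scan_id},
#'   \code{actor}, \code{recipient}, \code{context}. Records are directed:
#'   A to B and B to A are distinct.
#' @param roster roster data.frame.
#' @return validated data.frame.
#' @export
read_interactions <- function(path, roster) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("scan_id", "actor", "recipient", "context")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("interaction file is missing required column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$scan_id <- suppressWarnings(as.integer(df$scan_id))
  validate_interactions(df, roster)
  df
}

validate_interactions <- function(interactions, roster) {
  errs <- character(0)
  if (anyNA(interactions$scan_id))
    errs <- c(errs, "malformed scan_id in interaction records")
  unknown <- setdiff(c(interactions$actor, interactions$recipient), roster$id)
  if (length(unknown) > 0)
    errs <- c(errs, paste("unknown individual id(s):", paste(sort(unknown), collapse = ", ")))
  if (any(interactions$actor == interactions$recipient))
    errs <- c(errs, "actor equals recipient in at least one interaction record")
  bad_ctx <- setdiff(unique(interactions$context), CONTEXTS)
  if (length(bad_ctx) > 0)
    errs <- c(errs, paste("invalid context value(s):", paste(bad_ctx, collapse = ", ")))
  if (length(errs) > 0)
    stop("interaction records failed validation:\n", paste(errs, collapse = "\n"))
  invisible(interactions)
}

#' Read a full scan dataset (roster + scans + interactions)
#'
#' @param scans_path,interactions_path,roster_path CSV paths.
#' @return list with elements \code{roster}, \code{scans}, \code{interactions}.
#' @export
read_scan_data <- function(scans_path, interactions_path, roster_path) {
  roster <- read_roster(roster_path)
  scans <- read_scans(scans_path, roster)
  interactions <- read_interactions(interactions_path, roster)
  list(roster = roster, scans = scans, interactions = interactions)
}

# Writers (round-trip partners of the readers) ---------------------------

#' Write scan records, interactions or a roster back to CSV
#'
#' Inverse of the readers: \code{read_scans(write_scans(x))} round-trips.
#'
#' @param scans,interactions,roster objects as returned by the readers.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_scans <- function(scans, path) {
  out <- scans
  out$date <- format(out$date, "%Y-%m-%d")
  out$neighbours <- vapply(scans$neighbours, paste, character(1), collapse = ";")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scans
#' @export
write_interactions <- function(interactions, path) {
  utils::write.csv(interactions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scans
#' @export
write_roster <- function(roster, path) {
  out <- roster
  out$present_full_study <- ifelse(roster$present_full_study, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON validation report for a scan dataset
#'
#' @param data list as returned by \code{\link{read_scan_data}} or
#'   \code{\link{generate_scan_data}}.
#' @param path output JSON path.
#' @return the report list, invisibly.
#' @export
write_validation_report <- function(data, path) {
  rep <- list(
    n_individuals = nrow(data$roster),
    n_scan_records = nrow(data$scans),
    n_scans = length(unique(data$scans$scan_id)),
    n_interactions = nrow(data$interactions),
    contexts = as.list(table(data$scans$context)),
    valid = TRUE
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(rep)
}

# Exclusions -------------------------------------------------------------

#' Restrict a dataset to the analysis roster
#'
#' Infants and individuals not present for the full study are excluded from
#' analysis. Their own records are dropped; where an excluded individual
#' appears only as someone's neighbour, it is pruned from the neighbour set so
#' the focal record (and hence the focal individual's sighting count, which
#' the HWI denominator needs) is preserved.
#'
#' @param scans,interactions,roster validated collections.
#' @return list with filtered \code{scans}, \code{interactions} and the
#'   analysis \code{roster}.
#' @export
apply_exclusions <- function(scans, interactions, roster) {
  keep <- roster$age_class != "infant" & roster$present_full_study
  aroster <- roster[keep, , drop = FALSE]
  rownames(aroster) <- NULL
  if (nrow(aroster) == 0)
    stop("analysis roster is empty after exclusions")
  ids <- aroster$id
  scans <- scans[scans$individual_id %in% ids, , drop = FALSE]
  scans$neighbours <- lapply(scans$neighbours, function(nb) nb[nb %in% ids])
  rownames(scans) <- NULL
  interactions <- interactions[interactions$actor %in% ids &
                                 interactions$recipient %in% ids, , drop = FALSE]
  rownames(interactions) <- NULL
  list(scans = scans, interactions = interactions, roster = aroster)
}

# Tallies ----------------------------------------------------------------

#' Tally per-individual sightings
#'
#' A sighting is one (scan, individual) record; an individual recorded with no
#' neighbours still counts as one sighting (the HWI denominator is total
#' sightings, not social sightings).
#'
#' @param scans scan records.
#' @param roster roster (defines the id set; unobserved individuals get 0).
#' @param context one of \code{"road"}, \code{"forest"}, \code{"all"}.
#' @return named non-negative integer vector over roster ids.
#' @export
tally_sightings <- function(scans, roster, context = c("all", "road", "forest")) {
  context <- match.arg(context)
  if (context != "all")
    scans <- scans[scans$context == context, , drop = FALSE]
  counts <- table(factor(scans$individual_id, levels = roster$id))
  out <- as.integer(counts)
  names(out) <- roster$id
  out
}

#' Group-level context of each scan
#'
#' A scan is classed "road" if it contains at least one road-context record
#' (the group was at the road), "forest" otherwise.
#'
#' @param scans scan records.
#' @return named character vector, one element per distinct scan_id.
#' @export
scan_contexts <- function(scans) {
  any_road <- tapply(scans$context == "road", scans$scan_id, any)
  out <- ifelse(any_road, "road", "forest")
  names(out) <- names(any_road)
  out
}

#' Month label ("YYYY-MM") of each scan
#'
#' @param scans scan records.
#' @return named character vector over distinct scan_ids.
#' @export
scan_months <- function(scans) {
  m <- tapply(format(scans$date, "%Y-%m"), scans$scan_id, function(x) x[[1]])
  out <- as.character(m)
  names(out) <- names(m)
  out
}
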
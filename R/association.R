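# Half-weight association indices per context and data type.
#
# HWI(A,B) = 2 * N / (n_A + n_B), where N is the number of joint-sighting
# scans of the dyad and n_A, n_B are total sightings, all counted within one
# context. Proximity indices are symmetric; affiliative indices use directed
# joint counts over the undirected denominator, so they need not be.

#' Per-dyad joint sighting counts
#'
#' Proximity: N(A,B) is the number of scans (in the requested context) where A
#' lists B within 1 m or B lists A; reciprocal sightings within a single scan
#' are counted once. Affiliative: N(A -> B) is the number of scans containing
#' at least one A -> B interaction record; repeats within one scan count once
#' and direction is preserved.
#'
#' @param records scan records (for \code{data_type = "proximity"}) or
#'   interaction records (for \code{"affiliative"}).
#' @param roster analysis roster (defines the node set).
#' @param context \code{"road"}, \code{"forest"} or \code{"all"}.
#' @param data_type \code{"proximity"} or \code{"affiliative"}.
#' @return object of class \code{dyad_counts}: list with \code{ids},
#'   \code{context}, \code{data_type} and integer matrix \code{counts}.
#' @export
joint_counts <- function(records, roster, context = c("all", "road", "forest"),
                         data_type = c("proximity", "affiliative")) {
  context <- match.arg(context)
  data_type <- match.arg(data_type)
  ids <- roster$id
  n <- length(ids)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (context != "all")
    records <- records[records$context == context, , drop = FALSE]
  if (data_type == "proximity") {
    nb_len <- lengths(records$neighbours)
    if (sum(nb_len) > 0) {
      a <- rep(records$individual_id, nb_len)
      b <- unlist(records$neighbours, use.names = FALSE)
      scan <- rep(records$scan_id, nb_len)
      keep <- a %in% ids & b %in% ids
      a <- a[keep]; b <- b[keep]; scan <- scan[keep]
      if (length(a) > 0) {
        lo <- pmin(a, b)
        hi <- pmax(a, b)
        key <- paste(scan, lo, hi)
        first <- !duplicated(key)
        lo <- lo[first]; hi <- hi[first]
        i <- match(lo, ids); j <- match(hi, ids)
        tab <- tabulate((i - 1L) * n + j, nbins = n * n)
        counts[] <- tab
        counts <- counts + t(counts)
      }
    }
  } else {
    keep <- records$actor %in% ids & records$recipient %in% ids
    records <- records[keep, , drop = FALSE]
    if (nrow(records) > 0) {
      key <- paste(records$scan_id, records$actor, records$recipient)
      first <- !duplicated(key)
      i <- match(records$actor[first], ids)
      j <- match(records$recipient[first], ids)
      # counts[i, j] = N(actor i -> recipient j); column-major linear index
      tab <- tabulate((j - 1L) * n + i, nbins = n * n)
      counts[] <- tab
    }
  }
  structure(list(ids = ids, context = context, data_type = data_type,
                 counts = counts),
            class = "dyad_counts")
}

#' Half-weight association index matrix
#'
#' @param dyads \code{dyad_counts} from \code{\link{joint_counts}}.
#' @param sightings named sighting counts from \code{\link{tally_sightings}},
#'   tallied in the same context as \code{dyads}.
#' @return object of class \code{association_matrix}: list with \code{ids},
#'   \code{context}, \code{data_type}, logical \code{directed} and numeric
#'   matrix \code{hwi} with zero diagonal and entries in [0, 1].
#' @export
hwi <- function(dyads, sightings) {
  stopifnot(inherits(dyads, "dyad_counts"))
  ids <- dyads$ids
  if (!all(ids %in% names(sightings)))
    stop("sightings must cover every roster id")
  nvec <- as.numeric(sightings[ids])
  if (any(nvec < 0) || any(dyads$counts < 0))
    stop("internal error: negative sighting or joint counts")
  denom <- outer(nvec, nvec, "+")
  h <- ifelse(denom > 0, 2 * dyads$counts / denom, 0)
  diag(h) <- 0
  if (any(h > 1 + 1e-12))
    warning("HWI values above 1: joint counts exceed min(n_A, n_B) for some dyads")
  dimnames(h) <- list(ids, ids)
  structure(list(ids = ids, context = dyads$context, data_type = dyads$data_type,
                 directed = dyads$data_type == "affiliative", hwi = h),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix> %s / %s, %d individuals, %s\n",
              x$context, x$data_type, length(x$ids),
              if (x$directed) "directed" else "undirected"))
  nz <- if (x$directed) sum(x$hwi > 0) else sum(x$hwi > 0) / 2
  cat(sprintf("  nonzero dyads: %d; mean nonzero HWI: %.3f\n",
              as.integer(nz), if (nz > 0) mean(x$hwi[x$hwi > 0]) else NA_real_))
  invisible(x)
}

#' Proportion of each individual's records along the road
#'
#' proportion(i) = n_i(road) / (n_i(road) + n_i(forest)), on the percentage
#' scale by default (the scale of the regression response). Individuals with
#' zero total sightings are dropped with a warning.
#'
#' @param scans scan records.
#' @param roster analysis roster.
#' @param percent report on the 0-100 scale (default) rather than 0-1.
#' @return named numeric vector.
#' @export
road_proportion <- function(scans, roster, percent = TRUE) {
  road <- tally_sightings(scans, roster, "road")
  forest <- tally_sightings(scans, roster, "forest")
  tot <- road + forest
  if (any(tot == 0)) {
    warning("individual(s) with zero sightings excluded from road proportions: ",
            paste(names(tot)[tot == 0], collapse = ", "))
    road <- road[tot > 0]
    tot <- tot[tot > 0]
  }
  p <- road / tot
  if (percent) p <- 100 * p
  p
}

#' Top associate of an individual
#'
#' The group member with which an individual has its greatest HWI, taken from
#' a symmetric (proximity) association matrix. Ties break to the
#' lexicographically smallest id; an all-zero row is an error (no associate is
#' definable for a fully isolated individual).
#'
#' @param matrix an undirected \code{association_matrix}.
#' @param id focal individual id; if \code{NULL}, a named vector of top
#'   associates for every individual is returned.
#' @return id of the top associate (or named vector of them).
#' @export
top_associate <- function(matrix, id = NULL) {
  stopifnot(inherits(matrix, "association_matrix"))
  if (matrix$directed)
    stop("top associates are defined on the undirected (proximity) matrix")
  if (is.null(id)) {
    out <- vapply(matrix$ids, function(i) top_associate(matrix, i), character(1))
    names(out) <- matrix$ids
    return(out)
  }
  if (!id %in% matrix$ids) stop("unknown id: ", id)
  row <- matrix$hwi[id, ]
  row <- row[names(row) != id]
  if (all(row == 0))
    stop("no top associate definable for isolated individual: ", id)
  best <- names(row)[row == max(row)]
  sort(best)[1]
}

# Writers ----------------------------------------------------------------

#' Write an association matrix as a square CSV or an edge list
#'
#' @param matrix an \code{association_matrix}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_association_matrix <- function(matrix, path) {
  utils::write.csv(as.data.frame(matrix$hwi), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_association_matrix
#' @export
write_edge_list <- function(matrix, path) {
  h <- matrix$hwi
  idx <- which(h > 0, arr.ind = TRUE)
  if (!matrix$directed) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  df <- data.frame(from = matrix$ids[idx[, 1]], to = matrix$ids[idx[, 2]],
                   weight = h[idx], stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
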
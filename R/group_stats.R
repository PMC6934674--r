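# Risk-perception analysis (nearest-neighbour counts by age-sex class and
# context, compared with Mann-Whitney U tests) and per-class summaries of
# metric differences across contexts.

#' Age-sex class labels
#'
#' @param roster roster data.frame.
#' @return character vector like "adult male", "juvenile female".
#' @export
age_sex_class <- function(roster) {
  paste(roster$age_class, roster$sex)
}

#' Per-record nearest-neighbour counts by age-sex class and context
#'
#' One count per scan record: the number of conspecifics recorded within 1 m
#' (after exclusion pruning). Records are treated as independent observations,
#' replicating the standard field procedure; the non-independence of records
#' from the same individual is a known caveat, not corrected here.
#'
#' @param scans scan records (post-exclusion).
#' @param roster analysis roster.
#' @return data.frame with columns \code{id}, \code{class}, \code{context},
#'   \code{count}.
#' @export
neighbour_counts <- function(scans, roster) {
  cls <- age_sex_class(roster)
  names(cls) <- roster$id
  data.frame(id = scans$individual_id,
             class = unname(cls[scans$individual_id]),
             context = scans$context,
             count = lengths(scans$neighbours),
             stringsAsFactors = FALSE)
}

#' Summarise neighbour counts per class and context
#'
#' @param counts data.frame from \code{\link{neighbour_counts}}.
#' @return data.frame with \code{class}, \code{context}, \code{n},
#'   \code{mean}, \code{sd}; class/context cells with no records are flagged
#'   with n = 0 and NA summaries.
#' @export
neighbour_summary <- function(counts) {
  cells <- expand.grid(class = sort(unique(counts$class)), context = CONTEXTS,
                       stringsAsFactors = FALSE)
  cells$n <- NA_integer_; cells$mean <- NA_real_; cells$sd <- NA_real_
  for (r in seq_len(nrow(cells))) {
    v <- counts$count[counts$class == cells$class[r] &
                        counts$context == cells$context[r]]
    cells$n[r] <- length(v)
    if (length(v) > 0) {
      cells$mean[r] <- mean(v)
      cells$sd[r] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  cells
}

#' Mann-Whitney U test
#'
#' U statistic with midrank handling of ties. The p-value is exact (by
#' enumeration of labelings) when the combined sample size is at most 12 and
#' there are no ties, and otherwise uses the normal approximation with tie
#' and continuity corrections.
#'
#' @param x,y non-empty numeric samples.
#' @return list with \code{U}, \code{p}, \code{exact}.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)
  )
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Road-vs-forest neighbour-count tests per age-sex class
#'
#' @param counts data.frame from \code{\link{neighbour_counts}}.
#' @return data.frame with one row per class: sample sizes, means, U and p.
#'   Classes lacking records in either context are returned with NA results.
#' @export
risk_perception_tests <- function(counts) {
  classes <- sort(unique(counts$class))
  out <- lapply(classes, function(cl) {
    road <- counts$count[counts$class == cl & counts$context == "road"]
    forest <- counts$count[counts$class == cl & counts$context == "forest"]
    if (length(road) == 0 || length(forest) == 0) {
      return(data.frame(class = cl, n_road = length(road),
                        n_forest = length(forest), mean_road = NA_real_,
                        mean_forest = NA_real_, U = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    mw <- mann_whitney_u(road, forest)
    data.frame(class = cl, n_road = length(road), n_forest = length(forest),
               mean_road = mean(road), mean_forest = mean(forest),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-class mean and sd of per-individual metric differences
#'
#' Groups a vector of road-minus-estimated-forest differences by age-sex
#' class. Single-member classes report sd = 0 with an explicit flag (the
#' deterministic convention for descriptive tables).
#'
#' @param diffs named difference vector from
#'   \code{\link{metric_differences}}.
#' @param roster analysis roster (classes for the named individuals).
#' @return data.frame with \code{class}, \code{n}, \code{mean}, \code{sd},
#'   \code{single_member}.
#' @export
class_metric_differences <- function(diffs, roster) {
  cls <- age_sex_class(roster)
  names(cls) <- roster$id
  if (!all(names(diffs) %in% roster$id))
    stop("differences contain ids absent from the roster")
  groups <- split(unname(diffs), unname(cls[names(diffs)]))
  absent <- setdiff(unique(cls), names(groups))
  if (length(absent) > 0)
    warning("age-sex class(es) absent from differences: ",
            paste(absent, collapse = ", "))
  out <- data.frame(
    class = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, function(v) if (length(v) > 1) stats::sd(v) else 0,
                numeric(1)),
    single_member = lengths(groups) == 1,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
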
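# Permutation-based linear regression of road presence on life-history and
# network predictors, with sequential stopping per term.
#
# The response (per-individual percentage of records along the road) is
# permuted while the predictor rows stay fixed; each term's two-tailed p is
# the exceedance rate of |b*_j| over |b_j|. A term stops early once its p
# estimate has converged (relative standard error rule), or at max_iter.

PREDICTORS <- c("age", "sex", "eigenvector", "betweenness",
                "assoc_eigenvector", "assoc_betweenness")

#' Build the regression design
#'
#' One row per analysis-roster individual. Binary codings: age 1 = adult
#' (subadults are coded as adults), 0 = non-adult, so the intercept represents
#' non-adults; sex 1 = male, 0 = female, so the intercept represents females.
#' Network covariates (eigenvector and betweenness centrality, own and top
#' associate's) come from the comprehensive forest proximity network.
#'
#' @param roster analysis roster.
#' @param metrics \code{metric_table} of the comprehensive forest proximity
#'   network.
#' @param assoc the comprehensive forest proximity \code{association_matrix}
#'   (used to resolve top associates).
#' @param proportions named road proportions (percent scale) from
#'   \code{\link{road_proportion}}.
#' @return data.frame of class \code{regression_design} with columns
#'   \code{id}, \code{road_pct}, \code{age}, \code{sex}, \code{eigenvector},
#'   \code{betweenness}, \code{assoc_eigenvector}, \code{assoc_betweenness}.
#' @export
build_design <- function(roster, metrics, assoc, proportions) {
  ids <- roster$id
  missing_p <- setdiff(ids, names(proportions))
  if (length(missing_p) > 0)
    stop("no road proportion for individual(s): ", paste(missing_p, collapse = ", "))
  eig <- metric_vector(metrics, "eigenvector")
  btw <- metric_vector(metrics, "betweenness")
  if (!all(ids %in% names(eig)))
    stop("metric table does not cover the analysis roster")
  tops <- tryCatch(top_associate(assoc),
                   error = function(e) stop("unresolvable top associate: ",
                                            conditionMessage(e)))
  design <- data.frame(
    id = ids,
    road_pct = as.numeric(proportions[ids]),
    age = as.integer(roster$age_class %in% c("adult", "subadult")),
    sex = as.integer(roster$sex == "male"),
    eigenvector = as.numeric(eig[ids]),
    betweenness = as.numeric(btw[ids]),
    assoc_eigenvector = as.numeric(eig[tops[ids]]),
    assoc_betweenness = as.numeric(btw[tops[ids]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(design))
    stop("missing cells in regression design")
  class(design) <- c("regression_design", "data.frame")
  design
}

design_matrix <- function(design, predictors = PREDICTORS) {
  X <- cbind(`(Intercept)` = 1, as.matrix(design[predictors]))
  storage.mode(X) <- "double"
  X
}

#' Ordinary least-squares fit of the road-presence model
#'
#' @param design a \code{regression_design}.
#' @param predictors predictor column names (default all six).
#' @return list with named \code{coefficients}, \code{r_squared},
#'   \code{adjusted_r2}, \code{residuals}, \code{fitted}.
#' @export
ols_fit <- function(design, predictors = PREDICTORS) {
  X <- design_matrix(design, predictors)
  y <- design$road_pct
  n <- nrow(X); p <- ncol(X) - 1
  if (n <= p + 1) stop("need more observations than parameters")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-seq_len(qrX$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  b <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(coefficients = b, r_squared = r2, adjusted_r2 = adj,
       residuals = res, fitted = y - res)
}

#' Permutation-based linear regression with sequential stopping
#'
#' Reported coefficients are the plain OLS coefficients on the unpermuted
#' data. For each permutation the response is shuffled, the model refit, and
#' each term's exceedance count #\{|b*_j| >= |b_j|\} updated. A term stops
#' once \code{iterations >= min_iter} and the estimated standard error of its
#' p is below \code{ca} times p (the sequential rule of the
#' permutation-regression software family), or at \code{max_iter}; its
#' two-tailed p is (1 + count) / (1 + iterations). An omnibus p for the model
#' R-squared is computed from the same permutation stream. With
#' \code{exhaustive = TRUE} all n! permutations are enumerated (n <= 8) and p
#' = count / n! exactly (the identity permutation counts).
#'
#' @param design a \code{regression_design}.
#' @param max_iter maximum permutations per term (default 5000).
#' @param min_iter minimum permutations before a term may stop (default 50).
#' @param ca relative standard error threshold for stopping (default 0.1).
#' @param seed integer seed.
#' @param predictors predictor columns (default all six).
#' @param type \code{"raw"} permutes the raw response (default);
#'   \code{"freedman_lane"} permutes residuals of the term-reduced model.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return object of class \code{perm_reg_result}: list with data.frame
#'   \code{terms} (term, coefficient, iterations, p), \code{adjusted_r2},
#'   \code{r_squared}, \code{omnibus_p}, \code{max_iter}.
#' @export
perm_lm <- function(design, max_iter = 5000, min_iter = 50, ca = 0.1,
                    seed = NULL, predictors = PREDICTORS, type = c("raw", "freedman_lane"),
                    exhaustive = FALSE) {
  type <- match.arg(type)
  if (!exhaustive && max_iter < min_iter)
    stop("max_iter must be at least the minimum iteration count (", min_iter, ")")
  X <- design_matrix(design, predictors)
  y <- design$road_pct
  n <- nrow(X)
  fit <- ols_fit(design, predictors)
  b_obs <- fit$coefficients
  r2_obs <- fit$r_squared
  qrX <- qr(X)
  tss <- sum((y - mean(y))^2)
  nterm <- length(b_obs)
  tol <- 1e-12 * (1 + abs(b_obs))
  r2tol <- 1e-12

  if (type == "freedman_lane" && !exhaustive)
    return(perm_lm_freedman_lane(design, X, y, b_obs, fit, max_iter, min_iter,
                                 ca, seed, predictors))

  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    P <- all_permutations(n)
    counts <- numeric(nterm)
    r2_count <- 0
    for (k in seq_len(nrow(P))) {
      yk <- y[P[k, ]]
      bk <- qr.coef(qrX, yk)
      counts <- counts + (abs(bk) >= abs(b_obs) - tol)
      rk <- qr.resid(qrX, yk)
      r2k <- if (tss > 0) 1 - sum(rk^2) / tss else 0
      r2_count <- r2_count + (r2k >= r2_obs - r2tol)
    }
    terms <- data.frame(term = names(b_obs), coefficient = unname(b_obs),
                        iterations = nrow(P), p = counts / nrow(P),
                        stringsAsFactors = FALSE)
    return(structure(list(terms = terms, adjusted_r2 = fit$adjusted_r2,
                          r_squared = r2_obs, omnibus_p = r2_count / nrow(P),
                          max_iter = nrow(P)),
                     class = "perm_reg_result"))
  }

  if (!is.null(seed)) set.seed(seed)
  counts <- numeric(nterm)
  iters <- integer(nterm)
  active <- rep(TRUE, nterm)
  r2_count <- 0; r2_iters <- 0L; r2_active <- TRUE
  block <- 128L
  total <- 0L
  while ((any(active) || r2_active) && total < max_iter) {
    nb <- min(block, max_iter - total)
    Y <- vapply(seq_len(nb), function(k) y[sample.int(n)], numeric(n))
    B <- qr.coef(qrX, Y)                      # nterm x nb
    R2 <- if (tss > 0) 1 - colSums(qr.resid(qrX, Y)^2) / tss else numeric(nb)
    exceed <- abs(B) >= (abs(b_obs) - tol)    # recycled by column
    for (k in seq_len(nb)) {
      total <- total + 1L
      if (any(active)) {
        iters[active] <- iters[active] + 1L
        counts[active] <- counts[active] + exceed[active, k]
        phat <- (1 + counts) / (1 + iters)
        se <- sqrt(phat * (1 - phat) / pmax(iters, 1))
        done <- active & iters >= min_iter & se < ca * phat
        active[done] <- FALSE
      }
      if (r2_active) {
        r2_iters <- r2_iters + 1L
        r2_count <- r2_count + (R2[k] >= r2_obs - r2tol)
        phat <- (1 + r2_count) / (1 + r2_iters)
        se <- sqrt(phat * (1 - phat) / r2_iters)
        if (r2_iters >= min_iter && se < ca * phat) r2_active <- FALSE
      }
      if (!any(active) && !r2_active) break
    }
  }
  terms <- data.frame(term = names(b_obs), coefficient = unname(b_obs),
                      iterations = iters, p = (1 + counts) / (1 + iters),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, adjusted_r2 = fit$adjusted_r2,
                 r_squared = r2_obs,
                 omnibus_p = (1 + r2_count) / (1 + r2_iters),
                 max_iter = max_iter),
            class = "perm_reg_result")
}

# Freedman-Lane variant: for each term, permute residuals of the reduced
# model (term removed), add back reduced fitted values, refit the full model.
perm_lm_freedman_lane <- function(design, X, y, b_obs, fit, max_iter, min_iter,
                                  ca, seed, predictors) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  qrX <- qr(X)
  nterm <- length(b_obs)
  tol <- 1e-12 * (1 + abs(b_obs))
  iters <- integer(nterm); counts <- numeric(nterm)
  for (j in seq_len(nterm)) {
    Xr <- X[, -j, drop = FALSE]
    qr_r <- qr(Xr)
    fit_r <- y - qr.resid(qr_r, y)
    res_r <- qr.resid(qr_r, y)
    it <- 0L; cnt <- 0
    repeat {
      it <- it + 1L
      ystar <- fit_r + res_r[sample.int(n)]
      bstar <- qr.coef(qrX, ystar)
      cnt <- cnt + (abs(bstar[j]) >= abs(b_obs[j]) - tol[j])
      phat <- (1 + cnt) / (1 + it)
      se <- sqrt(phat * (1 - phat) / it)
      if ((it >= min_iter && se < ca * phat) || it >= max_iter) break
    }
    iters[j] <- it; counts[j] <- cnt
  }
  terms <- data.frame(term = names(b_obs), coefficient = unname(b_obs),
                      iterations = iters, p = (1 + counts) / (1 + iters),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, adjusted_r2 = fit$adjusted_r2,
                 r_squared = fit$r_squared, omnibus_p = NA_real_,
                 max_iter = max_iter),
            class = "perm_reg_result")
}

#' Exact permutation regression by full enumeration
#'
#' Enumeration oracle for small designs: refits the model (via
#' \code{stats::lm.fit}, a route independent of \code{\link{perm_lm}}'s
#' fixed-QR refits) under every permutation of the response and reports exact
#' two-tailed p-values p = #\{|b*| >= |b|\} / n!.
#'
#' @param design a \code{regression_design} with n <= 8 rows.
#' @param predictors predictor columns.
#' @return a \code{perm_reg_result} with exact p-values.
#' @export
exact_perm_lm <- function(design, predictors = PREDICTORS) {
  X <- design_matrix(design, predictors)
  y <- design$road_pct
  n <- nrow(X)
  if (n > 8) stop("exact enumeration refused for n > 8 (", n, " rows)")
  fit <- ols_fit(design, predictors)
  b_obs <- fit$coefficients
  tol <- 1e-12 * (1 + abs(b_obs))
  tss <- sum((y - mean(y))^2)
  P <- all_permutations(n)
  counts <- numeric(length(b_obs))
  r2_count <- 0
  for (k in seq_len(nrow(P))) {
    f <- stats::lm.fit(X, y[P[k, ]])
    counts <- counts + (abs(f$coefficients) >= abs(b_obs) - tol)
    r2k <- if (tss > 0) 1 - sum(f$residuals^2) / tss else 0
    r2_count <- r2_count + (r2k >= fit$r_squared - 1e-12)
  }
  terms <- data.frame(term = names(b_obs), coefficient = unname(b_obs),
                      iterations = nrow(P), p = counts / nrow(P),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, adjusted_r2 = fit$adjusted_r2,
                 r_squared = fit$r_squared, omnibus_p = r2_count / nrow(P),
                 max_iter = nrow(P)),
            class = "perm_reg_result")
}

# All n! permutations of 1..n as a matrix (rows = permutations).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' @export
print.perm_reg_result <- function(x, ...) {
  cat("<perm_reg_result>\n")
  df <- x$terms
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  cat(sprintf("  adjusted R^2 = %.3f; omnibus p = %s\n", x$adjusted_r2,
              format(signif(x$omnibus_p, 3))))
  invisible(x)
}

#' Write a permutation-regression result as CSV
#'
#' Mirrors the (Variable, Coefficient, Iterations, p-value) layout with an
#' adjusted R-squared footer row.
#'
#' @param result a \code{perm_reg_result}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_perm_reg <- function(result, path) {
  df <- result$terms
  names(df) <- c("variable", "coefficient", "iterations", "p_value")
  footer <- data.frame(variable = "adjusted_r2",
                       coefficient = result$adjusted_r2,
                       iterations = NA_integer_, p_value = result$omnibus_p,
                       stringsAsFactors = FALSE)
  utils::write.csv(rbind(df, footer), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
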
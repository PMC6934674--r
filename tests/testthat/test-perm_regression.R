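# Design construction, OLS, permutation regression with sequential stopping.

toy_design <- function(n = 6, seed = 1) {
  set.seed(seed)
  d <- data.frame(id = paste0("i", seq_len(n)),
                  road_pct = runif(n, 5, 30),
                  age = rep_len(c(1L, 0L), n),
                  sex = rep_len(c(1L, 1L, 0L), n),
                  x = rnorm(n), stringsAsFactors = FALSE)
  class(d) <- c("regression_design", "data.frame")
  d
}

test_that("build_design codes age, sex and associate covariates correctly", {
  roster <- rbind(make_roster("AM1", "adult", "male"),
                  make_roster("SM1", "subadult", "male"),
                  make_roster("JF1", "juvenile", "female"),
                  make_roster("AF1", "adult", "female"))
  ids <- roster$id
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m["AM1", "SM1"] <- m["SM1", "AM1"] <- 0.8
  m["AM1", "JF1"] <- m["JF1", "AM1"] <- 0.3
  m["AF1", "AM1"] <- m["AM1", "AF1"] <- 0.5
  assoc <- make_assoc(m)
  mt <- metric_table(build_network(assoc), "forest_proximity")
  props <- c(AM1 = 20, SM1 = 25, JF1 = 10, AF1 = 12)
  design <- build_design(roster, mt, assoc, props)
  expect_equal(design$age, c(1L, 1L, 0L, 1L))     # subadult coded adult
  expect_equal(design$sex, c(1L, 1L, 0L, 0L))
  # every individual's top associate is AM1 (their greatest HWI), whose
  # eigenvector value is the group maximum (1 after max-normalisation)
  eig <- metric_vector(mt, "eigenvector")
  expect_equal(design$assoc_eigenvector[2:4], rep(unname(eig["AM1"]), 3))
  expect_equal(unname(eig["AM1"]), 1)
  expect_error(build_design(roster, mt, assoc, props[1:3]),
               "no road proportion")
})

test_that("ols_fit matches hand-computed normal equations", {
  # 3 points, single predictor: slope = Sxy/Sxx = 1.5, intercept = 7/6
  d <- data.frame(road_pct = c(1, 3, 4), x = c(0, 1, 2))
  fit <- ols_fit(d, predictors = "x")
  expect_equal(unname(fit$coefficients["x"]), 1.5, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 7 / 6,
               tolerance = 1e-12)
  lmref <- lm(road_pct ~ x, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(lmref)), tolerance = 1e-12)
})

test_that("exact linear responses and constant responses fit as expected", {
  set.seed(2)
  d <- data.frame(road_pct = 0, x = rnorm(10), z = rnorm(10))
  d$road_pct <- 2 + 3 * d$x
  fit <- ols_fit(d, predictors = c("x", "z"))
  expect_equal(unname(fit$coefficients["x"]), 3, tolerance = 1e-10)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-10)
  d$road_pct <- 5
  fit0 <- ols_fit(d, predictors = c("x", "z"))
  expect_equal(unname(fit0$coefficients[c("x", "z")]), c(0, 0),
               tolerance = 1e-10)
  expect_equal(fit0$r_squared, 0)
  # collinear columns named in the error
  d$x2 <- 2 * d$x
  expect_error(ols_fit(d, predictors = c("x", "x2")), "collinear.*x2")
})

test_that("exact enumeration p-values are multiples of 1/n! and degenerate cases work", {
  d <- data.frame(road_pct = c(3, 1, 8), x = c(0.2, -1, 0.9))
  class(d) <- c("regression_design", "data.frame")
  res <- exact_perm_lm(d, predictors = "x")
  expect_equal(res$terms$iterations, rep(6L, 2), ignore_attr = TRUE)
  expect_true(all(abs(res$terms$p * 6 - round(res$terms$p * 6)) < 1e-12))
  # constant response -> every permutation ties the observed statistic
  dc <- data.frame(road_pct = rep(2, 4), x = rnorm(4))
  expect_equal(exact_perm_lm(dc, predictors = "x")$terms$p, c(1, 1))
  expect_error(exact_perm_lm(toy_design(9), predictors = "x"), "n > 8")
})

test_that("perm_lm in exhaustive mode equals the independent enumeration oracle", {
  d <- toy_design(6, seed = 3)
  mine <- perm_lm(d, predictors = c("age", "sex", "x"), exhaustive = TRUE)
  oracle <- exact_perm_lm(d, predictors = c("age", "sex", "x"))
  expect_equal(mine$terms$p, oracle$terms$p, tolerance = 1e-12)
  expect_equal(mine$omnibus_p, oracle$omnibus_p, tolerance = 1e-12)
  expect_equal(mine$terms$coefficient, oracle$terms$coefficient,
               tolerance = 1e-12)
})

test_that("sampled permutation p-values agree with enumeration within Monte-Carlo error", {
  d <- toy_design(6, seed = 5)
  exact <- exact_perm_lm(d, predictors = c("sex", "x"))
  mc <- perm_lm(d, predictors = c("sex", "x"), max_iter = 20000, ca = 0,
                seed = 11)
  for (k in seq_len(nrow(exact$terms))) {
    p0 <- exact$terms$p[k]
    se <- sqrt(p0 * (1 - p0) / 20000)
    expect_lt(abs(mc$terms$p[k] - p0), 3 * se + 1e-3)
  }
})

test_that("slope p-values are invariant to affine rescaling of the response", {
  d <- toy_design(12, seed = 7)
  r1 <- perm_lm(d, predictors = c("age", "sex", "x"), max_iter = 500, seed = 4)
  d2 <- d
  d2$road_pct <- 3.7 * d$road_pct + 11
  r2 <- perm_lm(d2, predictors = c("age", "sex", "x"), max_iter = 500, seed = 4)
  slopes <- r1$terms$term != "(Intercept)"
  expect_equal(r1$terms$p[slopes], r2$terms$p[slopes], tolerance = 1e-12)
  expect_equal(r1$terms$iterations[slopes], r2$terms$iterations[slopes])
})

test_that("reported coefficients equal the OLS fit on unpermuted data", {
  d <- toy_design(10, seed = 9)
  res <- perm_lm(d, predictors = c("age", "sex", "x"), max_iter = 200, seed = 1)
  fit <- ols_fit(d, predictors = c("age", "sex", "x"))
  expect_equal(res$terms$coefficient, unname(fit$coefficients))
  expect_equal(res$adjusted_r2, fit$adjusted_r2)
})

test_that("a perfect predictor reaches the minimum attainable p", {
  set.seed(10)
  d <- data.frame(id = paste0("i", 1:10), road_pct = 0, x = rnorm(10),
                  z = rnorm(10), stringsAsFactors = FALSE)
  d$road_pct <- 10 + 4 * d$x
  class(d) <- c("regression_design", "data.frame")
  res <- perm_lm(d, predictors = c("x", "z"), max_iter = 400, seed = 2)
  row <- res$terms[res$terms$term == "x", ]
  expect_equal(row$p, 1 / (1 + row$iterations))
  expect_equal(row$iterations, 400)  # significant terms never converge early
})

test_that("sequential stopping obeys iteration bounds and configuration errors", {
  d <- toy_design(12, seed = 13)
  res <- perm_lm(d, predictors = c("age", "sex", "x"), max_iter = 300,
                 min_iter = 50, seed = 6)
  expect_true(all(res$terms$iterations >= 50))
  expect_true(all(res$terms$iterations <= 300))
  expect_true(all(res$terms$p > 0 & res$terms$p <= 1))
  expect_error(perm_lm(d, max_iter = 10), "at least the minimum")
})

test_that("the Freedman-Lane option runs and agrees roughly with raw permutation", {
  d <- toy_design(12, seed = 17)
  fl <- perm_lm(d, predictors = c("sex", "x"), max_iter = 400, seed = 3,
                type = "freedman_lane")
  raw <- perm_lm(d, predictors = c("sex", "x"), max_iter = 400, seed = 3)
  expect_equal(fl$terms$coefficient, raw$terms$coefficient)
  expect_true(all(fl$terms$p > 0 & fl$terms$p <= 1))
})
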
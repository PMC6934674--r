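# Monthly-matched subsampling, estimated networks, Spearman validation,
# randomization tests.

test_that("subsamples match the road monthly pattern exactly", {
  sim <- small_sim(seed = 17)
  excl <- apply_exclusions(sim$scans, sim$interactions, sim$roster)
  plan <- subsample_plan(excl$scans, n_samples = 10, seed = 5)
  samples <- monthly_matched_subsamples(plan)
  expect_length(samples, 10)
  mon <- scan_months(excl$scans)
  ctx <- scan_contexts(excl$scans)
  for (s in samples[1:3]) {
    expect_true(all(ctx[as.character(s)] == "forest"))
    drawn <- table(mon[as.character(s)])
    for (m in names(plan$per_month_quota)) {
      q <- plan$per_month_quota[[m]]
      got <- if (m %in% names(drawn)) drawn[[m]] else 0L
      expect_equal(got, q)
    }
    expect_equal(length(s), length(unique(s)))  # without replacement
  }
})

test_that("subsample draws are reproducible and row-order invariant", {
  sim <- small_sim(seed = 17)
  scans <- sim$scans
  plan1 <- subsample_plan(scans, n_samples = 4, seed = 9)
  shuffled <- scans[sample(nrow(scans)), ]
  plan2 <- subsample_plan(shuffled, n_samples = 4, seed = 9)
  expect_identical(monthly_matched_subsamples(plan1),
                   monthly_matched_subsamples(plan2))
})

test_that("an infeasible quota names the offending month", {
  sim <- small_sim(seed = 17)
  plan <- subsample_plan(sim$scans, n_samples = 2, seed = 1)
  plan$per_month_quota[["2016-09"]] <-
    length(plan$forest_pool[["2016-09"]]) + 1L
  expect_error(monthly_matched_subsamples(plan), "2016-09")
})

test_that("estimated network averages per-sample HWI matrices", {
  # sample 1 (scans 1-5): A,B together once -> HWI 0.2
  # sample 2 (scans 6-10): A,B together twice -> HWI 0.4
  roster <- make_roster(c("A", "B"))
  togas <- function(sid, together) {
    rbind(make_scans(sid, "A", neighbours = if (together) list("B") else list(character(0))),
          make_scans(sid, "B", neighbours = if (together) list("A") else list(character(0))))
  }
  scans <- do.call(rbind, c(lapply(1:10, function(s)
    togas(s, together = s %in% c(1, 6, 7)))))
  est <- estimated_network(list(1:5, 6:10), scans, roster, "proximity")
  expect_equal(est$hwi["A", "B"], 0.3)
  # identical samples -> equals the single-sample HWI
  est2 <- estimated_network(list(1:5, 1:5), scans, roster, "proximity")
  expect_equal(est2$hwi["A", "B"], 0.2)
  # dyad never co-observed -> 0
  scans0 <- do.call(rbind, lapply(1:4, function(s) togas(s, FALSE)))
  est0 <- estimated_network(list(1:2, 3:4), scans0, roster, "proximity")
  expect_equal(est0$hwi["A", "B"], 0)
})

test_that("quota covering every forest scan reproduces the comprehensive network", {
  sim <- small_sim(seed = 23)
  excl <- apply_exclusions(sim$scans, sim$interactions, sim$roster)
  plan <- subsample_plan(excl$scans, n_samples = 3, seed = 2)
  plan$per_month_quota <- lengths(plan$forest_pool)
  samples <- monthly_matched_subsamples(plan)
  full_pool <- sort(unlist(plan$forest_pool, use.names = FALSE))
  expect_true(all(vapply(samples, function(s) identical(s, full_pool),
                         logical(1))))
})

test_that("spearman validation handles perfect, reversed and tiny samples", {
  mk <- function(v) data.frame(id = names(v), degree = unname(v),
                               stringsAsFactors = FALSE)
  v <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  expect_equal(spearman_validate(mk(v), mk(v), "degree")$rho, 1)
  expect_equal(spearman_validate(mk(v), mk(rev(unname(v)) + 0 * v), "degree")$rho, -1)
  # n = 5 exact p against enumeration over all 120 rank permutations
  set.seed(77)
  w <- c(a = 0.3, b = 1.2, c = 0.7, d = 2.0, e = 0.1)
  sv <- spearman_validate(mk(v), mk(w), "degree")
  perms <- asNamespace("socioscan")$all_permutations(5)
  rho_obs <- cor(unname(v), unname(w), method = "spearman")
  rhos <- apply(perms, 1, function(p) cor(unname(v), unname(w)[p],
                                          method = "spearman"))
  p_oracle <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(sv$p, p_oracle, tolerance = 1e-12)
  # constant vector flagged
  expect_warning(out <- spearman_validate(mk(v * 0 + 1), mk(w), "degree"),
                 "constant")
  expect_true(is.na(out$rho))
})

test_that("metric differences subtract estimated forest from road per individual", {
  mk <- function(v) data.frame(id = names(v), degree = unname(v),
                               stringsAsFactors = FALSE)
  a <- c(x = 1, y = 2, z = 3)
  expect_equal(metric_differences(mk(a), mk(a), "degree"),
               c(x = 0, y = 0, z = 0))
  d <- metric_differences(mk(a + 0.1), mk(a), "degree")
  expect_equal(unname(d), rep(0.1, 3))
  expect_error(metric_differences(mk(a), mk(a[1:2]), "degree"),
               "different node sets")
})

test_that("sign-flip enumeration gives exact randomization p-values", {
  r <- randomization_test(rep(1, 5), exhaustive = TRUE)
  expect_equal(r$p, 2 / 32)
  expect_equal(r$direction, "greater along road")
  r2 <- randomization_test(c(1, -1), exhaustive = TRUE)
  expect_equal(r2$p, 1)
  r12 <- randomization_test(rep(1, 12), exhaustive = TRUE)
  expect_equal(r12$p, 2 / 4096)
})

test_that("Monte-Carlo randomization p converges to the exact value", {
  set.seed(3)
  d <- c(0.8, 1.3, -0.2, 0.6, 0.9, -0.4, 1.1, 0.3, 0.5, -0.1)
  exact <- randomization_test(d, exhaustive = TRUE)$p
  mc <- randomization_test(d, n_resamples = 10000, seed = 42)$p
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(mc - exact), 3 * se + 1e-4)
  # reproducible under a fixed seed
  expect_identical(mc, randomization_test(d, n_resamples = 10000, seed = 42)$p)
})

test_that("degenerate difference vectors are handled", {
  expect_warning(r <- randomization_test(c(0, 0, 0)), "zero")
  expect_equal(r$p, 1)
  expect_error(randomization_test(1), "at least two")
})

test_that("centered bootstrap mode gives a valid, seeded p-value", {
  set.seed(1)
  d <- rnorm(15, mean = 0.5)
  r1 <- randomization_test(d, n_resamples = 2000, mode = "centered_bootstrap",
                           seed = 7)
  r2 <- randomization_test(d, n_resamples = 2000, mode = "centered_bootstrap",
                           seed = 7)
  expect_identical(r1$p, r2$p)
  expect_true(r1$p > 0 && r1$p <= 1)
  expect_equal(r1$mode, "centered_bootstrap")
  expect_error(randomization_test(d, mode = "centered_bootstrap",
                                  exhaustive = TRUE), "sign_flip")
})
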
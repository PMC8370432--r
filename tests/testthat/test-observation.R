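test_that("ERF projection is the stated linear map of depolarisations", {
  net <- network_spec()
  tr <- integrate_network(net)
  vl <- net$microcircuit$constants$VL
  # one-hot weight on superficial pyramidal cells, gain 2
  obs1 <- observation_spec(j = c(ss = 0, sp = 1, si = 0, dp = 0, di = 0,
                                 tp = 0), gain = 2)
  erf <- project_erf(tr, obs1)
  sp_cols <- grep("\\.sp$", colnames(tr$v))
  expect_equal(unname(erf), unname(2 * t(tr$v[, sp_cols] - vl)),
               tolerance = 1e-12)
  # linearity in the trajectories
  set.seed(1)
  x <- matrix(rnorm(length(tr$v)), nrow(tr$v))
  y <- matrix(rnorm(length(tr$v)), nrow(tr$v))
  mk <- function(m) { t2 <- tr; t2$v <- vl + m; t2 }
  obs <- observation_spec()
  lhs <- project_erf(mk(2 * x + 3 * y), obs)
  rhs <- 2 * project_erf(mk(x), obs) + 3 * project_erf(mk(y), obs)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # zero deviation from baseline gives a zero field
  expect_true(all(project_erf(mk(0 * x), obs) == 0))
})

test_that("observation spec requires a pyramidal contribution", {
  expect_error(observation_spec(j = c(ss = 1, sp = 0, si = 0, dp = 0,
                                      di = 0, tp = 0)), "pyramidal")
})

test_that("the Tukey window is exactly 1 on the protected interval", {
  t_grid <- cmm_times()
  w <- microdcm:::tukey_window(t_grid)
  inside <- t_grid >= 50 & t_grid <= 350
  expect_true(all(w[inside] == 1))
  expect_true(all(w[!inside] < 1))
  expect_equal(w[1], 0)
  expect_equal(w[length(w)], 0)
  expect_error(microdcm:::tukey_window(t_grid, flat = c(-200, 350)),
               "inside the epoch")
})

test_that("conditioning suppresses 60 Hz by more than 20 dB", {
  t_grid <- cmm_times()
  x <- matrix(sin(2 * pi * 60 * t_grid / 1000), 1)
  out <- condition_erf(x, time_ms = t_grid)
  expect_lt(mean(out^2) / mean(x^2), 0.01)
})

test_that("DC content in the protected interval is untouched", {
  t_grid <- cmm_times()
  x <- matrix(1, 1, length(t_grid))
  out <- condition_erf(x, time_ms = t_grid)
  inside <- t_grid >= 50 & t_grid <= 350
  expect_equal(unname(out[1, inside]), rep(1, sum(inside)),
               tolerance = 1e-12)
})

test_that("conditioning is idempotent on band-limited responses", {
  t_grid <- cmm_times()
  # 20 Hz burst under a Gaussian envelope centred in the protected window
  x <- matrix(exp(-0.5 * ((t_grid - 200) / 25)^2) *
                sin(2 * pi * 20 * t_grid / 1000), 1)
  once <- condition_erf(x, time_ms = t_grid)
  twice <- condition_erf(once, time_ms = t_grid)
  expect_lt(max(abs(twice - once)) / max(abs(once)), 1e-6)
})

test_that("conditioning has zero group delay", {
  t_grid <- cmm_times()
  x <- matrix(exp(-0.5 * ((t_grid - 200) / 30)^2), 1)
  out <- condition_erf(x, time_ms = t_grid)
  expect_equal(t_grid[which.max(out)], t_grid[which.max(x)])
})

test_that("conditioning refuses undersampled data", {
  t_sparse <- seq(-100, 400, by = 15)
  expect_error(condition_erf(matrix(rnorm(length(t_sparse)), 1),
                             time_ms = t_sparse), "twice")
})

test_that("conditioning a tibble preserves shape and time axis", {
  net <- network_spec()
  erf <- simulate_erf(net)
  out <- condition_erf(erf)
  expect_identical(dim(out), dim(erf))
  expect_identical(out$time_ms, erf$time_ms)
  expect_identical(out$source, erf$source)
})

test_that("fit statistics reproduce the Pearson formula", {
  t5 <- 1:5
  obs <- tibble::tibble(source = "lA1", time_ms = t5,
                        value = c(2, 1, 4, 3, 6))
  prd <- tibble::tibble(source = "lA1", time_ms = t5,
                        value = c(1, 2, 3, 5, 4))
  st <- erf_fit_statistics(obs, prd)
  x <- obs$value; y <- prd$value
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(st$by_trace$r, r_hand, tolerance = 1e-12)
  # perfect and anti-perfect prediction
  expect_equal(erf_fit_statistics(obs, obs)$by_trace$r, 1)
  neg <- prd; neg$value <- -obs$value
  expect_equal(erf_fit_statistics(obs, neg)$by_trace$r, -1)
})

test_that("zero-variance traces yield missing correlations, not NaN", {
  obs <- tibble::tibble(source = rep(c("lA1", "rA1"), each = 4),
                        time_ms = rep(1:4, 2),
                        value = c(1, 2, 3, 4, 5, 5, 5, 5))
  prd <- obs; prd$value <- c(1, 2, 3, 4, rnorm(4))
  st <- erf_fit_statistics(obs, prd)
  expect_true(is.na(st$by_trace$r[st$by_trace$source == "rA1"]))
  expect_false(any(is.nan(st$by_trace$r)))
  expect_equal(st$summary$n, 1)
})

test_that("pooled summary reports median and IQR across traces", {
  mk <- function(src, r_target, seed) {
    set.seed(seed)
    x <- rnorm(50)
    y <- r_target * x + sqrt(1 - r_target^2) * rnorm(50)
    list(obs = tibble::tibble(source = src, time_ms = 1:50, value = x),
         prd = tibble::tibble(source = src, time_ms = 1:50, value = y))
  }
  parts <- Map(mk, c("lA1", "rA1", "lSTG"), c(0.9, 0.5, 0.1), 1:3)
  obs <- dplyr::bind_rows(lapply(parts, `[[`, "obs"))
  prd <- dplyr::bind_rows(lapply(parts, `[[`, "prd"))
  st <- erf_fit_statistics(obs, prd)
  expect_equal(st$summary$median_r, sort(st$by_trace$r)[2])
  expect_equal(st$summary$iqr_r,
               unname(diff(quantile(st$by_trace$r, c(0.25, 0.75)))))
})
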
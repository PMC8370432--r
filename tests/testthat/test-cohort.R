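test_that("cohort generation is bit-identical under the same seed", {
  spec <- cohort_spec(n_control = 1, n_psp = 1, n_bvftd = 1, seed = 5)
  model <- compile_cmm(network_spec())
  c1 <- generate_cohort(spec, model)
  c2 <- generate_cohort(spec, model)
  expect_identical(c1$erf, c2$erf)
  expect_identical(c1$truth, c2$truth)
  # and the RNG stream of the caller is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_cohort(spec, model)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("effect-free cohorts have zero-mean parameters", {
  spec <- cohort_spec(n_control = 40, n_psp = 30, n_bvftd = 30,
                      effects = default_effects()[0, ], seed = 11)
  coh <- generate_cohort(spec, simulate = FALSE)
  th <- coh$truth$theta |>
    dplyr::filter(.data$condition == "standard") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(m = mean(.data$value), se = sd(.data$value) / sqrt(100))
  expect_true(all(abs(th$m) < 3 * th$se + 1e-12))
})

test_that("injected effects realise their nominal sizes exactly", {
  spec <- cohort_spec(seed = 12)
  coh <- generate_cohort(spec, simulate = FALSE)
  th <- coh$truth$theta |>
    dplyr::filter(.data$condition == "deviant") |>
    dplyr::left_join(coh$subjects, by = "subject")
  prior_sd <- 0.25
  # drug effect on tonic:di: within-subject session difference is exact
  di <- th |>
    dplyr::filter(.data$parameter == "tonic:di") |>
    tidyr::pivot_wider(names_from = "session", values_from = "value")
  # size 0.5 SD, drug coded +-1: TGB - PLA = 2 * 0.5 * prior_sd = 0.25
  expect_equal(di$tiagabine - di$placebo, rep(0.25, nrow(di)),
               tolerance = 1e-12)
  # group effect on the backward gain: controls - patients = 2 * size * sd
  bw <- th |>
    dplyr::filter(.data$parameter == "bwd:lIFG->lSTG",
                  .data$session == "placebo")
  gap <- mean(bw$value[bw$group == "control"]) -
    mean(bw$value[bw$group != "control"])
  # subject noise remains, but the systematic gap is 0.25
  expect_equal(gap, 2 * 0.5 * prior_sd, tolerance = 0.1)
})

test_that("patient groups have lower GABA than controls", {
  coh <- generate_cohort(cohort_spec(seed = 13), simulate = FALSE)
  m <- tapply(coh$subjects$gaba, coh$subjects$group, mean)
  expect_gt(m["control"], m["PSP"])
  expect_gt(m["control"], m["bvFTD"])
})

test_that("unknown effect parameters are rejected", {
  bad <- cohort_spec(effects = tibble::tibble(
    parameter = "tonic:zz", type = "drug", size = 0.5))
  expect_error(generate_cohort(bad, simulate = FALSE), "tonic:zz")
  expect_error(cohort_spec(n_control = 0), "group sizes")
  expect_error(cohort_spec(snr = -1), "snr")
})

test_that("realised SNR tracks the nominal value within 10%", {
  model <- compile_cmm(network_spec())
  coh <- generate_cohort(cohort_spec(n_control = 2, n_psp = 1, n_bvftd = 1,
                                     seed = 14), model)
  rep <- snr_report(coh)
  expect_true(all(abs(rep$snr - 10) / 10 < 0.1))
})

test_that("noiseless cohorts reproduce the stored truth exactly", {
  model <- compile_cmm(network_spec())
  coh <- generate_cohort(cohort_spec(n_control = 1, n_psp = 1, n_bvftd = 1,
                                     snr = Inf, seed = 15), model)
  joined <- dplyr::inner_join(
    coh$erf, dplyr::rename(coh$truth$erf_clean, clean = "value"),
    by = c("subject", "group", "session", "condition", "source", "time_ms"))
  expect_equal(joined$value, joined$clean, tolerance = 1e-12)
})

test_that("averaging more trials shrinks noise by 1/n", {
  model <- compile_cmm(network_spec())
  noise_var <- function(tc, seed) {
    coh <- generate_cohort(cohort_spec(n_control = 2, n_psp = 1,
                                       n_bvftd = 1, trial_count = tc,
                                       seed = seed), model)
    joined <- dplyr::inner_join(
      coh$erf, dplyr::rename(coh$truth$erf_clean, clean = "value"),
      by = c("subject", "group", "session", "condition", "source",
             "time_ms"))
    mean((joined$value - joined$clean)^2)
  }
  ratio <- noise_var(300, 16) / noise_var(150, 16)
  expect_equal(ratio, 0.5, tolerance = 0.1)
})

test_that("true parameters live only in the sealed truth store", {
  coh <- generate_cohort(cohort_spec(n_control = 1, n_psp = 1, n_bvftd = 1,
                                     seed = 17), compile_cmm(network_spec()))
  expect_false("parameter" %in% names(coh$erf))
  expect_false("value" %in% names(coh$subjects))
  expect_true(all(c("theta", "erf_clean") %in% names(coh$truth)))
})

test_that("roving sequences respect the stimulus grammar", {
  seq1 <- generate_roving_sequence(5000, seed = 2)
  expect_true(all(seq1$freq_hz %in% seq(400, 800, by = 50)))
  lens <- table(seq1$train)
  full <- head(lens, -1)  # final train may be truncated
  expect_true(all(full >= 3 & full <= 10))
  expect_true(all(seq1$label[seq1$position == 1 & seq1$train > 1] ==
                    "deviant"))
  expect_true(all(seq1$label[seq1$position == 6] == "standard"))
  expect_true(all(seq1$label[seq1$position %in% c(2:5, 7:10) |
                               (seq1$position == 1 & seq1$train == 1)] ==
                    "other"))
  expect_lte(sum(seq1$label == "standard"),
             sum(tapply(seq1$position, seq1$train, max) >= 6))
  # frequency steps are +-50 Hz between consecutive trains
  f_tr <- tapply(seq1$freq_hz, seq1$train, unique)
  expect_true(all(abs(diff(unlist(f_tr))) == 50))
  expect_identical(generate_roving_sequence(500, seed = 3),
                   generate_roving_sequence(500, seed = 3))
  expect_error(generate_roving_sequence(0), ">= 1")
})
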
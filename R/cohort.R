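#' Default injected effects of the synthetic cohort
#'
#' The default effect map targets the loci the group analyses are designed
#' to interrogate: a reduced backward frontotemporal gain in both patient
#' groups, a drug effect on the tonic inhibition of deep interneurons, an
#' opposing drug effect between patient groups at the stellate phasic
#' synapse, and GABA-concentration slopes on the deep phasic synapses.
#' Sizes are in units of the parameter's prior standard deviation.
#'
#' @export
default_effects <- function() {
  tibble::tibble(
    parameter = c("bwd:lIFG->lSTG", "tonic:di", "phasic:si->ss",
                  "phasic:di->dp", "phasic:di->tp"),
    type = c("group-contrast", "drug", "interaction",
             "gaba-slope", "gaba-slope"),
    size = c(0.5, 0.5, 0.5, 0.5, 0.5)
  )
}

#' Specification of a synthetic cohort
#'
#' Defines the statistical structure of a simulated crossover study:
#' group sizes (20 controls, 15 PSP, 17 bvFTD), two sessions (placebo,
#' tiagabine), two conditions (standard, deviant), injected effects on
#' named synaptic parameters, a per-group GABA model (patients lower than
#' controls, arbitrary units) and the observation signal-to-noise ratio.
#'
#' @param n_control,n_psp,n_bvftd group sizes.
#' @param effects tibble (`parameter`, `type`, `size`) of injected effects;
#'   `type` is one of `group-contrast` (controls - patients), `drug`
#'   (tiagabine - placebo), `interaction` (PSP - bvFTD by drug) or
#'   `gaba-slope` (per unit-SD GABA). Sizes in prior-SD units.
#' @param gaba_mean,gaba_sd per-group GABA means and common SD (arbitrary
#'   units; only orderings and slopes are meaningful).
#' @param subject_sd between-subject SD of every free parameter (theta
#'   units).
#' @param snr observation signal-to-noise ratio (RMS signal / RMS noise per
#'   source, at the reference trial count); `Inf` for noiseless data.
#' @param deviant_offset named theta offsets applied in the deviant
#'   condition (default: +0.25 on the four forward extrinsic gains).
#' @param trial_count trials averaged per condition (noise variance of the
#'   average scales as 1/n relative to `trial_ref`).
#' @param trial_ref reference trial count at which `snr` is nominal.
#' @param seed master seed; regeneration with the same spec and seed is
#'   bit-identical.
#' @export
cohort_spec <- function(n_control = 20, n_psp = 15, n_bvftd = 17,
                        effects = default_effects(),
                        gaba_mean = c(control = 1, PSP = 0.85, bvFTD = 0.8),
                        gaba_sd = 0.1, subject_sd = 0.1, snr = 10,
                        deviant_offset = NULL, trial_count = 150,
                        trial_ref = 150, seed = 1) {
  if (min(n_control, n_psp, n_bvftd) < 1) abort("group sizes must be >= 1")
  if (snr <= 0) abort("`snr` must be positive")
  if (is.null(deviant_offset)) {
    fwd <- c("fwd:lA1->lSTG", "fwd:lSTG->lIFG", "fwd:rA1->rSTG",
             "fwd:rSTG->rIFG")
    deviant_offset <- setNames(rep(0.25, 4), fwd)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject parameters as `theta = X beta_true + epsilon` with the
#' specified effects, draws GABA per group (linked to designated synapses
#' via the `gaba-slope` effects), and simulates the source ERFs with the
#' conductance model plus additive Gaussian observation noise. The true
#' parameters and noiseless ERFs are stored in a separate `truth` component
#' that the inversion and PEB stages never read.
#'
#' @param spec a [cohort_spec()].
#' @param model optional pre-compiled [compile_cmm()] model (compiled from
#'   the default network otherwise).
#' @param simulate generate ERFs (set `FALSE` to draw only parameters and
#'   covariates, for fast statistical checks of the generator).
#' @return object of class `synthetic_cohort` with `erf` (long tibble),
#'   `subjects` (tibble: `subject`, `group`, `gaba`, `trial_count`), `spec`
#'   and `truth` (list: `theta` tibble, `erf_clean`).
#' @export
generate_cohort <- function(spec = cohort_spec(), model = NULL,
                            simulate = TRUE) {
  if (is.null(model) && simulate)
    model <- compile_cmm(network_spec())
  free_names <- if (!is.null(model)) model$free_names
    else names(build_parameter_priors(network_spec())$mean)
  prior_sd <- if (!is.null(model)) sqrt(diag(model$priors$cov))
    else sqrt(diag(build_parameter_priors(network_spec())$cov))
  bad <- setdiff(spec$effects$parameter, free_names)
  if (length(bad) > 0)
    abort(paste("unknown parameter name in effects:",
                paste(bad, collapse = ", ")))
  bad_dev <- setdiff(names(spec$deviant_offset), free_names)
  if (length(bad_dev) > 0)
    abort(paste("unknown parameter name in deviant offset:",
                paste(bad_dev, collapse = ", ")))

  groups <- rep(c("control", "PSP", "bvFTD"),
                c(spec$n_control, spec$n_psp, spec$n_bvftd))
  n <- length(groups)
  subjects <- tibble::tibble(
    subject = sprintf("S%03d", seq_len(n)),
    group = groups
  )

  with_local_seed(spec$seed, {
    subjects$gaba <- rnorm(n, unname(spec$gaba_mean[groups]), spec$gaba_sd)
    subjects$trial_count <- rep(spec$trial_count, length.out = n)
    gaba_z <- as.numeric(scale(subjects$gaba))
    cvp <- ifelse(groups == "control", 1, -1)
    pvb <- ifelse(groups == "PSP", 1, ifelse(groups == "bvFTD", -1, 0))

    p <- length(free_names)
    theta_base <- matrix(rnorm(n * p, 0, spec$subject_sd), n, p,
                         dimnames = list(subjects$subject, free_names))

    # per subject x session theta (before condition offsets)
    theta_of <- function(i, drug) {
      th <- theta_base[i, ]
      for (r in seq_len(nrow(spec$effects))) {
        ef <- spec$effects[r, ]
        xval <- switch(ef$type,
                       "group-contrast" = cvp[i],
                       "drug" = drug,
                       "interaction" = pvb[i] * drug,
                       "gaba-slope" = gaba_z[i],
                       abort(paste("unknown effect type:", ef$type)))
        th[ef$parameter] <- th[ef$parameter] +
          ef$size * prior_sd[ef$parameter] * xval
      }
      th
    }

    sessions <- c(placebo = -1, tiagabine = 1)
    conditions <- c("standard", "deviant")
    truth_rows <- list()
    erf_rows <- list()
    clean_rows <- list()
    for (i in seq_len(n)) {
      for (ses in names(sessions)) {
        th_ses <- theta_of(i, sessions[[ses]])
        for (cond in conditions) {
          th <- th_ses
          if (cond == "deviant" && length(spec$deviant_offset) > 0)
            th[names(spec$deviant_offset)] <-
              th[names(spec$deviant_offset)] + spec$deviant_offset
          truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
            subject = subjects$subject[i], session = ses, condition = cond,
            parameter = free_names, value = unname(th))
          if (!simulate) next
          m <- predict_erf_matrix(model, th)
          if (is.null(m))
            abort("cohort simulation diverged; check effect sizes",
                  class = "microdcm_divergence")
          noise_sd <- if (is.infinite(spec$snr)) rep(0, nrow(m)) else
            apply(m, 1, rms) / spec$snr *
              sqrt(spec$trial_ref / subjects$trial_count[i])
          noisy <- m + matrix(rnorm(length(m), 0, rep(noise_sd, ncol(m))),
                              nrow(m), ncol(m))
          base_cols <- tibble::tibble(
            subject = subjects$subject[i], group = groups[i],
            session = ses, condition = cond)
          erf_rows[[length(erf_rows) + 1L]] <- dplyr::bind_cols(
            base_cols[rep(1, 6 * length(model$t_grid)), ],
            erf_matrix_to_tibble(noisy, model$t_grid))
          clean_rows[[length(clean_rows) + 1L]] <- dplyr::bind_cols(
            base_cols[rep(1, 6 * length(model$t_grid)), ],
            erf_matrix_to_tibble(m, model$t_grid))
        }
      }
    }
    structure(list(
      erf = if (simulate) dplyr::bind_rows(erf_rows) else NULL,
      subjects = subjects,
      spec = spec,
      truth = list(theta = dplyr::bind_rows(truth_rows),
                   erf_clean = if (simulate) dplyr::bind_rows(clean_rows)
                               else NULL)
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), seed %d\n",
              nrow(x$subjects),
              paste(table(x$subjects$group)[c("control", "PSP", "bvFTD")],
                    collapse = "/"), x$spec$seed))
  invisible(x)
}

#' Realized signal-to-noise of a synthetic cohort
#'
#' Compares each generated ERF with its stored noiseless reference and
#' reports the realized SNR (RMS signal over RMS noise, pooled over
#' sources) per subject, session and condition.
#'
#' @param cohort a [generate_cohort()] result with simulated ERFs.
#' @return tibble with `subject`, `session`, `condition`, `snr`.
#' @export
snr_report <- function(cohort) {
  if (is.null(cohort$erf)) abort("cohort was generated without ERFs")
  joined <- dplyr::inner_join(
    cohort$erf,
    dplyr::rename(cohort$truth$erf_clean, clean = "value"),
    by = c("subject", "group", "session", "condition", "source", "time_ms"))
  joined |>
    dplyr::group_by(.data$subject, .data$session, .data$condition) |>
    dplyr::summarise(
      snr = rms(.data$clean) / rms(.data$value - .data$clean),
      .groups = "drop")
}
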
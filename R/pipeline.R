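#' Fit every subject of a cohort
#'
#' Runs the per-subject variational inversions for the requested sessions
#' and conditions. Data are conditioned (low-pass + Tukey window) before
#' inversion. Fits are resumable: with a `cache_dir`, completed fits are
#' identified by a hash of the data and settings and skipped on re-run.
#'
#' @param cohort a [generate_cohort()] result, or any long ERF tibble with
#'   `subject`, `session`, `condition`, `source`, `time_ms`, `value`.
#' @param model a [compile_cmm()] model (the default network is compiled
#'   otherwise).
#' @param conditions conditions to invert (group analyses use the deviant
#'   response; pass `c("standard", "deviant")` for both).
#' @param settings an [invert_settings()] list.
#' @param cache_dir optional directory for resumable fits.
#' @param verbose print one line per fit.
#' @return object of class `cohort_fits`: named list `fits` (key
#'   `subject/session/condition`), tibble `table` (one row per fit: free
#'   energy, convergence, median and per-source correlations, cache hits).
#' @export
fit_cohort <- function(cohort, model = NULL, conditions = "deviant",
                       settings = invert_settings(), cache_dir = NULL,
                       verbose = FALSE) {
  erf <- if (inherits(cohort, "synthetic_cohort")) cohort$erf else cohort
  if (is.null(erf)) abort("cohort has no ERF data")
  model <- model %||% compile_cmm(network_spec())
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  erf <- dplyr::filter(erf, .data$condition %in% conditions)
  cells <- dplyr::distinct(erf, .data$subject, .data$session,
                           .data$condition)
  settings_key <- settings[sort(names(settings))]
  fits <- list()
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    key <- paste(cell$subject, cell$session, cell$condition, sep = "/")
    y <- erf |>
      dplyr::semi_join(cell, by = c("subject", "session", "condition")) |>
      erf_tibble_to_matrix()
    y <- condition_erf(y, settings$lowpass_hz, settings$window,
                       time_ms = model$t_grid)
    cached <- FALSE
    fit <- NULL
    cache_file <- NULL
    if (!is.null(cache_dir)) {
      hash <- rlang::hash(list(y, settings_key, model$free_names))
      cache_file <- file.path(cache_dir, paste0(hash, ".rds"))
      if (file.exists(cache_file)) {
        fit <- readRDS(cache_file)
        cached <- TRUE
      }
    }
    if (is.null(fit)) {
      fit <- invert_erf(y, model, settings = settings)
      if (!is.null(cache_file)) saveRDS(fit, cache_file)
    }
    fits[[key]] <- fit
    r_by_src <- if (is.null(fit$stats)) rep(NA_real_, 6) else
      fit$stats$by_trace$r[match(cmm_sources(), fit$stats$by_trace$source)]
    rows[[i]] <- dplyr::bind_cols(
      cell,
      tibble::tibble(f = fit$posterior$free_energy,
                     converged = fit$converged,
                     iterations = fit$iterations,
                     r_median = if (is.null(fit$stats)) NA_real_ else
                       fit$stats$summary$median_r,
                     cached = cached),
      tibble::as_tibble(as.list(setNames(r_by_src,
                                         paste0("r_", cmm_sources())))))
    if (verbose)
      message(sprintf("%s F=%.1f r=%.3f%s", key, fit$posterior$free_energy,
                      rows[[i]]$r_median, if (cached) " [cache]" else ""))
  }
  structure(list(fits = fits, table = dplyr::bind_rows(rows),
                 model = model, settings = settings),
            class = "cohort_fits")
}

#' @export
print.cohort_fits <- function(x, ...) {
  cat(sprintf("<cohort_fits> %d fits, median r = %.3f, %d%% converged\n",
              nrow(x$table), median(x$table$r_median, na.rm = TRUE),
              round(100 * mean(x$table$converged))))
  invisible(x)
}

#' Combine session posteriors into crossover blocks
#'
#' Rotates each subject's two session posteriors into independent
#' session-level and drug-response beliefs: `level = (placebo + drug)/2`
#' and `drug = (drug - placebo)/2` (sessions are inverted independently,
#' so the blocks are independent Gaussians with covariance `(S1+S2)/4`).
#' This makes the crossover structure explicit at the second level:
#' subject trait variance loads on the `level|` block and drug-response
#' variance on the `drug|` block, each with its own between-subject
#' log-precision in [fit_peb()].
#'
#' @inheritParams analyse_groups
#' @param condition condition whose posteriors are combined.
#' @return list with `beliefs` (one per subject, parameters
#'   `level|<name>` and `drug|<name>`), `rows` (subject covariates) and
#'   the matching first-level `prior`.
#' @export
combine_sessions <- function(fits, subjects, condition = "deviant") {
  db <- deviant_beliefs(fits, subjects, condition)
  pla <- which(db$rows$session == "placebo")
  tgb <- which(db$rows$session == "tiagabine")
  if (!identical(db$rows$subject[pla], db$rows$subject[tgb]))
    abort("every subject needs both sessions for the crossover analysis")
  nm <- names(db$beliefs[[1]]$mean)
  nm2 <- c(paste0("level|", nm), paste0("drug|", nm))
  beliefs <- lapply(seq_along(pla), function(i) {
    b1 <- db$beliefs[[pla[i]]]; b2 <- db$beliefs[[tgb[i]]]
    s <- (b1$cov + b2$cov) / 4
    gaussian_belief(setNames(c((b1$mean + b2$mean) / 2,
                               (b2$mean - b1$mean) / 2), nm2),
                    rbind(cbind(s, 0 * s), cbind(0 * s, s)))
  })
  prior1 <- belief_subset(fits$model$priors, nm)
  s0 <- prior1$cov / 2
  prior <- gaussian_belief(setNames(rep(0, 2 * length(nm)), nm2),
                           rbind(cbind(s0, 0 * s0), cbind(0 * s0, s0)))
  rows <- db$rows[pla, setdiff(names(db$rows), "session")]
  list(beliefs = beliefs, rows = rows, prior = prior)
}

# deviant-condition posteriors + aligned covariate rows, in a stable order
deviant_beliefs <- function(fits, subjects, condition = "deviant") {
  tab <- fits$table |>
    dplyr::filter(.data$condition == !!condition) |>
    dplyr::arrange(.data$subject, .data$session)
  missing <- setdiff(subjects$subject, tab$subject)
  if (length(missing) > 0)
    abort(paste("missing posteriors for subjects:",
                paste(missing, collapse = ", ")))
  keys <- paste(tab$subject, tab$session, tab$condition, sep = "/")
  beliefs <- lapply(fits$fits[keys], `[[`, "posterior")
  rows <- dplyr::left_join(tab[, c("subject", "session")], subjects,
                           by = "subject")
  list(beliefs = beliefs, rows = rows)
}

#' Parameter families entered into the group-level analyses
#'
#' The group analyses interrogate two parameter families separately, in
#' separate PEB models: the extrinsic (between-source) connection gains,
#' and the intrinsic GABAergic synapses (six tonic self-connections plus
#' four phasic interneuron efferents). Input and observation parameters are
#' first-level nuisance parameters and are not carried to the group level.
#'
#' @param model a [compile_cmm()] model.
#' @return named list of parameter-name vectors.
#' @export
peb_families <- function(model) {
  tab <- model$param_table
  fam <- list(
    extrinsic = tab$name[tab$free & tab$class == "extrinsic"],
    intrinsic_gabaa = tab$name[tab$free & tab$class == "intrinsic_gabaa"])
  lapply(fam, function(nm) as.vector(outer(c("level|", "drug|"), nm,
                                           paste0)))
}

#' Group and drug effects via hierarchical PEB
#'
#' Implements the three-level analysis for each parameter family. Each
#' subject's two session posteriors are first combined into independent
#' session-level (`level|`) and drug-response (`drug|`) blocks (the
#' crossover rotation, see [combine_sessions()]); per-group second-level
#' PEBs then estimate the group typical value of both blocks, and a
#' third-level PEB-of-PEBs compares groups. Group contrasts on the level
#' block measure group differences in connectivity; group contrasts on the
#' drug-response block are group-by-drug interactions.
#'
#' @param fits a [fit_cohort()] result (deviant condition present).
#' @param subjects covariate tibble (`subject`, `group`, optionally
#'   `gaba`).
#' @param pp_threshold posterior-probability threshold for the reported
#'   effect table.
#' @param families named list of parameter subsets analysed in separate
#'   PEBs (default [peb_families()]: extrinsic gains and intrinsic
#'   GABAergic synapses).
#' @param prune run greedy Bayesian-model-reduction pruning on an
#'   all-subject group-mean PEB per family first and restrict subsequent
#'   analyses to the retained parameters.
#' @param settings [peb_settings()].
#' @return list of class `group_analysis`: `pebs` (per family, per group),
#'   `peb3` (per family), `effects` (tidy table with a `family` column),
#'   `significant` (thresholded), `pruned`.
#' @export
analyse_groups <- function(fits, subjects, pp_threshold = 0.95,
                           families = NULL, prune = FALSE,
                           settings = peb_settings()) {
  cs <- combine_sessions(fits, subjects)
  families <- families %||% peb_families(fits$model)
  grp_levels <- c("control", "PSP", "bvFTD")
  x2 <- cbind(mean = c(1, 1, 1), cvp = c(1, -1, -1), pvb = c(0, 1, -1))
  pruned <- character(0)
  pebs <- list(); peb3 <- list(); effects <- list()
  for (fam in names(families)) {
    parameters <- families[[fam]]
    if (prune) {
      peb_mean <- fit_peb(cs$beliefs, peb_design(cs$rows), cs$prior,
                          parameters, settings)
      pr <- greedy_prune(peb_mean$belief, peb_mean$beta_prior,
                         names(peb_mean$belief$mean))
      pruned <- c(pruned, sub("^mean\\|", "", pr$pruned))
      parameters <- setdiff(parameters, sub("^mean\\|", "", pr$pruned))
    }
    pf <- lapply(grp_levels, function(g) {
      sel <- cs$rows$group == g
      fit_peb(cs$beliefs[sel], peb_design(cs$rows[sel, ]), cs$prior,
              parameters, settings)
    })
    names(pf) <- grp_levels
    p3 <- peb_of_pebs(pf, x2)
    pebs[[fam]] <- pf
    peb3[[fam]] <- p3
    effects[[fam]] <- dplyr::mutate(tidy(p3), family = fam,
                                    .before = 1)
  }
  effects <- dplyr::bind_rows(effects)
  structure(list(pebs = pebs, peb3 = peb3, effects = effects,
                 significant = effects[effects$pp > pp_threshold, ] |>
                   dplyr::arrange(dplyr::desc(.data$pp)),
                 pruned = pruned, pp_threshold = pp_threshold),
            class = "group_analysis")
}

#' GABA-covariate model comparison and interactions
#'
#' Fits the all-subject second-level PEB of the combined session-level /
#' drug-response posteriors with and without the (mean-centred, unit-SD)
#' GABA covariate and compares the two models by free energy. The GABA
#' column's loading on the level block is the covariate main effect; its
#' loading on the drug-response block is the GABA-by-drug interaction.
#' GABA-by-group interactions are explored in a separate PEB so the model
#' comparison isolates the covariate's explanatory value.
#'
#' @inheritParams analyse_groups
#' @param parameters parameter subset analysed (default: the intrinsic
#'   GABAergic family, the synapse set the covariate question concerns).
#' @param base_terms design columns of the GABA-free reference model.
#' @param interaction_terms extra GABA interaction columns of the separate
#'   interaction PEB (GABA-by-drug needs no column: it is the gaba column
#'   of the drug-response block).
#' @return list of class `gaba_analysis`: `comparison`
#'   ([compare_evidence()] table for the with/without-GABA designs),
#'   `peb_with`, `peb_without`, `peb_interactions`, `effects` (tidy table
#'   of the GABA and interaction columns), `significant`. Returns `NULL`
#'   with a warning when the covariate is absent.
#' @export
analyse_gaba <- function(fits, subjects, pp_threshold = 0.95,
                         parameters = NULL,
                         base_terms = c("cvp", "pvb"),
                         interaction_terms = "gaba:pvb",
                         settings = peb_settings()) {
  if (!"gaba" %in% names(subjects) || anyNA(subjects$gaba)) {
    warn("GABA covariate missing; analysis skipped")
    return(NULL)
  }
  cs <- combine_sessions(fits, subjects)
  # the covariate analysis interrogates the GABAergic synapses
  parameters <- parameters %||% peb_families(fits$model)$intrinsic_gabaa
  level_params <- grep("^level\\|", parameters, value = TRUE)
  # The with/without comparison concerns the covariate as a
  # between-subjects variable, i.e. the session-level block. Per-parameter
  # between-subject variances are estimated once, under the fuller
  # (covariate-inclusive) model, and both designs are evaluated at those
  # components — the REML-style treatment of variance parameters when
  # comparing fixed effects. A true covariate then leaves residual
  # variances the base design cannot meet, while a permuted covariate
  # leaves components that fit both designs, so the comparison rewards
  # only genuinely explained between-subject variation.
  settings_var <- settings
  settings_var$gamma_per <- "parameter"
  peb_with <- fit_peb(cs$beliefs,
                      peb_design(cs$rows, c(base_terms, "gaba")),
                      cs$prior, level_params, settings_var)
  settings_fixed <- settings_var
  settings_fixed$gamma_fixed <- peb_with$gamma
  peb_without <- fit_peb(cs$beliefs, peb_design(cs$rows, base_terms),
                         cs$prior, level_params, settings_fixed)
  comparison <- compare_evidence(
    c(without_gaba = peb_without$free_energy,
      with_gaba = peb_with$free_energy))
  # interactions over both blocks: the gaba column of the drug-response
  # block is the GABA-by-drug interaction; gaba:pvb tests group-dependent
  # slopes on the session level
  peb_int <- fit_peb(cs$beliefs,
                     peb_design(cs$rows, c(base_terms, "gaba",
                                           interaction_terms)),
                     cs$prior, parameters, settings)
  effects <- dplyr::bind_rows(
    dplyr::filter(tidy(peb_with), .data$effect == "gaba"),
    dplyr::filter(tidy(peb_int), .data$effect %in% interaction_terms |
                    (.data$effect == "gaba" &
                       grepl("^drug\\|", .data$parameter))))
  structure(list(comparison = comparison, peb_with = peb_with,
                 peb_without = peb_without, peb_interactions = peb_int,
                 effects = effects,
                 significant = effects[effects$pp > pp_threshold, ],
                 pp_threshold = pp_threshold),
            class = "gaba_analysis")
}

#' Assemble a run report
#'
#' Collects the per-subject fit table, the PEB effect tables and the model
#' comparison into a single report with provenance (content hash and seed),
#' optionally writing CSV/JSON files.
#'
#' @param fits a [fit_cohort()] result (or `NULL`).
#' @param groups an [analyse_groups()] result (or `NULL`).
#' @param gaba an [analyse_gaba()] result (or `NULL`).
#' @param seed seed to record in the provenance block.
#' @param dir optional output directory; tables are written as CSV and the
#'   report skeleton as JSON.
#' @return list of class `run_report` with `fit_table`, `group_effects`,
#'   `gaba_effects`, `model_comparison`, `provenance` (`hash`, `seed`,
#'   `partial`, `created`).
#' @export
run_report <- function(fits = NULL, groups = NULL, gaba = NULL, seed = NA,
                       dir = NULL) {
  report <- list(
    fit_table = if (!is.null(fits)) fits$table else NULL,
    group_effects = if (!is.null(groups)) groups$effects else NULL,
    group_significant = if (!is.null(groups)) groups$significant else NULL,
    gaba_effects = if (!is.null(gaba)) gaba$effects else NULL,
    model_comparison = if (!is.null(gaba)) gaba$comparison else NULL
  )
  partial <- any(vapply(report[c("fit_table", "group_effects")], is.null,
                        logical(1)))
  report$provenance <- list(
    hash = rlang::hash(report),
    seed = seed,
    partial = partial,
    n_analyses = sum(!vapply(report, is.null, logical(1))) - 0L
  )
  class(report) <- "run_report"
  if (!is.null(dir)) write_report(report, dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>",
      if (x$provenance$partial) "(partial)" else "(complete)", "\n")
  if (!is.null(x$fit_table))
    cat(sprintf("  fits: %d, median r = %.3f\n", nrow(x$fit_table),
                median(x$fit_table$r_median, na.rm = TRUE)))
  if (!is.null(x$group_significant))
    cat(sprintf("  significant group/drug effects: %d\n",
                nrow(x$group_significant)))
  if (!is.null(x$model_comparison))
    cat(sprintf("  GABA-inclusive model probability: %.3f\n",
                x$model_comparison$prob[x$model_comparison$model ==
                                          "with_gaba"]))
  invisible(x)
}

#' Correlate a behavioural score with fitted connectivity
#'
#' Optional hook for cohorts carrying per-subject behavioural or clinical
#' scores: correlates the score with each subject's posterior estimate of
#' a chosen parameter (averaged over that subject's fitted sessions).
#' Purely descriptive — no claim beyond the reported correlation.
#'
#' @param fits a [fit_cohort()] result.
#' @param subjects covariate tibble containing `score_col`.
#' @param score_col name of the numeric score column.
#' @param parameter parameter whose posterior mean is correlated (default:
#'   the backward frontotemporal gain).
#' @return tibble with `parameter`, `score`, `r`, `n`.
#' @export
correlate_scores <- function(fits, subjects, score_col,
                             parameter = "bwd:lIFG->lSTG") {
  if (!score_col %in% names(subjects))
    abort(paste0("no column `", score_col, "` in subjects"))
  db <- deviant_beliefs(fits, subjects)
  est <- vapply(db$beliefs, function(b) b$mean[[parameter]], numeric(1))
  per_subj <- tapply(est, db$rows$subject, mean)
  score <- subjects[[score_col]][match(names(per_subj), subjects$subject)]
  ok <- !is.na(score)
  tibble::tibble(parameter = parameter, score = score_col,
                 r = cor(per_subj[ok], score[ok]), n = sum(ok))
}
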
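#' Between-subject design matrix
#'
#' Builds a named design matrix from a covariate tibble. The first column
#' is always the constant group mean. Recognised terms:
#' * `"drug"` — session contrast, +1 tiagabine, -1 placebo;
#' * `"cvp"` — group contrast controls - patients (+1 control, -1 PSP/bvFTD);
#' * `"pvb"` — group contrast PSP - bvFTD (+1 PSP, -1 bvFTD, 0 control);
#' * `"gaba"` — GABA covariate, mean-centred and scaled to unit SD;
#' * products `"a:b"` of any two recognised terms (interactions, elementwise
#'   products of the built columns).
#' Any other term must name a numeric column of `data`, which is
#' mean-centred.
#'
#' @param data tibble with one row per observation (subject-session), with
#'   whatever of `session`, `group`, `gaba` the terms require.
#' @param terms character vector of effect columns (besides the mean).
#' @return numeric matrix with named columns, first column `mean` all ones.
#' @export
peb_design <- function(data, terms = character(0)) {
  n <- nrow(data)
  build1 <- function(term) {
    switch(term,
      drug = ifelse(data$session == "tiagabine", 1, -1),
      cvp  = ifelse(data$group == "control", 1, -1),
      pvb  = ifelse(data$group == "PSP", 1, ifelse(data$group == "bvFTD",
                                                   -1, 0)),
      gaba = {
        g <- data$gaba
        if (anyNA(g)) abort("missing GABA covariate")
        as.numeric(scale(g))
      },
      {
        if (!term %in% names(data))
          abort(paste0("unknown design term `", term, "`"))
        v <- data[[term]]
        v - mean(v)
      })
  }
  cols <- lapply(terms, function(term) {
    if (grepl(":", term, fixed = TRUE)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      Reduce(`*`, lapply(parts, build1))
    } else build1(term)
  })
  x <- cbind(mean = rep(1, n), do.call(cbind, cols))
  colnames(x) <- c("mean", terms)
  validate_design(x)
  x
}

# first column of ones, unique names, full column rank (else name the
# collinear columns)
validate_design <- function(x) {
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    abort("design matrix columns must be uniquely named")
  if (!all(x[, 1] == 1)) abort("first design column must be the constant mean")
  # all-zero effect columns are permitted (they carry no evidence and leave
  # their effects at the prior); rank is checked over the rest
  nz <- colSums(x != 0) > 0
  qrx <- qr(x[, nz, drop = FALSE])
  if (qrx$rank < sum(nz)) {
    drop_cols <- colnames(x)[nz][qrx$pivot[(qrx$rank + 1):sum(nz)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(drop_cols, collapse = ", ")))
  }
  invisible(x)
}

#' Settings for parametric empirical Bayes
#'
#' @param gamma_range search interval for the between-subject log-precision
#'   scaling.
#' @param gamma_fixed optional fixed value (used for saturated third-level
#'   designs where the between-model variance is not identifiable).
#' @param gamma_per grain of the between-subject log-precision: one per
#'   parameter class (default) or one per parameter (finer random-effects
#'   model; slower but sharper when variance differs across synapses).
#' @param gamma_prior_var prior variance of the log-precision (mean 0).
#' @param between_scale between-subject variance at `gamma = 0`, as a
#'   fraction of the first-level prior variance.
#' @param beta_prior_scale second-level effect prior variance, as a
#'   fraction of the first-level prior variance. Effects across subjects
#'   are expected to be a fraction of the within-subject prior range, so
#'   the second level shrinks harder than the first (the PEB convention);
#'   1/8 balances shrinkage against detection of moderate effects.
#' @param sweeps coordinate-ascent sweeps over per-class log-precisions.
#' @export
peb_settings <- function(gamma_range = c(-4, 6), gamma_fixed = NULL,
                         gamma_per = c("class", "parameter"),
                         gamma_prior_var = 1, between_scale = 1 / 4,
                         beta_prior_scale = 1 / 8, sweeps = 2) {
  gamma_per <- match.arg(gamma_per)
  as.list(environment())
}

#' Fit a parametric empirical Bayes model
#'
#' Places a general linear model over subjects' parameter posteriors:
#' `theta_i = X[i,] %*% beta + epsilon_i`, with random effects
#' `epsilon_i ~ N(0, Sigma_b)` whose magnitude is controlled by one shared
#' log-precision per parameter class (estimated by deterministic
#' maximisation of the exact marginal likelihood). Effect posterior
#' probabilities are computed by Bayesian model reduction of the
#' second-level posterior with versus without each (column, parameter)
#' entry.
#'
#' @param posteriors list of [gaussian_belief()] first-level posteriors
#'   sharing parameter names.
#' @param x design matrix (rows align with `posteriors`), see
#'   [peb_design()].
#' @param prior the first-level prior belief the posteriors were obtained
#'   under.
#' @param parameters optional subset of parameter names to carry to the
#'   second level (defaults to all).
#' @param settings a [peb_settings()] list.
#' @return object of class `peb_model`: `beta` (parameters x effects
#'   matrix), `belief` (Gaussian over `vec(beta)`, stacked by effect
#'   column), `beta_prior`, `pp` (parameters x effects posterior
#'   probabilities), `free_energy`, `gamma`, `x`, `parameters`.
#' @export
fit_peb <- function(posteriors, x, prior, parameters = NULL,
                    settings = peb_settings()) {
  validate_design(x)
  if (nrow(x) != length(posteriors))
    abort("design rows must align with the posteriors")
  parameters <- parameters %||% names(posteriors[[1]]$mean)
  nm0 <- names(posteriors[[1]]$mean)
  for (b in posteriors)
    if (!identical(names(b$mean), nm0))
      abort("posteriors do not share parameter names")
  beliefs <- lapply(posteriors, belief_subset, parameters)
  pr <- belief_subset(prior, parameters)
  p <- length(parameters); k <- ncol(x); n <- length(beliefs)

  # precision-form sufficient statistics per subject: the second level is
  # evaluated through the Bayesian-model-reduction identity (replace the
  # first-level prior N(m0, S0) by N(X beta, Sigma_b)), which keeps every
  # quantity bounded even along directions the data barely inform (naive
  # prior-stripping divides by near-zero precisions there)
  p0m <- inv_sym(pr$cov)
  h0 <- drop(p0m %*% pr$mean)
  post_prec <- lapply(beliefs, function(b) inv_sym(b$cov))
  post_h <- Map(function(pp, b) drop(pp %*% b$mean), post_prec, beliefs)
  ld_p <- unname(vapply(post_prec, logdet, numeric(1)))
  quad_mu <- vapply(seq_len(n), function(i)
    drop(t(beliefs[[i]]$mean) %*% post_prec[[i]] %*% beliefs[[i]]$mean),
    numeric(1))
  const0 <- 0.5 * drop(t(pr$mean) %*% p0m %*% pr$mean) +
    0.5 * logdet(pr$cov)

  # parameter classes share one between-subject log-precision
  classes <- if (identical(settings$gamma_per, "parameter")) parameters
    else vapply(strsplit(parameters, ":", fixed = TRUE), `[[`, "", 1)
  class_of <- match(classes, unique(classes))
  n_class <- max(class_of)
  v_base <- settings$between_scale * diag(pr$cov)

  # second-level effect prior: zero mean, scaled first-level variances
  beta_names <- as.vector(outer(parameters, colnames(x),
                                function(a, b) paste(b, a, sep = "|")))
  v_beta <- rep(settings$beta_prior_scale * diag(pr$cov), k)
  beta_prior <- gaussian_belief(setNames(rep(0, p * k), beta_names), v_beta)
  p_b0 <- diag(1 / v_beta, p * k)

  evidence <- function(gamma) {
    pr_b <- diag(1 / (v_base * exp(-gamma[class_of])), p)
    ld_pr <- sum(log(diag(pr_b)))
    h <- p_b0
    g <- numeric(p * k)
    kconst <- 0
    for (i in seq_len(n)) {
      a_i <- post_h[[i]] - h0
      pq <- post_prec[[i]] + pr_b - p0m
      ipq <- inv_sym(pq)
      w <- pr_b %*% ipq
      ceff <- pr_b - w %*% pr_b
      xi <- x[i, ]
      h <- h + kronecker(tcrossprod(xi), (ceff + t(ceff)) / 2)
      g <- g + kronecker(xi, drop(w %*% a_i))
      kconst <- kconst + 0.5 * drop(t(a_i) %*% ipq %*% a_i) +
        0.5 * (ld_p[i] + ld_pr - logdet(pq)) - 0.5 * quad_mu[i] +
        const0
    }
    sb <- inv_sym(h)
    bhat <- drop(sb %*% g)
    f <- unname(kconst) + 0.5 * sum(g * bhat) +
      0.5 * (logdet(sb) - sum(log(v_beta))) -
      0.5 * sum(gamma^2) / settings$gamma_prior_var
    list(f = f, bhat = bhat, sb = sb)
  }

  if (!is.null(settings$gamma_fixed)) {
    gamma <- rep(settings$gamma_fixed, length.out = n_class)
  } else {
    gamma <- rep(0, n_class)
    for (sw in seq_len(settings$sweeps)) {
      for (cl in seq_len(n_class)) {
        gamma[cl] <- optimize(function(gc) {
          gg <- gamma; gg[cl] <- gc
          evidence(gg)$f
        }, settings$gamma_range, maximum = TRUE, tol = 1e-3)$maximum
      }
    }
  }
  fit <- evidence(gamma)
  belief <- gaussian_belief(setNames(fit$bhat, beta_names), fit$sb,
                            free_energy = fit$f)

  # effect posterior probabilities via BMR with/without each entry
  pp <- matrix(NA_real_, p, k, dimnames = list(parameters, colnames(x)))
  for (j in seq_len(k)) for (a in seq_len(p)) {
    nmja <- paste(colnames(x)[j], parameters[a], sep = "|")
    rp <- pin_prior(beta_prior, nmja)
    df_without <- bmr_reduce(belief, beta_prior, rp)$df
    pp[a, j] <- 1 / (1 + exp(df_without))
  }

  beta <- matrix(fit$bhat, p, k, dimnames = list(parameters, colnames(x)))
  structure(list(beta = beta, belief = belief, beta_prior = beta_prior,
                 pp = pp, free_energy = fit$f, gamma = gamma,
                 x = x, parameters = parameters, settings = settings),
            class = "peb_model")
}

#' @export
print.peb_model <- function(x, ...) {
  cat(sprintf("<peb_model> %d parameters x %d effects, F = %s\n",
              nrow(x$beta), ncol(x$beta), format(x$free_energy, digits = 6)))
  invisible(x)
}

#' Third-level PEB over second-level PEB models
#'
#' Treats the second-level effect posteriors of several PEB models (for
#' example one per diagnostic group) as data for a third-level general
#' linear model, giving group-difference and interaction effects: a group
#' contrast applied to the drug-effect block is a group-by-drug
#' interaction.
#'
#' @param pebs list of `peb_model` objects with identical parameter/effect
#'   structure.
#' @param x2 third-level design matrix (rows align with `pebs`).
#' @param settings [peb_settings()]; the between-model variance defaults to
#'   a small fixed value because typical third-level designs (3 groups, 3
#'   columns) are saturated.
#' @return a `peb_model` whose "parameters" are
#'   `<level-2 effect>|<parameter>` pairs.
#' @export
peb_of_pebs <- function(pebs, x2,
                        settings = peb_settings(gamma_fixed = 8)) {
  stopifnot(length(pebs) >= 2)
  struct <- lapply(pebs, function(pm) names(pm$belief$mean))
  if (!all(vapply(struct, identical, logical(1), struct[[1]])))
    abort("input PEB models do not share parameter/effect structure")
  beliefs <- lapply(pebs, `[[`, "belief")
  fit_peb(beliefs, x2, pebs[[1]]$beta_prior, settings = settings)
}

#' Significant effects of a PEB model
#'
#' @param peb a fitted `peb_model`.
#' @param pp_threshold report effects with posterior probability strictly
#'   above this value (default 0.95).
#' @return tibble with `effect`, `parameter`, `estimate`, `pp`, `sign`,
#'   sorted by decreasing posterior probability.
#' @export
threshold_effects <- function(peb, pp_threshold = 0.95) {
  tab <- tidy(peb)
  tab[tab$pp > pp_threshold, , drop = FALSE] |>
    dplyr::arrange(dplyr::desc(.data$pp))
}
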
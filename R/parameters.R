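#' Gaussian belief over named parameters
#'
#' The common currency of the package: a multivariate Gaussian over named
#' log-scaling parameters, used for priors, single-subject posteriors and
#' second-level effect posteriors. Parameters act multiplicatively on their
#' prior means (`actual = prior_mean * exp(theta)`), so `theta = 0`
#' reproduces the prior-mean model exactly.
#'
#' @param mean named numeric vector of parameter means.
#' @param cov covariance matrix (symmetric positive semi-definite); a
#'   numeric vector is taken as a diagonal.
#' @param lambda optional named log-precision hyperparameters of the
#'   observation noise (one per source).
#' @param free_energy variational free energy associated with the belief.
#' @param converged logical convergence flag (inversions only).
#' @param meta optional list of provenance metadata.
#' @return an object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, cov, lambda = NULL, free_energy = NA_real_,
                            converged = NA, meta = list()) {
  nm <- names(mean)
  if (is.null(nm) && length(mean) > 0) abort("`mean` must be named")
  if (anyDuplicated(nm)) abort("parameter names must be unique")
  if (!is.matrix(cov)) cov <- diag(as.numeric(cov), length(mean))
  if (!identical(dim(cov), c(length(mean), length(mean))))
    abort("`cov` dimensions do not match `mean`")
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(nm, nm)
  if (length(mean) > 0 && min(eigen(cov, symmetric = TRUE,
                                    only.values = TRUE)$values) < -1e-8)
    abort("`cov` is not positive semi-definite")
  structure(list(mean = mean, cov = cov, lambda = lambda,
                 free_energy = free_energy, converged = converged,
                 meta = meta),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief> %d parameters, F = %s\n", length(x$mean),
              format(x$free_energy, digits = 6)))
  invisible(x)
}

#' @export
length.gaussian_belief <- function(x) length(x$mean)

# subset a belief to a set of parameter names (marginal)
belief_subset <- function(belief, params) {
  miss <- setdiff(params, names(belief$mean))
  if (length(miss) > 0)
    abort(paste("unknown parameters:", paste(miss, collapse = ", ")))
  gaussian_belief(belief$mean[params],
                  belief$cov[params, params, drop = FALSE],
                  lambda = belief$lambda,
                  free_energy = belief$free_energy,
                  converged = belief$converged, meta = belief$meta)
}

#' Prior configuration for the free parameters
#'
#' Selects which parameter groups are free to vary and their prior
#' variances (on the log-scaling scale). The four groups mirror the
#' quantities the group analyses interrogate: the GABAergic intrinsic
#' synapses (six tonic self-connections plus four phasic interneuron
#' efferents, shared across sources), the extrinsic connection gains, the
#' exogenous input (amplitude and latency) and the observation gain.
#'
#' @param free character vector of free parameter classes, a subset of
#'   `c("intrinsic_gabaa", "extrinsic", "input", "observation")`.
#' @param var named numeric vector of prior variances per class;
#'   `input_latency` may be given separately (tighter by default since the
#'   input peak is well localised in time).
#' @export
prior_config <- function(free = c("intrinsic_gabaa", "extrinsic", "input",
                                  "observation"),
                         var = c(intrinsic_gabaa = 1 / 16, extrinsic = 1 / 16,
                                 input = 1 / 16, input_latency = 1 / 64,
                                 observation = 1 / 16)) {
  known <- c("intrinsic_gabaa", "extrinsic", "input", "observation")
  bad <- setdiff(free, known)
  if (length(bad) > 0)
    abort(paste("unknown parameter class:", paste(bad, collapse = ", ")))
  defaults <- c(intrinsic_gabaa = 1 / 16, extrinsic = 1 / 16, input = 1 / 16,
                input_latency = 1 / 64, observation = 1 / 16)
  defaults[names(var)] <- var
  list(free = free, var = defaults)
}

# full parameter table of a network: one row per named log-scaling
# parameter, with the weight-matrix entries it controls.
# Intrinsic GABAergic parameters are shared across the six sources.
cmm_parameter_table <- function(net, config = prior_config()) {
  pops <- cmm_populations()
  src <- net$sources
  nsrc <- length(src)
  npop <- length(pops)
  n <- nsrc * npop
  idx <- function(s, p) (match(s, src) - 1L) * npop + match(p, pops)
  lin <- function(row, col) (col - 1L) * n + row  # 1-based linear index

  rows <- list()
  add <- function(name, class, receptor, entries, bases) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, class = class,
      prior_var = unname(
        if (name == "input:latency") config$var["input_latency"]
        else config$var[class]),
      free = class %in% config$free,
      receptor = receptor,
      entries = list(as.integer(entries)), bases = list(as.numeric(bases)))
  }

  # intrinsic GABAergic synapses: tonic self-connections + phasic efferents,
  # one parameter per synapse type scaling the same entry in every source
  wg <- net$microcircuit$wg
  for (p in pops) {
    e <- vapply(src, function(s) lin(idx(s, p), idx(s, p)), integer(1))
    add(paste0("tonic:", p), "intrinsic_gabaa", "gabaa", e,
        rep(wg[p, p], nsrc))
  }
  phasic <- list(c("si", "ss"), c("si", "sp"), c("di", "dp"), c("di", "tp"))
  for (ph in phasic) {
    e <- vapply(src, function(s) lin(idx(s, ph[2]), idx(s, ph[1])),
                integer(1))
    add(paste0("phasic:", ph[1], "->", ph[2]), "intrinsic_gabaa", "gabaa",
        e, rep(wg[ph[2], ph[1]], nsrc))
  }

  # extrinsic gains: one parameter per directed edge, scaling all its
  # laminar termination entries
  for (i in seq_len(nrow(net$edges))) {
    ed <- net$edges[i, ]
    term <- net$termination[[ed$type]]
    origin <- .ext_origin[[ed$type]]
    e <- vapply(names(term),
                function(tp) lin(idx(ed$to, tp), idx(ed$from, origin)),
                integer(1))
    add(paste0(.ext_tag[[ed$type]], ":", ed$from, "->", ed$to), "extrinsic",
        "extrinsic", e, ed$gain * unname(term))
  }

  add("input:amp", "input", "input", integer(0), numeric(0))
  add("input:latency", "input", "input", integer(0), numeric(0))
  add("obs:gain", "observation", "observation", integer(0), numeric(0))

  dplyr::bind_rows(rows)
}

#' Build Gaussian priors over the model parameters
#'
#' Constructs the prior belief over all free log-scaling parameters of a
#' network: mean zero (so the prior-mean model is reproduced exactly) and a
#' diagonal covariance with per-class variances from the configuration.
#'
#' @param net a [network_spec()].
#' @param config a [prior_config()] selecting free classes and variances.
#' @return a [gaussian_belief()] with a `"param_table"` attribute holding
#'   the parameter bookkeeping used by the compiled model.
#' @export
build_parameter_priors <- function(net, config = prior_config()) {
  tab <- cmm_parameter_table(net, config)
  free <- tab[tab$free, ]
  belief <- gaussian_belief(setNames(rep(0, nrow(free)), free$name),
                            diag(free$prior_var, nrow(free)))
  attr(belief, "param_table") <- tab
  belief
}
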
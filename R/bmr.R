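#' Bayesian model reduction
#'
#' Computes, in closed form and without touching the data, the posterior
#' and change in log evidence of a model whose priors have been changed
#' from `full_prior` to `reduced_prior`, given the posterior obtained under
#' the full prior. Gaussian algebra:
#' reduced posterior precision `Pq = P + Pr - P0`, mean
#' `Pq^-1 (P mu + Pr mr - P0 m0)`, and
#' `dF = 1/2 [ln|P| + ln|Pr| - ln|P0| - ln|Pq|]
#'      + 1/2 [hq' Pq^-1 hq - mu'P mu - mr'Pr mr + m0'P0 m0]`.
#'
#' @param posterior,full_prior,reduced_prior [gaussian_belief()] objects
#'   over the same parameter names.
#' @param ridge ridge added before inverting near-singular covariances.
#' @return list with `posterior` (reduced belief) and `df` (the log
#'   evidence of the reduced model minus that of the full model).
#' @export
bmr_reduce <- function(posterior, full_prior, reduced_prior, ridge = 1e-8) {
  nm <- names(posterior$mean)
  if (!identical(nm, names(full_prior$mean)) ||
      !identical(nm, names(reduced_prior$mean)))
    abort("all three beliefs must share the same parameter names")
  p  <- inv_sym(posterior$cov, ridge)
  p0 <- inv_sym(full_prior$cov, ridge)
  pr <- inv_sym(reduced_prior$cov, ridge)
  pq <- p + pr - p0
  ev <- eigen((pq + t(pq)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    load <- abs(ev$vectors[, which.min(ev$values)])
    worst <- nm[order(load, decreasing = TRUE)][seq_len(min(3, length(nm)))]
    abort(paste0("reduced posterior precision is not positive definite; ",
                 "offending parameters: ", paste(worst, collapse = ", ")))
  }
  sq <- ev$vectors %*% (t(ev$vectors) / ev$values)
  hq <- drop(p %*% posterior$mean + pr %*% reduced_prior$mean -
               p0 %*% full_prior$mean)
  mq <- drop(sq %*% hq)
  df <- 0.5 * (logdet(p) + logdet(pr) - logdet(p0) -
                 sum(log(ev$values))) +
    0.5 * (drop(t(hq) %*% mq) -
             drop(t(posterior$mean) %*% p %*% posterior$mean) -
             drop(t(reduced_prior$mean) %*% pr %*% reduced_prior$mean) +
             drop(t(full_prior$mean) %*% p0 %*% full_prior$mean))
  list(posterior = gaussian_belief(setNames(mq, nm), sq,
                                   free_energy = posterior$free_energy + df),
       df = df)
}

# reduced prior with a set of parameters pinned to zero (near-delta)
pin_prior <- function(prior, params, off_var = 1e-8) {
  idx <- match(params, names(prior$mean))
  if (anyNA(idx)) abort("unknown parameter in `params`")
  m <- prior$mean; m[idx] <- 0
  s <- prior$cov
  s[idx, ] <- 0; s[, idx] <- 0
  diag(s)[idx] <- off_var
  gaussian_belief(m, s)
}

#' Greedy pruning of redundant parameters
#'
#' Repeatedly switches off (pins to zero with a near-delta prior) the
#' candidate parameter whose removal most increases the model evidence, as
#' long as the evidence does not drop by more than `margin` nats. The
#' search order is deterministic: largest evidence gain first, ties broken
#' alphabetically by parameter name. Uses [bmr_reduce()] only, so the data
#' are never revisited.
#'
#' @param posterior posterior [gaussian_belief()] under `prior`.
#' @param prior full prior belief.
#' @param candidate_params names of parameters eligible for removal; empty
#'   input returns the model unchanged.
#' @param margin tolerated evidence loss per removal (nats), default 0.
#' @param off_var pinning variance.
#' @return list with `prior` (final reduced prior), `posterior` (reduced
#'   posterior), `pruned`, `retained`, `df_total` and a `path` tibble of
#'   accepted removals.
#' @export
greedy_prune <- function(posterior, prior, candidate_params, margin = 0,
                         off_var = 1e-8) {
  if (length(candidate_params) == 0)
    return(list(prior = prior, posterior = posterior, pruned = character(0),
                retained = names(prior$mean), df_total = 0,
                path = tibble::tibble(parameter = character(0),
                                      df = numeric(0))))
  pruned <- character(0)
  df_acc <- 0
  path <- list()
  remaining <- sort(candidate_params)
  repeat {
    if (length(remaining) == 0) break
    dfs <- vapply(remaining, function(pn) {
      rp <- pin_prior(prior, c(pruned, pn), off_var)
      bmr_reduce(posterior, prior, rp)$df - df_acc
    }, numeric(1))
    ord <- order(-dfs, names(dfs))
    best <- ord[1]
    if (dfs[best] < -margin) break
    pruned <- c(pruned, remaining[best])
    df_acc <- df_acc + dfs[best]
    path[[length(path) + 1L]] <- tibble::tibble(
      parameter = remaining[best], df = dfs[best])
    remaining <- remaining[-best]
  }
  red_prior <- if (length(pruned) > 0) pin_prior(prior, pruned, off_var)
               else prior
  red <- bmr_reduce(posterior, prior, red_prior)
  list(prior = red_prior, posterior = red$posterior, pruned = pruned,
       retained = setdiff(names(prior$mean), pruned), df_total = red$df,
       path = dplyr::bind_rows(path))
}

#' Compare models by free energy
#'
#' Posterior model probabilities under flat model priors: the softmax of
#' the free energies, with log Bayes factors relative to the best model.
#'
#' @param f numeric vector of free energies (same data).
#' @param labels model labels.
#' @return tibble with `model`, `f`, `log_bf` (F minus best F) and `prob`.
#' @export
compare_evidence <- function(f, labels = names(f) %||%
                               paste0("model", seq_along(f))) {
  if (length(f) < 2) abort("need at least two models to compare")
  lbf <- unname(f - max(f))
  tibble::tibble(model = labels, f = unname(f), log_bf = lbf,
                 prob = exp(lbf) / sum(exp(lbf)))
}
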
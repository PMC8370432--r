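#' Settings for variational Laplace inversion
#'
#' @param max_iter maximum Gauss-Newton iterations (Jacobian evaluations).
#' @param tol_f convergence: free-energy improvement below `tol_f` nats on
#'   `n_converge` consecutive accepted steps.
#' @param n_converge see `tol_f`.
#' @param fd_step central finite-difference step in theta.
#' @param damping0 initial Levenberg-Marquardt damping; doubled on a
#'   rejected step (free-energy decrease), halved on acceptance.
#' @param max_reject rejected trial steps per iteration before giving up.
#' @param restarts number of additional prior-jittered restarts (0 = single
#'   deterministic start at the prior mean); the best final free energy
#'   wins, ties broken by the lowest restart index.
#' @param jacobian_every recompute the finite-difference Jacobian every
#'   this many iterations (1 = every iteration; 2 roughly halves the cost
#'   of an inversion at a small cost in steps, used for cohort-scale runs).
#' @param lowpass_hz,window conditioning applied to model predictions so
#'   they live in the same space as the conditioned data.
#' @param jac_dt_ms integration step (ms) used only inside
#'   finite-difference Jacobians; free-energy evaluations always use the
#'   model's own grid. The fixed-step integrator's step-halving error is
#'   below 1e-3, so a 2 ms Jacobian grid changes Gauss-Newton steps and
#'   posterior curvature negligibly while halving their cost.
#' @param fit_decim_ms spacing (ms) of the samples entering the Gaussian
#'   likelihood. After the 48 Hz low-pass the observation noise
#'   decorrelates over about 10 ms, so evaluating the likelihood on every
#'   millisecond sample would overcount the data by roughly the
#'   oversampling factor and produce overconfident posteriors; 10 ms
#'   spacing makes the white-noise likelihood approximately exact.
#' @export
invert_settings <- function(max_iter = 64, tol_f = 0.01, n_converge = 4,
                            fd_step = 1e-3, damping0 = 1 / 128,
                            max_reject = 16, restarts = 0,
                            jacobian_every = 1, fit_decim_ms = 10,
                            jac_dt_ms = 2,
                            lowpass_hz = 48, window = c(50, 350)) {
  as.list(environment())
}

# build the prediction closure: theta -> conditioned sources x time matrix
# (NULL on integration failure); also a batched version for Jacobians
make_predictor <- function(model, settings) {
  cond <- function(m) {
    if (is.null(m)) return(NULL)
    condition_matrix(m, model$t_grid, settings$lowpass_hz, settings$window)
  }
  list(
    one = function(theta) cond(predict_erf_matrix(model, theta)),
    batch = function(Theta) lapply(predict_erf_matrix(model, Theta), cond)
  )
}

# spec free-energy expression at a Gaussian belief (mu, Sigma):
#   F = -1/2 e'Pi e + 1/2 ln|Pi| - n/2 ln(2 pi)
#       - 1/2 (mu-m0)' Pi0 (mu-m0) - 1/2 ln(|Sigma0|/|Sigma|)
# with Pi the per-source noise precision. Reported complexity is the full
# Gaussian KL[q || prior]; accuracy = F + complexity.
fe_terms <- function(e, lambda, mu, sigma, prior) {
  n <- length(e)
  t_per <- n / length(lambda)
  prec <- rep(exp(lambda), each = t_per)
  p0 <- inv_sym(prior$cov)
  dm <- mu - prior$mean
  f <- -0.5 * sum(prec * e^2) + 0.5 * t_per * sum(lambda) -
    (n / 2) * log(2 * pi) - 0.5 * drop(t(dm) %*% p0 %*% dm) -
    0.5 * (logdet(prior$cov) - logdet(sigma))
  kl <- gaussian_kl(mu, sigma, prior$mean, prior$cov)
  list(f = f, accuracy = f + kl, complexity = kl)
}

#' Variational free energy at a parameter point
#'
#' Evaluates the Laplace free energy, its gradient and Gauss-Newton
#' curvature at a parameter value, for a compiled network model or any
#' prediction function. The free energy decomposes as
#' `F = accuracy - complexity` with complexity the Gaussian
#' Kullback-Leibler divergence between the belief and the prior.
#'
#' @param theta named parameter vector (the belief point).
#' @param data conditioned data: sources x time matrix (or numeric vector
#'   for a generic model).
#' @param model a `cmm_model` or a function `theta -> prediction` returning
#'   a matrix/vector shaped like `data` (or `NULL` on failure).
#' @param priors prior [gaussian_belief()].
#' @param lambda per-source noise log-precisions (recycled if length 1).
#' @param sigma posterior covariance at which to evaluate F; when `NULL`
#'   the Gauss-Newton covariance `(J' Pi J + Pi0)^-1` at `theta` is used.
#' @param settings [invert_settings()] (finite-difference step,
#'   conditioning).
#' @return list with `f`, `accuracy`, `complexity`, `gradient`,
#'   `curvature`, `sigma`. On integration failure `f` is `-Inf` and a
#'   `diagnostic` message is included.
#' @export
free_energy <- function(theta, data, model, priors, lambda = 4,
                        sigma = NULL, settings = invert_settings()) {
  generic <- is.function(model)
  pred <- if (generic) {
    list(one = model,
         batch = function(Theta) apply(Theta, 2, model, simplify = FALSE))
  } else make_predictor(model, settings)
  # the likelihood is evaluated on the decimated grid for network models
  # (conditioned noise is correlated at 1 ms spacing); generic prediction
  # functions are taken at face value
  flatten <- if (generic) function(m) as.numeric(t(m))
             else make_flatten(model$t_grid,
                               if (is.matrix(data)) nrow(data) else 1L,
                               settings$fit_decim_ms)
  theta <- theta[names(priors$mean)]
  y <- flatten(data)
  n_src <- if (is.matrix(data)) nrow(data) else 1L
  lambda <- rep(lambda, length.out = n_src)
  mu_hat <- pred$one(theta)
  if (is.null(mu_hat))
    return(list(f = -Inf, accuracy = -Inf, complexity = NA_real_,
                gradient = NULL, curvature = NULL, sigma = NULL,
                diagnostic = "integration failed at the evaluation point"))
  e <- y - flatten(mu_hat)
  J <- fd_jacobian(pred, theta, settings$fd_step, flatten, length(y))
  prec <- rep(exp(lambda), each = length(y) / n_src)
  p0 <- inv_sym(priors$cov)
  h <- crossprod(J, J * prec) + p0
  g <- drop(crossprod(J, e * prec)) - drop(p0 %*% (theta - priors$mean))
  if (is.null(sigma)) sigma <- inv_sym(h)
  out <- fe_terms(e, lambda, theta, sigma, priors)
  c(out, list(gradient = g, curvature = h, sigma = sigma))
}

# flatten a sources x time matrix to the stacked likelihood vector,
# keeping every `decim_ms` milliseconds
make_flatten <- function(t_grid, n_src, decim_ms) {
  dt <- diff(t_grid[1:2])
  sel <- seq(1, length(t_grid), by = max(1L, round(decim_ms / dt)))
  T <- length(t_grid)
  idx <- as.vector(outer(sel, (seq_len(n_src) - 1L) * T, `+`))
  structure(function(m) as.numeric(t(m))[idx], n_sel = length(sel))
}

# central finite-difference Jacobian, batched through the predictor
fd_jacobian <- function(pred, theta, h, flatten, n_out) {
  p <- length(theta)
  if (p == 0) return(matrix(0, n_out, 0))
  Theta <- matrix(theta, length(theta), 2 * p)
  for (k in seq_len(p)) {
    Theta[k, 2 * k - 1] <- theta[k] + h
    Theta[k, 2 * k] <- theta[k] - h
  }
  preds <- pred$batch(Theta)
  if (any(vapply(preds, is.null, logical(1))))
    abort("integration failed while computing the Jacobian",
          class = "microdcm_divergence")
  J <- matrix(0, n_out, p, dimnames = list(NULL, names(theta)))
  for (k in seq_len(p))
    J[, k] <- (flatten(preds[[2 * k - 1]]) - flatten(preds[[2 * k]])) /
      (2 * h)
  J
}

# one guarded Newton update of the per-source noise log-precisions;
# returns new lambda (maximises the lambda-likelihood, shrunk to the prior)
update_lambda <- function(lambda, sse, t_per, prior) {
  lp_m <- prior[["mean"]]; lp_v <- prior[["var"]]
  for (it in 1:3) {
    g <- t_per / 2 - exp(lambda) * sse / 2 - (lambda - lp_m) / lp_v
    hgrad <- -exp(lambda) * sse / 2 - 1 / lp_v
    lambda <- lambda - g / hgrad
  }
  lambda
}

#' Invert a subject-condition ERF by variational Laplace
#'
#' Fits the generative model to one conditioned ERF by Gauss-Newton ascent
#' on the variational free energy with Levenberg-Marquardt damping,
#' alternated with closed-form updates of the per-source noise
#' log-precision. Deterministic given data, priors and settings. The
#' accepted-step free-energy sequence is non-decreasing by construction and
#' is returned for inspection.
#'
#' @param data conditioned ERF for one subject/session/condition: long
#'   tibble or sources x time matrix (see [condition_erf()]).
#' @param model a [compile_cmm()] model.
#' @param priors prior [gaussian_belief()] from [build_parameter_priors()];
#'   defaults to the model's own priors.
#' @param settings an [invert_settings()] list.
#' @return an object of class `cmm_fit`: `posterior` (a
#'   [gaussian_belief()] with noise hyperposteriors and final free energy),
#'   `f_trace`, `converged`, `iterations`, per-source fit correlations and
#'   the conditioned data/prediction matrices.
#' @export
invert_erf <- function(data, model, priors = NULL,
                       settings = invert_settings()) {
  if (!inherits(model, "cmm_model")) abort("`model` must be a cmm_model")
  priors <- priors %||% model$priors
  y_mat <- if (is.matrix(data)) data else erf_tibble_to_matrix(data)
  if (!identical(ncol(y_mat), length(model$t_grid)))
    abort("data time axis does not match the model grid")
  pred <- make_predictor(model, settings)
  n_src <- nrow(y_mat)
  flatten <- make_flatten(model$t_grid, n_src, settings$fit_decim_ms)
  y <- flatten(y_mat)
  t_per <- attr(flatten, "n_sel")
  # coarser integration grid for Jacobians only (see invert_settings)
  dt0 <- diff(model$t_grid[1:2])
  if (settings$jac_dt_ms > dt0 &&
      settings$fit_decim_ms %% settings$jac_dt_ms == 0) {
    model_j <- model
    model_j$t_grid <- seq(min(model$t_grid), max(model$t_grid),
                          by = settings$jac_dt_ms)
    pred_j <- make_predictor(model_j, settings)
    flatten_j <- make_flatten(model_j$t_grid, n_src, settings$fit_decim_ms)
  } else {
    pred_j <- pred
    flatten_j <- flatten
  }
  lp <- model$obs$lambda_prior
  p0 <- inv_sym(priors$cov)
  pnames <- names(priors$mean)

  run_once <- function(theta0) {
    theta <- theta0
    lambda <- rep(lp[["mean"]], n_src)
    mu_hat <- pred$one(theta)
    if (is.null(mu_hat))
      return(list(ok = FALSE, diagnostic = "integration failed at start"))
    e <- y - flatten(mu_hat)
    # initialise noise log-precisions from the prior-mean residuals so the
    # first Gauss-Newton steps are on the right scale
    lambda <- update_lambda(lambda,
                            rowSums(matrix(e^2, n_src, t_per, byrow = TRUE)),
                            t_per, lp)
    damping <- settings$damping0
    f_trace <- numeric(0)
    f_cur <- -Inf
    sigma <- priors$cov
    n_small <- 0L
    converged <- FALSE
    iter <- 0L
    J <- NULL
    J_last <- NULL
    j_fresh <- FALSE
    j_age <- 0L
    while (iter < settings$max_iter && !converged) {
      iter <- iter + 1L
      if (is.null(J) || j_age >= settings$jacobian_every) {
        J <- tryCatch(fd_jacobian(pred_j, theta, settings$fd_step,
                                  flatten_j, length(y)),
                      microdcm_divergence = function(e) NULL)
        if (is.null(J)) {
          # finite-difference probe left the stable region: keep the
          # current point and stop rather than fail the whole fit
          if (length(f_trace) > 0) { J <- J_last; break }
          return(list(ok = FALSE,
                      diagnostic = "integration failed near the start"))
        }
        J_last <- J
        j_fresh <- TRUE
        j_age <- 0L
      } else {
        j_fresh <- FALSE
      }
      j_age <- j_age + 1L
      prec <- rep(exp(lambda), each = t_per)
      h <- crossprod(J, J * prec) + p0
      g <- drop(crossprod(J, e * prec)) - drop(p0 %*% (theta - priors$mean))
      if (!is.finite(f_cur)) {
        sigma <- inv_sym(h)
        f_cur <- fe_terms(e, lambda, theta, sigma, priors)$f
      }
      # Levenberg-Marquardt damping ladder, starting a notch below the
      # last accepted damping: keep the best improving trial step, stop
      # once past the ladder's optimum (trial steps cost one integration
      # each, cheap next to the Jacobian)
      accepted <- FALSE
      sigma_new <- inv_sym(h)
      best <- NULL
      d_try <- damping / 4
      for (try in seq_len(settings$max_reject)) {
        h_lm <- h + d_try * diag(diag(h), nrow(h))
        step <- drop(solve(h_lm, g))
        theta_new <- theta + step
        mu_new <- pred$one(theta_new)
        if (!is.null(mu_new)) {
          e_new <- y - flatten(mu_new)
          f_new <- fe_terms(e_new, lambda, theta_new, sigma_new, priors)$f
          if (is.finite(f_new) && f_new > f_cur &&
              (is.null(best) || f_new > best$f)) {
            best <- list(theta = theta_new, e = e_new, f = f_new,
                         damping = d_try)
          } else if (!is.null(best)) break  # past the optimum of the ladder
        }
        d_try <- d_try * 2
      }
      if (!is.null(best)) {
        # noise hyperparameter update, kept only if it raises F
        sse <- rowSums(matrix(best$e^2, n_src, t_per, byrow = TRUE))
        lam_try <- update_lambda(lambda, sse, t_per, lp)
        f_lam <- fe_terms(best$e, lam_try, best$theta, sigma_new, priors)$f
        if (is.finite(f_lam) && f_lam > best$f) {
          lambda <- lam_try; best$f <- f_lam
        }
        if (best$f - f_cur < settings$tol_f) n_small <- n_small + 1L
        else n_small <- 0L
        theta <- best$theta; e <- best$e; sigma <- sigma_new
        f_cur <- best$f
        f_trace <- c(f_trace, f_cur)
        damping <- best$damping
        accepted <- TRUE
      }
      # convergence and stuck states only count against a fresh Jacobian:
      # with a stale one, recompute and try again before deciding
      if (!accepted || n_small >= settings$n_converge) {
        if (j_fresh) {
          if (accepted || length(f_trace) > 0) converged <- TRUE
          else break  # no improving step from the start
        } else {
          J <- NULL
          if (!accepted) n_small <- 0L
        }
      }
    }
    # polish with exact-grid Jacobian steps, then the final posterior
    # covariance at the accepted point (also exact grid)
    polish <- 0L
    while (polish < 4L) {
      polish <- polish + 1L
      J_try <- tryCatch(fd_jacobian(pred, theta, settings$fd_step, flatten,
                                    length(y)),
                        microdcm_divergence = function(e) NULL)
      if (is.null(J_try)) break
      J <- J_try
      prec <- rep(exp(lambda), each = t_per)
      h <- crossprod(J, J * prec) + p0
      g <- drop(crossprod(J, e * prec)) - drop(p0 %*% (theta - priors$mean))
      sigma_new <- inv_sym(h)
      f_cur <- fe_terms(e, lambda, theta, sigma_new, priors)$f
      best <- NULL
      d_try <- damping / 4
      for (try in seq_len(settings$max_reject)) {
        h_lm <- h + d_try * diag(diag(h), nrow(h))
        theta_new <- theta + drop(solve(h_lm, g))
        mu_new <- pred$one(theta_new)
        if (!is.null(mu_new)) {
          e_new <- y - flatten(mu_new)
          f_new <- fe_terms(e_new, lambda, theta_new, sigma_new, priors)$f
          if (is.finite(f_new) && f_new > f_cur &&
              (is.null(best) || f_new > best$f))
            best <- list(theta = theta_new, e = e_new, f = f_new)
          else if (!is.null(best)) break
        }
        d_try <- d_try * 2
      }
      if (is.null(best)) break
      gain <- best$f - f_cur
      theta <- best$theta; e <- best$e
      # the polish objective is re-based on the exact-grid sigma, so only
      # extend the accepted-step trace where it actually increases
      if (length(f_trace) == 0 || best$f > f_trace[length(f_trace)])
        f_trace <- c(f_trace, best$f)
      if (gain < settings$tol_f) break
    }
    prec <- rep(exp(lambda), each = t_per)
    sigma <- inv_sym(crossprod(J, J * prec) + p0)
    f_final <- fe_terms(e, lambda, theta, sigma, priors)$f
    list(ok = length(f_trace) > 0 || converged, theta = theta,
         sigma = sigma, lambda = lambda, f = f_final, f_trace = f_trace,
         converged = converged && length(f_trace) > 0, iterations = iter)
  }

  starts <- list(priors$mean)
  if (settings$restarts > 0) {
    sdv <- sqrt(diag(priors$cov))
    extra <- with_local_seed(1L, lapply(seq_len(settings$restarts),
      function(k) priors$mean + 0.5 * sdv * rnorm(length(priors$mean))))
    starts <- c(starts, extra)
  }
  runs <- lapply(starts, run_once)
  fs <- vapply(runs, function(r) if (isTRUE(r$ok)) r$f else -Inf, numeric(1))
  best <- which.max(fs)  # ties broken by lowest index
  r <- runs[[best]]

  if (!isTRUE(r$ok)) {
    post <- gaussian_belief(priors$mean, priors$cov,
                            lambda = setNames(rep(lp[["mean"]], n_src),
                                              rownames(y_mat)),
                            free_energy = -Inf, converged = FALSE)
    return(structure(list(posterior = post, f_trace = numeric(0),
                          converged = FALSE, iterations = 0L,
                          data = y_mat, predicted = NULL, stats = NULL,
                          model = model, priors = priors,
                          settings = settings),
                     class = "cmm_fit"))
  }
  predicted <- pred$one(r$theta)
  stats <- erf_fit_statistics(erf_matrix_to_tibble(y_mat, model$t_grid),
                              erf_matrix_to_tibble(predicted, model$t_grid))
  post <- gaussian_belief(setNames(r$theta, pnames), r$sigma,
                          lambda = setNames(r$lambda, rownames(y_mat)),
                          free_energy = r$f, converged = r$converged)
  structure(list(posterior = post, f_trace = r$f_trace,
                 converged = r$converged, iterations = r$iterations,
                 data = y_mat, predicted = predicted, stats = stats,
                 model = model, priors = priors, settings = settings),
            class = "cmm_fit")
}

#' @export
print.cmm_fit <- function(x, ...) {
  cat(sprintf("<cmm_fit> F = %s, %s after %d iterations, median r = %s\n",
              format(x$posterior$free_energy, digits = 6),
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$iterations,
              if (is.null(x$stats)) "NA"
              else format(x$stats$summary$median_r, digits = 3)))
  invisible(x)
}

#' Predict from a fitted model
#'
#' Generates the ERF at the posterior mean (the prediction depends only on
#' the mean, not the posterior covariance) and its fit statistics against
#' the fitted data.
#'
#' @param object a `cmm_fit`.
#' @param ... unused.
#' @return list with `erf` (tibble), `matrix` (sources x time) and `stats`
#'   ([erf_fit_statistics()]).
#' @export
predict.cmm_fit <- function(object, ...) {
  pred <- make_predictor(object$model, object$settings)
  m <- pred$one(object$posterior$mean)
  stats <- erf_fit_statistics(
    erf_matrix_to_tibble(object$data, object$model$t_grid),
    erf_matrix_to_tibble(m, object$model$t_grid))
  list(erf = erf_matrix_to_tibble(m, object$model$t_grid), matrix = m,
       stats = stats)
}
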
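# conjugate linear-Gaussian toys: the Laplace free energy at the exact
# posterior must equal the closed-form log marginal likelihood

make_toy <- function(seed, n = 40, p = 3) {
  set.seed(seed)
  J <- matrix(rnorm(n * p), n, p)
  prec <- exp(runif(1, 0, 2))
  m0 <- rnorm(p, 0, 0.5)
  s0 <- diag(runif(p, 0.2, 1))
  theta_true <- m0 + rnorm(p, 0, 0.3)
  y <- drop(J %*% theta_true) + rnorm(n, 0, 1 / sqrt(prec))
  nm <- paste0("b", seq_len(p))
  list(J = J, prec = prec, y = y,
       priors = gaussian_belief(setNames(m0, nm), s0),
       model = function(th) drop(J %*% th))
}

test_that("free energy equals the analytic log evidence on linear toys", {
  for (seed in 1:5) {
    toy <- make_toy(seed)
    post <- oracle_posterior(toy$y, toy$J, toy$prec, toy$priors$mean,
                             toy$priors$cov)
    fe <- free_energy(setNames(post$mean, names(toy$priors$mean)),
                      toy$y, toy$model, toy$priors,
                      lambda = log(toy$prec), sigma = post$cov)
    ref <- oracle_log_evidence(toy$y, toy$J, rep(toy$prec, length(toy$y)),
                               toy$priors$mean, toy$priors$cov)
    expect_equal(fe$f, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("reported complexity is the Gaussian KL from the prior", {
  toy <- make_toy(11)
  post <- oracle_posterior(toy$y, toy$J, toy$prec, toy$priors$mean,
                           toy$priors$cov)
  fe <- free_energy(setNames(post$mean, names(toy$priors$mean)),
                    toy$y, toy$model, toy$priors, lambda = log(toy$prec),
                    sigma = post$cov)
  kl <- oracle_kl(post$mean, post$cov, toy$priors$mean, toy$priors$cov)
  expect_equal(fe$complexity, as.numeric(kl), tolerance = 1e-8)
  expect_gte(fe$complexity, 0)
  expect_equal(fe$f, fe$accuracy - fe$complexity, tolerance = 1e-10)
})

test_that("belief at the prior with zero residuals has zero complexity", {
  toy <- make_toy(12)
  y0 <- drop(toy$J %*% toy$priors$mean)
  fe <- free_energy(toy$priors$mean, y0, toy$model, toy$priors,
                    lambda = log(toy$prec), sigma = toy$priors$cov)
  expect_equal(fe$complexity, 0, tolerance = 1e-12)
})

test_that("redundant parameters do not raise, duplicates strictly lower F", {
  toy <- make_toy(13)
  nm <- names(toy$priors$mean)
  # a parameter with no effect on predictions leaves the evidence unchanged
  priors_plus <- gaussian_belief(c(toy$priors$mean, unused = 0),
                                 diag(c(diag(toy$priors$cov), 0.5)))
  model_plus <- function(th) drop(toy$J %*% th[1:3])
  post <- oracle_posterior(toy$y, cbind(toy$J, 0), toy$prec,
                           priors_plus$mean, priors_plus$cov)
  fe_plus <- free_energy(setNames(post$mean, names(priors_plus$mean)),
                         toy$y, model_plus, priors_plus,
                         lambda = log(toy$prec), sigma = post$cov)
  post0 <- oracle_posterior(toy$y, toy$J, toy$prec, toy$priors$mean,
                            toy$priors$cov)
  fe0 <- free_energy(setNames(post0$mean, nm), toy$y, toy$model,
                     toy$priors, lambda = log(toy$prec), sigma = post0$cov)
  expect_lte(fe_plus$f, fe0$f + 1e-6)
  # duplicating an active predictor costs evidence (complexity penalty)
  J_dup <- cbind(toy$J, toy$J[, 1])
  priors_dup <- gaussian_belief(c(toy$priors$mean, dup = 0),
                                diag(c(diag(toy$priors$cov), 0.5)))
  ref_dup <- oracle_log_evidence(toy$y, J_dup,
                                 rep(toy$prec, length(toy$y)),
                                 priors_dup$mean, priors_dup$cov)
  ref0 <- oracle_log_evidence(toy$y, toy$J, rep(toy$prec, length(toy$y)),
                              toy$priors$mean, toy$priors$cov)
  post_dup <- oracle_posterior(toy$y, J_dup, toy$prec, priors_dup$mean,
                               priors_dup$cov)
  fe_dup <- free_energy(setNames(post_dup$mean, names(priors_dup$mean)),
                        toy$y, function(th) drop(J_dup %*% th),
                        priors_dup, lambda = log(toy$prec),
                        sigma = post_dup$cov)
  expect_equal(fe_dup$f, as.numeric(ref_dup), tolerance = 1e-6)
  expect_lt(fe_dup$f, fe0$f)
  expect_lt(as.numeric(ref_dup), as.numeric(ref0))
})

test_that("integration failure yields a -Inf sentinel with diagnostics", {
  toy <- make_toy(14)
  fe <- free_energy(toy$priors$mean, toy$y, function(th) NULL, toy$priors,
                    lambda = log(toy$prec))
  expect_identical(fe$f, -Inf)
  expect_match(fe$diagnostic, "failed")
})
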
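test_that("reducing to the same prior changes nothing", {
  nm <- c("a", "b", "c")
  post <- random_belief(nm, 1)
  prior <- gaussian_belief(setNames(rep(0, 3), nm), diag(0.5, 3))
  red <- bmr_reduce(post, prior, prior)
  expect_equal(red$df, 0, tolerance = 1e-10)
  expect_equal(red$posterior$mean, post$mean, tolerance = 1e-8)
  expect_equal(red$posterior$cov, post$cov, tolerance = 1e-8)
})

test_that("reduction evidence matches the analytic difference", {
  # linear-Gaussian model fitted under a full prior; the evidence change of
  # any reduced prior is computed directly from marginal likelihoods
  for (seed in 1:10) {
    set.seed(seed)
    p <- sample(2:5, 1)
    n <- 30
    J <- matrix(rnorm(n * p), n, p)
    prec <- rep(2, n)
    m0 <- rnorm(p, 0, 0.3)
    s0 <- diag(runif(p, 0.2, 1))
    y <- drop(J %*% (m0 + rnorm(p, 0, 0.4))) + rnorm(n, 0, 1 / sqrt(2))
    nm <- paste0("t", 1:p)
    post <- oracle_posterior(y, J, 2, m0, s0)
    posterior <- gaussian_belief(setNames(post$mean, nm), post$cov)
    prior <- gaussian_belief(setNames(m0, nm), s0)
    s0r <- s0 * runif(p, 0.1, 1)
    m0r <- m0 * 0.5
    reduced <- gaussian_belief(setNames(m0r, nm), s0r)
    df_pkg <- bmr_reduce(posterior, prior, reduced)$df
    df_ref <- oracle_log_evidence(y, J, prec, m0r, s0r) -
      oracle_log_evidence(y, J, prec, m0, s0)
    expect_equal(df_pkg, as.numeric(df_ref), tolerance = 1e-6)
    # the reduced posterior matches a direct fit under the reduced prior
    red <- bmr_reduce(posterior, prior, reduced)
    direct <- oracle_posterior(y, J, 2, m0r, s0r)
    expect_equal(unname(red$posterior$mean), direct$mean,
                 tolerance = 1e-6)
  }
})

test_that("pinning a parameter reproduces the Savage-Dickey ratio", {
  set.seed(3)
  nm <- c("a", "b", "c")
  prior <- gaussian_belief(setNames(rep(0, 3), nm), diag(c(0.3, 0.5, 0.4)))
  post <- random_belief(nm, 5)
  red <- microdcm:::pin_prior(prior, "b", off_var = 1e-10)
  df <- bmr_reduce(post, prior, red)$df
  # marginal density ratio at zero (prior independence over parameters)
  sd_ref <- log(stats::dnorm(0, post$mean["b"], sqrt(post$cov["b", "b"]))) -
    log(stats::dnorm(0, 0, sqrt(0.5)))
  expect_equal(df, as.numeric(sd_ref), tolerance = 1e-4)
})

test_that("non-positive-definite reductions name the offending parameters", {
  nm <- c("a", "b")
  # posterior broader than the prior makes the reduction ill-posed when the
  # reduced prior removes all regularisation
  post <- gaussian_belief(setNames(c(0.1, 0), nm), diag(2, 2))
  prior <- gaussian_belief(setNames(c(0, 0), nm), diag(0.5, 2))
  loose <- gaussian_belief(setNames(c(0, 0), nm), diag(100, 2))
  expect_error(bmr_reduce(post, prior, loose), "offending")
  expect_error(bmr_reduce(post, prior,
                          gaussian_belief(setNames(0, "a"),
                                          matrix(0.5))),
               "same parameter names")
})

test_that("greedy pruning removes irrelevant parameters and keeps strong ones", {
  nm <- c("strong", "weak", "null")
  prior <- gaussian_belief(setNames(rep(0, 3), nm), diag(0.25, 3))
  # posterior: strong parameter 3 prior SD from zero with tight variance;
  # null parameter sits at zero with data-dominated precision
  post <- gaussian_belief(setNames(c(1.5, 0.02, 0.001), nm),
                          diag(c(0.01, 0.02, 0.01)))
  pr <- greedy_prune(post, prior, nm)
  expect_true("strong" %in% pr$retained)
  expect_true("null" %in% pr$pruned)
  expect_true(all(pr$path$df >= 0))
  # empty candidate list returns the model unchanged
  pr0 <- greedy_prune(post, prior, character(0))
  expect_identical(pr0$pruned, character(0))
  expect_equal(pr0$df_total, 0)
  expect_identical(pr0$posterior$mean, post$mean)
})

test_that("commuting reductions accumulate evidence additively", {
  # with independent (diagonal) beliefs, pinning two parameters jointly
  # must equal the sum of pinning each alone
  nm <- paste0("p", 1:4)
  prior <- gaussian_belief(setNames(rep(0, 4), nm), diag(0.25, 4))
  post <- gaussian_belief(setNames(c(0.9, 0.005, -0.003, 0.3), nm),
                          diag(c(0.01, 0.02, 0.015, 0.02)))
  pin <- microdcm:::pin_prior
  df_joint <- bmr_reduce(post, prior, pin(prior, c("p2", "p3")))$df
  df_each <- bmr_reduce(post, prior, pin(prior, "p2"))$df +
    bmr_reduce(post, prior, pin(prior, "p3"))$df
  expect_equal(df_joint, df_each, tolerance = 1e-6)
  # and the greedy path total matches its own accumulated increments
  pr <- greedy_prune(post, prior, nm)
  expect_equal(pr$df_total, sum(pr$path$df), tolerance = 1e-8)
})

test_that("model comparison is the softmax of free energies", {
  cmp <- compare_evidence(c(m1 = -100, m2 = -100))
  expect_equal(cmp$prob, c(0.5, 0.5))
  cmp2 <- compare_evidence(c(a = 0, b = 3))
  expect_equal(cmp2$prob[2] / cmp2$prob[1], exp(3), tolerance = 1e-9)
  set.seed(2)
  cmp3 <- compare_evidence(rnorm(5, -50, 5))
  expect_equal(sum(cmp3$prob), 1, tolerance = 1e-12)
  expect_error(compare_evidence(-3), "two models")
})
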
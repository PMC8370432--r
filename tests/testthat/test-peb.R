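# small helper: first-level beliefs for a constructed cohort with known
# second-level structure theta_i = X beta + noise
make_beliefs <- function(theta_mat, post_sd = 0.05) {
  lapply(seq_len(nrow(theta_mat)), function(i)
    gaussian_belief(theta_mat[i, ], diag(post_sd^2, ncol(theta_mat))))
}

peb_prior <- function(nm, var = 1 / 16)
  gaussian_belief(setNames(rep(0, length(nm)), nm), diag(var, length(nm)))

test_that("design matrix builder produces the documented contrasts", {
  d <- tibble::tibble(
    subject = rep(c("a", "b", "c", "d", "e", "f"), each = 2),
    session = rep(c("placebo", "tiagabine"), 6),
    group = rep(c("control", "PSP", "bvFTD"), each = 4),
    gaba = rep(c(1.1, 1.05, 0.9, 0.82, 0.7, 0.78), each = 2))
  x <- peb_design(d, c("drug", "cvp", "pvb", "gaba", "gaba:drug"))
  expect_identical(colnames(x),
                   c("mean", "drug", "cvp", "pvb", "gaba", "gaba:drug"))
  expect_true(all(x[, "mean"] == 1))
  expect_identical(unname(x[, "drug"]), rep(c(-1, 1), 6))
  expect_identical(unname(x[, "cvp"]), rep(c(1, -1, -1), each = 4))
  expect_identical(unname(x[, "pvb"]), rep(c(0, 1, -1), each = 4))
  expect_equal(mean(x[, "gaba"]), 0, tolerance = 1e-12)
  expect_equal(sd(x[, "gaba"]), 1, tolerance = 1e-12)
  expect_equal(unname(x[, "gaba:drug"]), unname(x[, "gaba"] * x[, "drug"]))
  expect_error(peb_design(d, "nonsense"), "unknown design term")
  d2 <- d; d2$gaba[1] <- NA
  expect_error(peb_design(d2, "gaba"), "missing GABA")
})

test_that("rank-deficient designs are rejected with the columns named", {
  x <- cbind(mean = rep(1, 6), a = rep(c(1, -1), 3), b = rep(c(1, -1), 3))
  expect_error(fit_peb(make_beliefs(matrix(0, 6, 2,
                                           dimnames = list(NULL,
                                                           c("p1", "p2")))),
                       x, peb_prior(c("p1", "p2"))),
               "collinear column\\(s\\): b")
})

test_that("a mean-only PEB of identical subjects returns their mean", {
  nm <- c("p1", "p2", "p3")
  mu <- c(0.12, -0.3, 0.04)
  theta <- matrix(rep(mu, each = 12), 12, dimnames = list(NULL, nm))
  beliefs <- make_beliefs(theta, post_sd = 0.01)
  x <- cbind(mean = rep(1, 12))
  # wide first-level and effect priors isolate the empirical-Bayes
  # algebra from prior-stripping and second-level shrinkage
  peb <- fit_peb(beliefs, x, peb_prior(nm, var = 1e4),
                 settings = peb_settings(beta_prior_scale = 1e2))
  expect_equal(unname(peb$beta[, "mean"]), mu, tolerance = 1e-6)
})

test_that("mismatched posterior names are rejected", {
  b1 <- gaussian_belief(c(a = 0, b = 0), diag(0.1, 2))
  b2 <- gaussian_belief(c(a = 0, c = 0), diag(0.1, 2))
  expect_error(fit_peb(list(b1, b2), cbind(mean = c(1, 1)),
                       peb_prior(c("a", "b"))),
               "share parameter names")
})

test_that("an injected group effect is detected at the right cell", {
  set.seed(21)
  nm <- paste0("p", 1:6)
  n <- 40
  grp <- rep(c(1, -1), each = n / 2)
  theta <- matrix(rnorm(n * 6, 0, 0.05), n, dimnames = list(NULL, nm))
  theta[, "p3"] <- theta[, "p3"] + 0.12 * grp
  beliefs <- make_beliefs(theta)
  x <- cbind(mean = rep(1, n), grp = grp)
  peb <- fit_peb(beliefs, x, peb_prior(nm))
  expect_gt(peb$pp["p3", "grp"], 0.95)
  expect_gt(peb$beta["p3", "grp"], 0)
  # sign antisymmetry under label swap
  x2 <- cbind(mean = rep(1, n), grp = -grp)
  peb2 <- fit_peb(beliefs, x2, peb_prior(nm))
  expect_equal(unname(peb2$beta[, "grp"]), unname(-peb$beta[, "grp"]),
               tolerance = 1e-6)
  # cells without effects stay quiet
  expect_lt(max(peb$pp[c("p1", "p2", "p4", "p5", "p6"), "grp"]), 0.95)
})

test_that("an all-zero effect column carries no evidence", {
  set.seed(22)
  nm <- c("q1", "q2")
  theta <- matrix(rnorm(20 * 2, 0, 0.05), 20, dimnames = list(NULL, nm))
  x <- cbind(mean = rep(1, 20), nothing = rep(0, 20))
  peb <- fit_peb(make_beliefs(theta), x, peb_prior(nm))
  expect_true(all(peb$pp[, "nothing"] <= 0.5 + 1e-6))
})

test_that("PEB-of-PEBs finds no difference between identical models", {
  set.seed(23)
  nm <- c("p1", "p2")
  theta <- matrix(rnorm(16 * 2, 0, 0.05), 16, dimnames = list(NULL, nm))
  beliefs <- make_beliefs(theta)
  x <- cbind(mean = rep(1, 16))
  peb <- fit_peb(beliefs, x, peb_prior(nm))
  p3 <- peb_of_pebs(list(peb, peb), cbind(mean = c(1, 1),
                                          diff = c(1, -1)))
  expect_lt(max(abs(p3$beta[, "diff"])), 1e-6)
  expect_true(all(p3$pp[, "diff"] <= 0.5 + 1e-6))
})

test_that("PEB-of-PEBs is invariant to joint reordering", {
  set.seed(24)
  nm <- c("p1", "p2")
  mk <- function(shift) {
    theta <- matrix(rnorm(16 * 2, 0, 0.05), 16, dimnames = list(NULL, nm))
    theta[, 1] <- theta[, 1] + shift
    fit_peb(make_beliefs(theta), cbind(mean = rep(1, 16)), peb_prior(nm))
  }
  pa <- mk(0.1); pb <- mk(-0.1); pc <- mk(0)
  x2 <- cbind(mean = c(1, 1, 1), c1 = c(1, -1, 0), c2 = c(0, 1, -1))
  r1 <- peb_of_pebs(list(pa, pb, pc), x2)
  r2 <- peb_of_pebs(list(pc, pa, pb), x2[c(3, 1, 2), ])
  expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
  expect_equal(r1$free_energy, r2$free_energy, tolerance = 1e-6)
})

test_that("opposing drug effects appear as a third-level interaction", {
  set.seed(25)
  nm <- paste0("p", 1:4)
  mk_group <- function(drug_effect, n = 24) {
    drug <- rep(c(-1, 1), n / 2)
    theta <- matrix(rnorm(n * 4, 0, 0.05), n, dimnames = list(NULL, nm))
    theta[, "p2"] <- theta[, "p2"] + drug_effect * drug
    fit_peb(make_beliefs(theta),
            cbind(mean = rep(1, n), drug = drug), peb_prior(nm))
  }
  pebs <- list(ctrl = mk_group(0), psp = mk_group(0.12),
               ftd = mk_group(-0.12))
  x2 <- cbind(mean = c(1, 1, 1), cvp = c(1, -1, -1), pvb = c(0, 1, -1))
  p3 <- peb_of_pebs(pebs, x2)
  expect_gt(p3$pp["drug|p2", "pvb"], 0.95)
  expect_gt(p3$beta["drug|p2", "pvb"], 0)
  # no spurious main drug effect (they cancel across groups)
  expect_lt(p3$pp["drug|p2", "mean"], 0.95)
})

test_that("threshold_effects filters at the requested level", {
  set.seed(26)
  nm <- c("p1", "p2")
  theta <- matrix(rnorm(20 * 2, 0, 0.05), 20, dimnames = list(NULL, nm))
  theta[, 1] <- theta[, 1] + 0.15
  peb <- fit_peb(make_beliefs(theta), cbind(mean = rep(1, 20)),
                 peb_prior(nm))
  expect_identical(nrow(threshold_effects(peb, 1)), 0L)
  expect_identical(nrow(threshold_effects(peb, 0)), 2L)
  tab <- threshold_effects(peb, 0.95)
  expect_true(all(tab$pp > 0.95))
  expect_true(all(c("effect", "parameter", "estimate", "pp", "sign") %in%
                    names(tab)))
})
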
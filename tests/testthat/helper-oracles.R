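# Independent analytic oracles used across the suite. These deliberately
# re-derive every quantity from first principles (base R only) so they can
# serve as references for the package's implementations.

# exact log marginal likelihood of the linear-Gaussian model
#   y = J theta + e,  e ~ N(0, diag(1/prec)),  theta ~ N(m0, s0)
oracle_log_evidence <- function(y, J, prec, m0, s0) {
  n <- length(y)
  sy <- diag(1 / prec, n) + J %*% s0 %*% t(J)
  r <- y - drop(J %*% m0)
  -0.5 * drop(t(r) %*% solve(sy, r)) -
    0.5 * determinant(sy, logarithm = TRUE)$modulus - (n / 2) * log(2 * pi)
}

# exact conjugate posterior of the same model
oracle_posterior <- function(y, J, prec, m0, s0) {
  p0 <- solve(s0)
  pp <- t(J) %*% (J * prec) + p0
  sp <- solve(pp)
  mp <- drop(sp %*% (t(J) %*% (y * prec) + p0 %*% m0))
  list(mean = mp, cov = (sp + t(sp)) / 2)
}

# KL divergence between Gaussians, independent of the package's helper
oracle_kl <- function(m1, s1, m0, s0) {
  d <- length(m1)
  s0i <- solve(s0)
  0.5 * (sum(diag(s0i %*% s1)) - d +
           determinant(s0, TRUE)$modulus - determinant(s1, TRUE)$modulus +
           drop(t(m1 - m0) %*% s0i %*% (m1 - m0)))
}

# random Gaussian belief over named parameters (diagonal-ish posterior)
random_belief <- function(names, seed) {
  set.seed(seed)
  p <- length(names)
  a <- matrix(rnorm(p * p, 0, 0.2), p)
  cov <- diag(runif(p, 0.05, 0.3)) + crossprod(a) * 0.05
  gaussian_belief(setNames(rnorm(p, 0, 0.5), names), cov)
}

# elementwise re-evaluation of the stated equations of motion, written
# independently of the compiled code (same constants, base R)
oracle_derivs <- function(state, t, wa, wn, wg, b, amp, lat, isd, cn) {
  n <- nrow(wa)
  v <- state[1:n]
  ga <- state[n + 1:n]; gn <- state[2 * n + 1:n]; gg <- state[3 * n + 1:n]
  r0 <- 1 / (1 + exp(-cn$slope * (cn$VL - cn$threshold)))
  r <- pmax(1 / (1 + exp(-cn$slope * (v - cn$threshold))) - r0, 0)
  mg <- 1 / (1 + cn$mg_a * exp(-cn$mg_b * v))
  u <- b * amp * exp(-0.5 * ((t - lat) / isd)^2)
  dv <- (cn$gl * (cn$VL - v) + ga * (cn$VE - v) + gn * mg * (cn$VE - v) +
           gg * (cn$VI - v) + u) / cn$Cm
  c(dv,
    cn$kappa_ampa * (drop(wa %*% r) - ga),
    cn$kappa_nmda * (drop(wn %*% r) - gn),
    cn$kappa_gabaa * (drop(wg %*% r) - gg))
}

# expand a network + theta to full 36 x 36 weight matrices (R-side mirror
# of the compiled mapping, used by the derivative oracle)
oracle_network_matrices <- function(net, theta = NULL) {
  model <- compile_cmm(net)
  th <- setNames(rep(0, length(model$free_names)), model$free_names)
  if (!is.null(theta)) th[names(theta)] <- theta
  wa <- model$wa0; wn <- model$wn0; wg <- model$wg0
  if (nrow(model$map) > 0) {
    w <- model$base * exp(th[model$map[, 1] + 1])
    for (k in seq_len(nrow(model$map))) {
      i <- model$map[k, 3] + 1
      code <- model$map[k, 2]
      if (code == 0) wa[i] <- wa[i] + w[k]
      else if (code == 1) wn[i] <- wn[i] + w[k]
      else if (code == 2) wg[i] <- wg[i] + w[k]
      else { wa[i] <- wa[i] + w[k]; wn[i] <- wn[i] + model$ext_nmda * w[k] }
    }
  }
  list(wa = wa, wn = wn, wg = wg, b = model$b,
       amp = model$amp0 * exp(th["input:amp"]),
       lat = model$lat0 * exp(th["input:latency"]),
       isd = model$isd, consts = model$consts)
}
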
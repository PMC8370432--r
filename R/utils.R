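# internal helpers

# run code under a local RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# log-determinant of a symmetric positive definite matrix
logdet <- function(m) {
  if (length(m) == 1L) return(log(as.numeric(m)))
  2 * sum(log(diag(chol(m))))
}

# symmetric inverse with a small ridge for near-singular matrices
inv_sym <- function(m, ridge = 1e-8) {
  if (length(m) == 1L) return(matrix(1 / (as.numeric(m) + ridge), 1, 1,
                                     dimnames = dimnames(m)))
  m <- (m + t(m)) / 2
  out <- tryCatch(chol2inv(chol(m)), error = function(e) NULL)
  if (is.null(out)) out <- chol2inv(chol(m + ridge * diag(nrow(m))))
  dimnames(out) <- dimnames(m)
  out
}

# KL divergence between two Gaussians, KL[N(m1,S1) || N(m0,S0)]
gaussian_kl <- function(m1, s1, m0, s0) {
  d <- length(m1)
  p0 <- inv_sym(s0)
  dm <- m1 - m0
  0.5 * (sum(diag(p0 %*% s1)) - d + logdet(s0) - logdet(s1) +
           drop(t(dm) %*% p0 %*% dm))
}

# root-mean-square
rms <- function(x) sqrt(mean(x^2))
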
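#' Default epoch time grid
#'
#' Peristimulus time axis of the evoked response: -100 ms to 400 ms around
#' stimulus onset at 1 ms resolution (501 samples, 1 kHz).
#'
#' @param dt step size in ms.
#' @export
cmm_times <- function(dt = 1) seq(-100, 400, by = dt)

#' Compile a network into a fast generative model
#'
#' Pre-computes the 36-population weight matrices, the parameter-to-entry
#' mapping and the observation projection so that predicted ERFs (and their
#' finite-difference Jacobians) are generated entirely in compiled code.
#'
#' @param net a [network_spec()].
#' @param priors belief from [build_parameter_priors()] (its parameter table
#'   defines which entries are free).
#' @param obs an [observation_spec()].
#' @param t_grid time axis in ms (strictly increasing).
#' @param linear logical; replace the firing-rate nonlinearity, the
#'   magnesium gate and the conductance driving forces by their fixed-point
#'   linearisations (a diagnostic mode in which the network is exactly
#'   linear in its states and inputs).
#' @param v_bound integration is flagged as failed when any |V - VL|
#'   exceeds this bound (mV).
#' @return an object of class `cmm_model`.
#' @export
compile_cmm <- function(net, priors = build_parameter_priors(net),
                        obs = observation_spec(), t_grid = cmm_times(),
                        linear = FALSE, v_bound = 150) {
  if (any(diff(t_grid) <= 0)) abort("`t_grid` must be strictly increasing")
  tab <- attr(priors, "param_table")
  if (is.null(tab)) abort("`priors` must come from build_parameter_priors()")
  pops <- cmm_populations()
  nsrc <- length(net$sources)
  n <- nsrc * length(pops)
  mc <- net$microcircuit

  wa0 <- kronecker(diag(nsrc), mc$wa)
  wn0 <- kronecker(diag(nsrc), mc$wn)
  wg0 <- kronecker(diag(nsrc), mc$wg)
  ext_nmda <- 0.5

  free_names <- tab$name[tab$free]
  map <- matrix(integer(0), 0, 3)
  base <- numeric(0)
  rec_code <- c(ampa = 0L, nmda = 1L, gabaa = 2L, extrinsic = 3L)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    ent <- row$entries[[1]]
    if (length(ent) == 0) next
    if (row$free) {
      pid <- match(row$name, free_names) - 1L
      if (row$receptor == "gabaa") wg0[ent] <- 0
      map <- rbind(map, cbind(pid, rec_code[[row$receptor]], ent - 1L))
      base <- c(base, row$bases[[1]])
    } else if (row$receptor == "extrinsic") {
      wa0[ent] <- wa0[ent] + row$bases[[1]]
      wn0[ent] <- wn0[ent] + ext_nmda * row$bases[[1]]
    }
    # frozen gabaa entries already present in wg0
  }
  id_of <- function(nm) if (nm %in% free_names) match(nm, free_names) - 1L else -1L

  b <- numeric(n)
  for (s in net$input_targets)
    b[(match(s, net$sources) - 1L) * 6L + 1L] <- 1  # ss population

  jproj <- matrix(0, nsrc, n, dimnames = list(net$sources, NULL))
  for (s in seq_len(nsrc))
    jproj[s, (s - 1L) * 6L + seq_len(6L)] <- obs$j[pops]

  consts <- mc$constants
  consts$linear <- linear

  structure(list(
    net = net, obs = obs, priors = priors, param_table = tab,
    free_names = free_names, wa0 = wa0, wn0 = wn0, wg0 = wg0,
    map = map, base = base, ext_nmda = ext_nmda,
    amp_id = id_of("input:amp"), lat_id = id_of("input:latency"),
    gain_id = id_of("obs:gain"),
    amp0 = net$input$amp, lat0 = net$input$latency, isd = net$input$sd,
    gain0 = obs$gain, b = b, jproj = jproj, consts = consts,
    t_grid = t_grid, v_bound = v_bound
  ), class = "cmm_model")
}

#' @export
print.cmm_model <- function(x, ...) {
  cat(sprintf("<cmm_model> %d free parameters, %d states, %d time samples\n",
              length(x$free_names), 4 * nrow(x$wa0), length(x$t_grid)))
  invisible(x)
}

# resolve a theta argument (NULL, named vector or belief) to the model's
# free-parameter order; unknown names are an error naming the parameter
resolve_theta <- function(model, theta) {
  out <- setNames(rep(0, length(model$free_names)), model$free_names)
  if (is.null(theta)) return(out)
  if (inherits(theta, "gaussian_belief")) theta <- theta$mean
  bad <- setdiff(names(theta), model$free_names)
  if (length(bad) > 0)
    abort(paste("unresolvable parameter name(s):", paste(bad, collapse = ", ")))
  out[names(theta)] <- theta
  out
}

#' Predicted source ERFs for one or more parameter vectors
#'
#' @param model a [compile_cmm()] model.
#' @param theta named numeric vector (or matrix with one column per
#'   parameter draw) of log-scaling deviations; missing entries are 0.
#' @return a sources x time matrix (or list of matrices for a matrix
#'   input); `NULL` marks a diverged integration.
#' @export
predict_erf_matrix <- function(model, theta = NULL) {
  single <- !is.matrix(theta)
  th <- if (is.matrix(theta)) theta else as.matrix(resolve_theta(model, theta))
  out <- cmm_predict_multi(th, model$wa0, model$wn0, model$wg0,
                           model$map, model$base, model$ext_nmda,
                           model$amp_id, model$lat_id, model$gain_id,
                           model$amp0, model$lat0, model$isd, model$gain0,
                           model$b, model$jproj, model$consts, model$t_grid,
                           model$v_bound)
  out <- lapply(out, function(m) {
    if (is.null(m)) return(NULL)
    dimnames(m) <- list(model$net$sources, NULL)
    m
  })
  if (single) out[[1]] else out
}

#' Integrate the network dynamics
#'
#' Runs the fixed-step RK4 integration of the full 144-dimensional network
#' state over the epoch and returns the hidden-state trajectories.
#'
#' @inheritParams predict_erf_matrix
#' @param net a [network_spec()] (a compiled model is built internally) or
#'   a `cmm_model`.
#' @param t_grid time axis (ms), strictly increasing.
#' @param linear see [compile_cmm()].
#' @return an object of class `cmm_trajectory`: list with `time`, matrices
#'   `v`, `g_ampa`, `g_nmda`, `g_gabaa` (time x 36 populations, columns
#'   named `source.pop`), and the generating model.
#' @export
integrate_network <- function(net, theta = NULL, t_grid = cmm_times(),
                              linear = FALSE) {
  model <- if (inherits(net, "cmm_model")) net
           else compile_cmm(net, t_grid = t_grid, linear = linear)
  th <- resolve_theta(model, theta)
  # apply theta scalings to the weight matrices once, then integrate
  wa <- model$wa0; wn <- model$wn0; wg <- model$wg0
  if (nrow(model$map) > 0) {
    w <- model$base * exp(th[model$map[, 1] + 1L])
    for (k in seq_len(nrow(model$map))) {
      i <- model$map[k, 3] + 1L
      switch(model$map[k, 2] + 1L,
             wa[i] <- wa[i] + w[k],
             wn[i] <- wn[i] + w[k],
             wg[i] <- wg[i] + w[k],
             { wa[i] <- wa[i] + w[k]; wn[i] <- wn[i] + model$ext_nmda * w[k] })
    }
  }
  amp <- model$amp0 * if (model$amp_id >= 0) exp(th[model$amp_id + 1L]) else 1
  lat <- model$lat0 * if (model$lat_id >= 0) exp(th[model$lat_id + 1L]) else 1
  res <- cmm_integrate(wa, wn, wg, model$b, amp, lat, model$isd,
                       model$consts, model$t_grid, model$v_bound)
  if (!res$ok)
    abort("network integration diverged (|V - VL| exceeded bound)",
          class = "microdcm_divergence")
  n <- nrow(model$wa0)
  labs <- paste(rep(model$net$sources, each = 6), cmm_populations(),
                sep = ".")
  blocks <- lapply(0:3, function(k) {
    m <- res$state[, k * n + seq_len(n), drop = FALSE]
    colnames(m) <- labs
    m
  })
  structure(list(time = model$t_grid, v = blocks[[1]], g_ampa = blocks[[2]],
                 g_nmda = blocks[[3]], g_gabaa = blocks[[4]], model = model,
                 theta = th),
            class = "cmm_trajectory")
}

#' @export
print.cmm_trajectory <- function(x, ...) {
  cat(sprintf("<cmm_trajectory> %d samples x %d populations\n",
              length(x$time), ncol(x$v)))
  invisible(x)
}

#' Simulate a source-level event-related field
#'
#' Convenience wrapper: integrates the network at the given parameters and
#' projects the depolarisations to source ERFs.
#'
#' @inheritParams integrate_network
#' @param obs an [observation_spec()] (only used when `net` is not already
#'   compiled).
#' @return a tibble with columns `source`, `time_ms`, `value`.
#' @export
simulate_erf <- function(net, theta = NULL, obs = observation_spec(),
                         t_grid = cmm_times()) {
  model <- if (inherits(net, "cmm_model")) net
           else compile_cmm(net, obs = obs, t_grid = t_grid)
  m <- predict_erf_matrix(model, resolve_theta(model, theta))
  if (is.null(m))
    abort("network integration diverged (|V - VL| exceeded bound)",
          class = "microdcm_divergence")
  erf_matrix_to_tibble(m, model$t_grid)
}

#' Network state derivatives
#'
#' Evaluates d(state)/dt of the full network at one state and time point,
#' with parameters applied. The state vector stacks V, g_AMPA, g_NMDA,
#' g_GABAA blocks of 36 populations each (144 states).
#'
#' @inheritParams integrate_network
#' @param state numeric vector of length 144 (or a 1-row slice of a
#'   trajectory).
#' @param t time (ms).
#' @return named derivative vector of the same length.
#' @export
network_derivatives <- function(net, state, t, theta = NULL,
                                linear = FALSE) {
  model <- if (inherits(net, "cmm_model")) net
           else compile_cmm(net, linear = linear)
  th <- resolve_theta(model, theta)
  n <- nrow(model$wa0)
  if (length(state) != 4 * n) abort("state vector must have length 144")
  wa <- model$wa0; wn <- model$wn0; wg <- model$wg0
  if (nrow(model$map) > 0) {
    w <- model$base * exp(th[model$map[, 1] + 1L])
    for (k in seq_len(nrow(model$map))) {
      i <- model$map[k, 3] + 1L
      switch(model$map[k, 2] + 1L,
             wa[i] <- wa[i] + w[k],
             wn[i] <- wn[i] + w[k],
             wg[i] <- wg[i] + w[k],
             { wa[i] <- wa[i] + w[k]; wn[i] <- wn[i] + model$ext_nmda * w[k] })
    }
  }
  amp <- model$amp0 * if (model$amp_id >= 0) exp(th[model$amp_id + 1L]) else 1
  lat <- model$lat0 * if (model$lat_id >= 0) exp(th[model$lat_id + 1L]) else 1
  d <- cmm_derivs(as.numeric(state), t, wa, wn, wg, model$b, amp, lat,
                  model$isd, model$consts)
  labs <- paste(rep(model$net$sources, each = 6), cmm_populations(),
                sep = ".")
  setNames(as.numeric(d), c(paste0("V.", labs), paste0("gA.", labs),
                            paste0("gN.", labs), paste0("gG.", labs)))
}
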
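#' Population labels of the cortical column
#'
#' Six neuronal populations per source, in fixed order: layer-4 spiny
#' stellate cells (`ss`), superficial pyramidal cells (`sp`), superficial
#' inhibitory interneurons (`si`), deep cortico-cortical pyramidal cells
#' (`dp`), deep inhibitory interneurons (`di`) and thalamic-projection
#' pyramidal cells (`tp`).
#'
#' @export
cmm_populations <- function() c("ss", "sp", "si", "dp", "di", "tp")

# populations allowed to originate excitatory / inhibitory synapses
.excitatory_pops <- c("ss", "sp", "dp", "tp")
.inhibitory_pops <- c("si", "di")

#' Default biophysical constants of the conductance model
#'
#' All constants of the mean-field equations in one place. Units: potentials
#' in mV, rate constants in 1/ms, capacitance as the effective membrane time
#' constant scaling (C/gL = 10 ms), conductances as multiples of the leak
#' conductance `gl`, sigmoid slope in 1/mV.
#'
#' | constant | value | meaning |
#' |---|---|---|
#' | `VL` | -70 | leak (resting) reversal potential |
#' | `VE` | 60  | excitatory reversal potential (AMPA/NMDA) |
#' | `VI` | -90 | inhibitory reversal potential (GABA-A) |
#' | `gl` | 1   | leak conductance (unit of conductance) |
#' | `Cm` | 10  | membrane capacitance (so tau_m = 10 ms) |
#' | `kappa_ampa`  | 1/4   | AMPA conductance rate constant |
#' | `kappa_gabaa` | 1/16  | GABA-A conductance rate constant |
#' | `kappa_nmda`  | 1/100 | NMDA conductance rate constant |
#' | `threshold` | -40 | firing-rate sigmoid inflection (mV) |
#' | `slope` | 0.2 | firing-rate sigmoid slope (1/mV) |
#' | `mg_a`, `mg_b` | 0.2, 0.06 | magnesium-block gate constants |
#'
#' @return named list of constants, suitable for [microcircuit_spec()].
#' @export
cmm_constants <- function() {
  list(
    gl = 1, Cm = 10, VL = -70, VE = 60, VI = -90,
    kappa_ampa = 1 / 4, kappa_gabaa = 1 / 16, kappa_nmda = 1 / 100,
    threshold = -40, slope = 0.2, mg_a = 0.2, mg_b = 0.06,
    linear = FALSE, lin_gain = 0.0025
  )
}

#' Intrinsic connectivity of one cortical column
#'
#' Defines the prior-mean intrinsic synaptic weight matrices of a
#' six-population conductance-based cortical microcircuit, per receptor
#' channel (AMPA, NMDA, GABA-A). Matrices are target-by-source: entry
#' `W[i, j]` is the weight of the synapse from population `j` onto
#' population `i`.
#'
#' Structural rules enforced by the validator:
#' * AMPA/NMDA weights originate only from excitatory populations
#'   (ss, sp, dp, tp);
#' * off-diagonal GABA-A weights originate only from the interneuron
#'   populations (si, di);
#' * every population carries a GABA-A self-connection (tonic background
#'   inhibition), and the four phasic interneuron efferents
#'   si->ss, si->sp, di->dp, di->tp are present.
#'
#' @param wa,wn,wg optional 6x6 replacement matrices (target x source) for
#'   the AMPA, NMDA and GABA-A channels.
#' @param constants biophysical constants, see [cmm_constants()].
#' @return an object of class `microcircuit_spec`.
#' @export
microcircuit_spec <- function(wa = NULL, wn = NULL, wg = NULL,
                              constants = cmm_constants()) {
  pops <- cmm_populations()
  zero <- matrix(0, 6, 6, dimnames = list(pops, pops))
  if (is.null(wa)) {
    wa <- zero
    # laminar excitatory chain: granular input layer -> superficial ->
    # deep -> thalamic projection, with a thalamocortical return to ss
    wa["sp", "ss"] <- 2; wa["si", "ss"] <- 2
    wa["dp", "sp"] <- 2; wa["si", "sp"] <- 1
    wa["di", "dp"] <- 1; wa["tp", "dp"] <- 2
    wa["di", "tp"] <- 1; wa["ss", "tp"] <- 1
  }
  if (is.null(wn)) wn <- 0.5 * wa
  if (is.null(wg)) {
    wg <- zero
    diag(wg) <- 2                       # tonic self-inhibition, every pop
    wg["ss", "si"] <- 2; wg["sp", "si"] <- 2   # phasic, superficial
    wg["dp", "di"] <- 2; wg["tp", "di"] <- 2   # phasic, deep
  }
  spec <- structure(
    list(populations = pops, wa = wa, wn = wn, wg = wg,
         constants = constants),
    class = "microcircuit_spec"
  )
  validate_microcircuit(spec)
  spec
}

#' @rdname microcircuit_spec
#' @param spec a `microcircuit_spec`.
#' @export
validate_microcircuit <- function(spec) {
  pops <- cmm_populations()
  for (m in c("wa", "wn", "wg")) {
    W <- spec[[m]]
    if (!is.matrix(W) || !identical(dim(W), c(6L, 6L)))
      abort(sprintf("`%s` must be a 6x6 matrix", m))
    if (any(W < 0)) abort(sprintf("`%s` has negative weights", m))
  }
  for (m in c("wa", "wn")) {
    if (any(spec[[m]][, .inhibitory_pops] > 0))
      abort(sprintf("excitatory matrix `%s` has weights from interneurons", m))
  }
  wg <- spec$wg
  off <- wg; diag(off) <- 0
  exc_cols <- setdiff(pops, .inhibitory_pops)
  if (any(off[, exc_cols] > 0))
    abort("off-diagonal GABA-A weights may only originate from si/di")
  if (any(diag(wg) <= 0))
    abort("every population needs a GABA-A self-connection (tonic inhibition)")
  phasic <- rbind(c("ss", "si"), c("sp", "si"), c("dp", "di"), c("tp", "di"))
  if (any(wg[phasic] <= 0))
    abort("phasic synapses si->ss, si->sp, di->dp, di->tp must be present")
  invisible(spec)
}

#' Mean-field firing-rate function
#'
#' Logistic sigmoid mapping mean membrane potential to expected firing rate
#' in `[0, 1]`: `1 / (1 + exp(-slope * (V - threshold)))`. This is the raw
#' population rate; the network equations use the baseline-subtracted,
#' rectified version so that the resting state is a fixed point.
#'
#' @param v membrane potential (mV), vectorised.
#' @param spec a [microcircuit_spec()] providing `threshold` and `slope`.
#' @return expected firing rate(s) in `[0, 1]`.
#' @export
sigmoid_rate <- function(v, spec = microcircuit_spec()) {
  if (any(!is.finite(v))) abort("`v` must be finite")
  cn <- spec$constants
  1 / (1 + exp(-cn$slope * (v - cn$threshold)))
}

#' Voltage-dependent NMDA magnesium gate
#'
#' The fraction of NMDA channels unblocked by magnesium at potential `v`:
#' `1 / (1 + 0.2 * exp(-0.06 * v))`. Monotone increasing, tending to 1 as
#' the membrane depolarises.
#'
#' @param v membrane potential (mV), vectorised.
#' @param a,b gate constants.
#' @return gate value(s) in (0, 1).
#' @export
mg_block <- function(v, a = 0.2, b = 0.06) {
  if (any(!is.finite(v))) abort("`v` must be finite")
  1 / (1 + a * exp(-b * v))
}
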
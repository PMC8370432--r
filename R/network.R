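#' Source labels of the auditory hierarchy
#'
#' Six cortical sources in fixed order: bilateral primary auditory cortex
#' (`lA1`, `rA1`), superior temporal gyrus (`lSTG`, `rSTG`) and inferior
#' frontal gyrus (`lIFG`, `rIFG`).
#'
#' @export
cmm_sources <- function() c("lA1", "rA1", "lSTG", "rSTG", "lIFG", "rIFG")

#' Extrinsic connectivity of the six-source network
#'
#' Builds the fully connected frontotemporal hierarchy: forward connections
#' A1 -> STG -> IFG in each hemisphere, backward connections along the
#' reverse edges, and lateral connections between homologous regions.
#' Exogenous (auditory and expectancy) input drives the layer-4 stellate
#' populations of bilateral A1 and IFG with a Gaussian bump (peak 60 ms,
#' dispersion 8 ms).
#'
#' Laminar termination follows the canonical-microcircuit convention:
#' forward connections arise from superficial pyramidal cells and terminate
#' on ss (and si); backward connections arise from deep pyramidal cells and
#' terminate on sp, si, dp and di; lateral connections arise from
#' superficial pyramidal cells and terminate on ss and dp. The termination
#' weights are configurable through `termination`.
#'
#' @param microcircuit a [microcircuit_spec()] shared by all sources.
#' @param gains prior-mean extrinsic gains by connection type.
#' @param termination named list of termination weight vectors per type;
#'   names are target populations.
#' @param input_targets sources receiving the exogenous Gaussian bump.
#' @param input list with prior-mean input `amp`litude, `latency` (ms) and
#'   Gaussian dispersion `sd` (ms).
#' @return an object of class `network_spec` with an `edges` tibble
#'   (`from`, `to`, `type`, `gain`).
#' @export
network_spec <- function(microcircuit = microcircuit_spec(),
                         gains = c(forward = 1, backward = 0.5, lateral = 0.5),
                         termination = list(
                           forward  = c(ss = 1, si = 0.5),
                           backward = c(sp = 0.5, si = 0.5, dp = 0.5, di = 0.5),
                           lateral  = c(ss = 0.5, dp = 0.5)
                         ),
                         input_targets = c("lA1", "rA1", "lIFG", "rIFG"),
                         input = list(amp = 48, latency = 60, sd = 8)) {
  src <- cmm_sources()
  fwd <- rbind(c("lA1", "lSTG"), c("lSTG", "lIFG"),
               c("rA1", "rSTG"), c("rSTG", "rIFG"))
  lat <- rbind(c("lA1", "rA1"), c("rA1", "lA1"),
               c("lSTG", "rSTG"), c("rSTG", "lSTG"),
               c("lIFG", "rIFG"), c("rIFG", "lIFG"))
  edges <- tibble::tibble(
    from = c(fwd[, 1], fwd[, 2], lat[, 1]),
    to   = c(fwd[, 2], fwd[, 1], lat[, 2]),
    type = rep(c("forward", "backward", "lateral"), c(4, 4, 6))
  )
  edges$gain <- unname(gains[edges$type])
  stopifnot(all(input_targets %in% src))
  structure(
    list(sources = src, microcircuit = microcircuit, edges = edges,
         termination = termination, input_targets = input_targets,
         input = input, conditions = c("standard", "deviant")),
    class = "network_spec"
  )
}

# origin population of each extrinsic connection type
.ext_origin <- c(forward = "sp", backward = "dp", lateral = "sp")

# short tags used in parameter names
.ext_tag <- c(forward = "fwd", backward = "bwd", lateral = "lat")

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> 6 sources,", nrow(x$edges), "extrinsic connections\n")
  cat("  input ->", paste(x$input_targets, collapse = ", "),
      sprintf("(Gaussian bump, peak %g ms, sd %g ms)\n",
              x$input$latency, x$input$sd))
  invisible(x)
}
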
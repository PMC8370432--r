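#' Read and write ERF datasets as flat CSV
#'
#' The on-disk interchange format is a flat table with columns `subject`,
#' `group`, `session`, `condition`, `source`, `time_ms`, `value` (identifier
#' columns may be absent for single traces).
#'
#' @param erf long ERF tibble.
#' @param path file path.
#' @export
write_erf_csv <- function(erf, path) {
  utils::write.csv(erf, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_erf_csv
#' @export
read_erf_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a design matrix from CSV
#'
#' Expects a header row of column names; validates the design (constant
#' first column, unique names, full rank).
#'
#' @param path CSV file path.
#' @export
read_design_csv <- function(path) {
  x <- as.matrix(utils::read.csv(path, check.names = FALSE))
  validate_design(x)
}

#' Serialise model specifications to YAML
#'
#' Writes the microcircuit weight matrices, constants and the network edge
#' list in a plain editable format, and reads them back.
#'
#' @param net a [network_spec()].
#' @param path file path.
#' @export
write_network_yaml <- function(net, path) {
  mc <- net$microcircuit
  obj <- list(
    populations = mc$populations,
    wa = apply(mc$wa, 1, as.numeric, simplify = FALSE),
    wn = apply(mc$wn, 1, as.numeric, simplify = FALSE),
    wg = apply(mc$wg, 1, as.numeric, simplify = FALSE),
    constants = mc$constants[setdiff(names(mc$constants),
                                     c("linear", "lin_gain"))],
    sources = net$sources,
    edges = apply(net$edges, 1, as.list, simplify = FALSE),
    termination = lapply(net$termination, as.list),
    input_targets = net$input_targets,
    input = net$input
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  pops <- unlist(obj$populations)
  as_mat <- function(rows) {
    m <- do.call(rbind, lapply(rows, unlist))
    dimnames(m) <- list(pops, pops)
    m
  }
  consts <- modifyList(cmm_constants(), obj$constants)
  mc <- microcircuit_spec(as_mat(obj$wa), as_mat(obj$wn), as_mat(obj$wg),
                          constants = consts)
  net <- network_spec(
    microcircuit = mc,
    termination = lapply(obj$termination, unlist),
    input_targets = unlist(obj$input_targets),
    input = obj$input)
  edges <- dplyr::bind_rows(lapply(obj$edges, tibble::as_tibble))
  edges$gain <- as.numeric(edges$gain)
  net$edges <- edges
  net
}

#' Persist a Gaussian belief as JSON
#'
#' Stores parameter names, mean, covariance, noise hyperposteriors and free
#' energy in a portable text format.
#'
#' @param belief a [gaussian_belief()].
#' @param path file path.
#' @export
write_belief_json <- function(belief, path) {
  obj <- list(names = names(belief$mean),
              mean = unname(belief$mean),
              cov = unname(belief$cov),
              lambda = as.list(belief$lambda %||% list()),
              free_energy = belief$free_energy,
              converged = belief$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_belief_json
#' @export
read_belief_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gaussian_belief(setNames(obj$mean, obj$names),
                  matrix(unlist(obj$cov), length(obj$names)),
                  lambda = if (length(obj$lambda)) unlist(obj$lambda) else NULL,
                  free_energy = obj$free_energy,
                  converged = obj$converged)
}

#' Write a run report to disk
#'
#' Tables become CSV files, the report skeleton (provenance, model
#' comparison) a JSON file.
#'
#' @param report a [run_report()].
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("fit_table", "group_effects", "group_significant",
               "gaba_effects", "model_comparison")) {
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(
    list(provenance = report$provenance,
         model_comparison = report$model_comparison),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
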
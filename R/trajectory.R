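new_trajectory <- function(times, conc, events, params, scenario, meta) {
  structure(list(times = times, conc = conc, events = events,
                 params = params,
                 submodel = scenario$submodel,
                 solver = list(rtol = scenario$rtol, atol = scenario$atol,
                               report_dt_min = scenario$report_dt_min),
                 cells = dimnames(conc)[[2]],
                 meta = meta),
            class = "crypt_trajectory")
}

#' @export
print.crypt_trajectory <- function(x, ...) {
  cat("crypt_trajectory (", x$meta$kind, "): ", length(x$cells),
      " cells, t in [0, ", max(x$times) / 60, "] h, ",
      length(x$times), " samples\n", sep = "")
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x A `crypt_trajectory`.
#' @param row.names,optional,... Ignored (S3 signature compatibility).
#' @return A data.frame with columns `time_min`, `cell`, `species`, `value`.
#' @export
as.data.frame.crypt_trajectory <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  d <- dim(x$conc)
  data.frame(
    time_min = rep(x$times, times = d[2] * d[3]),
    cell = rep(rep(dimnames(x$conc)[[2]], each = d[1]), times = d[3]),
    species = rep(dimnames(x$conc)[[3]], each = d[1] * d[2]),
    value = as.vector(x$conc),
    stringsAsFactors = FALSE
  )
}

#' Extract one species' timecourse
#'
#' @param traj A `crypt_trajectory`.
#' @param species Species name (see [crypt_species()]).
#' @param cell Cell identifier (default: first cell).
#' @return Numeric vector along `traj$times`.
#' @export
species_series <- function(traj, species, cell = traj$cells[1]) {
  stopifnot(inherits(traj, "crypt_trajectory"))
  traj$conc[, cell, species]
}

#' Write a trajectory and its run manifest
#'
#' Writes the tidy CSV (`time_min`, `cell`, `species`, `value`) and a JSON
#' manifest recording parameters, events, solver settings and any seed.
#'
#' @param traj A `crypt_trajectory`.
#' @param csv_path Output CSV path.
#' @param manifest_path Optional JSON manifest path.
#' @return Invisibly, the CSV path.
#' @export
write_trajectory <- function(traj, csv_path, manifest_path = NULL) {
  utils::write.csv(as.data.frame(traj), csv_path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    manifest <- list(
      kind = traj$meta$kind,
      submodel = traj$submodel,
      cells = traj$cells,
      horizon_min = max(traj$times),
      events = traj$events,
      solver = traj$solver,
      meta = traj$meta[setdiff(names(traj$meta), "kind")],
      params = unclass(traj$params)
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}
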
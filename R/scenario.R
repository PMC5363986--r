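#' Standard initial conditions
#'
#' The standard resting state used to initialise simulations: the Wnt
#' species sit at the decoupled Wnt-submodel steady state for the given
#' stimulus (self-consistent with the shipped parameters), and each Notch
#' species is set to `notch_init` (0.5 nM by default; the slight 0.51 nM
#' offset used for the second cell of a pair is applied by
#' [build_scenario()]).
#'
#' @param params A [crypt_params()] object.
#' @param W Wnt stimulus at which the Wnt species are equilibrated.
#' @param notch_init Initial value for all seven Notch species (nM).
#' @param gsk_total Total GSK3beta pool `G + C + I2` (nM).
#' @return Named numeric vector over [crypt_species()].
#' @export
standard_state <- function(params, W = 1, notch_init = 0.5,
                           gsk_total = 50) {
  wnt <- wnt_steady_state(params, W = W, F_fix = notch_init,
                          gsk_total = gsk_total)
  c(stats::setNames(rep(notch_init, 7L), NOTCH_SPECIES), wnt)
}

#' Simulation scenario
#'
#' Bundles everything one deterministic or stochastic run needs: the cell
#' graph with its per-cell environment, per-cell initial states, the time
#' horizon, a (possibly empty) list of timed environment switches, the
#' submodel selector, and integrator settings.
#'
#' Rather than calling this directly, most users will want
#' [build_scenario()], which constructs the canonical two-cell experiments.
#'
#' @param graph A [cell_graph()].
#' @param init A cells x 12 matrix of initial concentrations (rows named by
#'   cell), or a single named state vector recycled to all cells.
#' @param hours Simulation horizon in hours.
#' @param events `NULL` or a data.frame with columns `time_h`, `cell`,
#'   `field` (one of `"W"`, `"rho_APC"`, `"theta2"`), `value`.  Events are
#'   instantaneous environment switches; species concentrations are
#'   continuous across them.
#' @param submodel `"full"` (all 12 equations), `"notch"` (the seven Notch
#'   equations with the Wnt species frozen at their initial values, i.e. the
#'   decoupled Notch submodel with beta-catenin as an input parameter), or
#'   `"wnt"` (the five Wnt equations with the Notch species frozen).
#' @param rtol,atol,report_dt_min Integrator relative/absolute tolerance and
#'   output grid spacing (minutes).
#' @return An object of class `crypt_scenario`.
#' @export
crypt_scenario <- function(graph, init, hours = 48, events = NULL,
                           submodel = c("full", "notch", "wnt"),
                           rtol = 1e-8, atol = 1e-10, report_dt_min = 1) {
  submodel <- match.arg(submodel)
  stopifnot(inherits(graph, "cell_graph"))
  if (is.null(dim(init))) {
    init <- matrix(rep(init, each = length(graph$cells)),
                   nrow = length(graph$cells),
                   dimnames = list(graph$cells, names(init)))
  }
  init <- as_state_matrix(init, graph$cells)
  if (any(init < 0)) stop("initial concentrations must be non-negative",
                          call. = FALSE)
  if (!is.null(events) && nrow(events)) {
    req <- c("time_h", "cell", "field", "value")
    if (!all(req %in% names(events))) {
      stop("'events' needs columns ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    if (any(events$time_h < 0) || any(events$time_h > hours)) {
      stop("event times must lie within [0, hours]", call. = FALSE)
    }
    if (!all(events$field %in% c("W", "rho_APC", "theta2"))) {
      stop("event field must be one of W, rho_APC, theta2", call. = FALSE)
    }
    if (!all(events$cell %in% graph$cells)) {
      stop("event cell must be a graph cell", call. = FALSE)
    }
    events <- events[order(events$time_h), , drop = FALSE]
  } else {
    events <- data.frame(time_h = numeric(0), cell = character(0),
                         field = character(0), value = numeric(0))
  }
  structure(list(graph = graph, init = init, hours = hours,
                 events = events, submodel = submodel,
                 rtol = rtol, atol = atol, report_dt_min = report_dt_min),
            class = "crypt_scenario")
}

#' Canonical two-cell experiments
#'
#' Builds the standard cell-pair scenarios: both cells start from the
#' standard Wnt conditions; the Notch species of cell 1 start at 0.5 nM and
#' those of cell 2 at 0.51 nM, a small asymmetry that permits heterogeneous
#' states to emerge.
#'
#' \describe{
#'   \item{`healthy_pair`}{No events.}
#'   \item{`apc_mutant_pair`}{Cell 2 acquires a single APC hit
#'     (`rho_APC = 0.5`) at 12 h and a second hit (`rho_APC = 0`) at 24 h.}
#'   \item{`wnt_hyper_pair`}{Cell 2 switches to a hyperstimulated state
#'     `W = 2` at 12 h.}
#'   \item{`notch_pair`}{The decoupled Notch submodel: the Wnt species are
#'     frozen at the standard state, so beta-catenin acts as a constant
#'     input, and (unless overridden) `theta2 = 1`, the wholly
#'     Notch-mediated promoter; used for oscillation-period studies.}
#' }
#'
#' @param kind Scenario name (see above).
#' @param params A [crypt_params()] object.
#' @param theta2 Promoter balance for both cells (default: value in
#'   `params`).
#' @param W Baseline Wnt stimulus for both cells.
#' @param hours Horizon (h).
#' @param notch_init Length-2 vector of initial values for the Notch species
#'   of the two cells (nM).
#' @param ... Passed on to [crypt_scenario()] (e.g. `rtol`, `report_dt_min`).
#' @return A `crypt_scenario`.
#' @export
build_scenario <- function(kind = c("healthy_pair", "apc_mutant_pair",
                                    "wnt_hyper_pair", "notch_pair"),
                           params = crypt_params(),
                           theta2 = params$theta2, W = 1, hours = 48,
                           notch_init = c(0.5, 0.51), ...) {
  kind <- match.arg(kind)
  if (kind == "notch_pair" && missing(theta2)) theta2 <- 1
  graph <- cell_graph(c("cell1", "cell2"), cbind("cell1", "cell2"),
                      W = W, theta2 = theta2)
  # Wnt species equilibrated at the baseline stimulus; for the decoupled
  # Notch pair the frozen beta-catenin input is the standard (W = 1) state.
  base <- standard_state(params, W = if (kind == "notch_pair") 1 else W)
  init <- rbind(cell1 = base, cell2 = base)
  init[1, NOTCH_SPECIES] <- notch_init[1]
  init[2, NOTCH_SPECIES] <- notch_init[2]
  events <- switch(
    kind,
    healthy_pair = NULL,
    notch_pair = NULL,
    apc_mutant_pair = data.frame(
      time_h = c(12, 24), cell = "cell2", field = "rho_APC",
      value = c(0.5, 0), stringsAsFactors = FALSE),
    wnt_hyper_pair = data.frame(
      time_h = 12, cell = "cell2", field = "W", value = 2,
      stringsAsFactors = FALSE)
  )
  crypt_scenario(graph, init, hours = hours, events = events,
                 submodel = if (kind == "notch_pair") "notch" else "full",
                 ...)
}

#' @export
print.crypt_scenario <- function(x, ...) {
  cat("crypt_scenario:", length(x$graph$cells), "cells,", x$hours,
      "h horizon, submodel =", x$submodel, "\n")
  if (nrow(x$events)) {
    cat("events:\n"); print(x$events, row.names = FALSE)
  } else cat("no events\n")
  invisible(x)
}

# Columns of the state matrix integrated for each submodel choice; the
# complementary species stay frozen at their initial values.
active_species <- function(submodel) {
  switch(submodel,
         full = crypt_species(),
         notch = NOTCH_SPECIES,
         wnt = WNT_SPECIES)
}
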
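#' Deterministic simulation of a scenario
#'
#' Integrates the coupled cell system with a stiff multistep solver
#' (`deSolve::ode`, method `"lsoda"`).  Timed environment switches are
#' handled by stopping the integrator at each event time, updating the
#' per-cell environment, and restarting from the current state, so species
#' concentrations are continuous across events while environment parameters
#' jump.
#'
#' @param scenario A [crypt_scenario()].
#' @param params A [crypt_params()] object.
#' @param homogeneous If `TRUE`, each cell sees its own Delta
#'   (`Dbar = D`), the homogeneous reduction used in steady-state analysis.
#' @return A `crypt_trajectory`: a list with `times` (minutes), `conc` (a
#'   time x cell x species array), `events`, and run metadata.  Use
#'   [as.data.frame()] for a tidy long table.
#' @export
run_deterministic <- function(scenario, params = crypt_params(),
                              homogeneous = FALSE) {
  stopifnot(inherits(scenario, "crypt_scenario"))
  graph <- scenario$graph
  cells <- graph$cells
  n_cells <- length(cells)
  sp <- crypt_species()
  act <- active_species(scenario$submodel)
  act_idx <- match(act, sp)

  horizon <- scenario$hours * 60
  grid <- seq(0, horizon, by = scenario$report_dt_min)
  ev <- scenario$events
  breaks <- sort(unique(c(0, ev$time_h * 60, horizon)))

  state_mat <- scenario$init
  env_graph <- graph

  deriv_fn <- function(t, y, parms) {
    m <- matrix(y, nrow = n_cells, dimnames = list(cells, sp))
    d <- coupled_rhs(m, env_graph, params, homogeneous = homogeneous)
    if (length(act_idx) < 12L) {
      frozen <- setdiff(seq_len(12L), act_idx)
      d[, frozen] <- 0
    }
    list(as.vector(d))
  }

  out_times <- numeric(0)
  out_rows <- NULL
  clipped <- 0L
  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    seg_times <- unique(c(t0, grid[grid > t0 & grid <= t1], t1))
    sol <- deSolve::ode(y = as.vector(state_mat), times = seg_times,
                        func = deriv_fn, parms = NULL, method = "lsoda",
                        rtol = scenario$rtol, atol = scenario$atol)
    if (attr(sol, "istate")[1L] < 0) {
      stop("integrator failure at t = ", utils::tail(sol[, 1], 1),
           " min; last good state retained in error condition",
           call. = FALSE)
    }
    vals <- sol[, -1, drop = FALSE]
    neg <- vals < 0
    if (any(neg)) {
      # below-zero excursions only within integrator tolerance are clipped
      worst <- min(vals)
      if (worst < -1e-6) {
        warning("state went negative beyond tolerance (min = ", worst, ")")
      }
      clipped <- clipped + sum(neg)
      vals[neg] <- 0
    }
    keep <- sol[, 1] %in% grid & !(sol[, 1] %in% out_times)
    out_times <- c(out_times, sol[keep, 1])
    out_rows <- rbind(out_rows, vals[keep, , drop = FALSE])
    state_mat <- matrix(vals[nrow(vals), ], nrow = n_cells,
                        dimnames = list(cells, sp))
    # apply events scheduled at t1
    if (nrow(ev)) {
      hits <- ev[abs(ev$time_h * 60 - t1) < 1e-9, , drop = FALSE]
      for (i in seq_len(nrow(hits))) {
        env_graph$env[env_graph$env$cell == hits$cell[i],
                      hits$field[i]] <- hits$value[i]
      }
    }
  }
  conc <- array(out_rows, dim = c(length(out_times), n_cells, 12L),
                dimnames = list(NULL, cells, sp))
  new_trajectory(times = out_times, conc = conc, events = ev,
                 params = params, scenario = scenario,
                 meta = list(kind = "deterministic", clipped = clipped,
                             homogeneous = homogeneous))
}

#' Stochastic simulation with extrinsic Hes1 production noise
#'
#' Fixed-step Euler scheme in which the Hes1 equation receives an additive
#' perturbation to its production term at every step, independently per cell
#' and per run.  Two scalings are available: `"wiener"` (default) adds a
#' state increment `sigma * sqrt(dt) * Z`, the Euler-Maruyama discretisation
#' of Gaussian white noise, so results are step-size-consistent; `"literal"`
#' perturbs the production *rate* by `N(0, sigma^2)` at each step (state
#' increment `dt * sigma * Z`), matching the common fixed-step recipe in
#' which noise is drawn per step without rescaling.  Negative intermediate
#' concentrations are clipped to zero.
#'
#' @param scenario A [crypt_scenario()].
#' @param params A [crypt_params()] object.
#' @param sigma Noise standard deviation (nM/min on the production rate).
#' @param dt Fixed time step (minutes).
#' @param n_runs Number of independent realisations.
#' @param seed Integer seed; the full ensemble is reproducible given `seed`.
#' @param mode `"wiener"` or `"literal"` (see above).
#' @param record_dt_min Output grid spacing (minutes; multiple of `dt`).
#' @return A list of `crypt_trajectory` objects, one per run.
#' @export
run_stochastic <- function(scenario, params = crypt_params(), sigma = 1,
                           dt = 0.1, n_runs = 10, seed = 1,
                           mode = c("wiener", "literal"),
                           record_dt_min = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "crypt_scenario"))
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  graph <- scenario$graph
  cells <- graph$cells
  n_cells <- length(cells)
  sp <- crypt_species()
  act_idx <- match(active_species(scenario$submodel), sp)
  frozen <- setdiff(seq_len(12L), act_idx)

  # neighbour-averaging matrix
  M <- matrix(0, n_cells, n_cells, dimnames = list(cells, cells))
  for (cl in cells) {
    nb <- graph$neighbours[[cl]]
    if (length(nb)) M[cl, nb] <- 1 / length(nb)
  }

  horizon <- scenario$hours * 60
  n_steps <- round(horizon / dt)
  rec_every <- max(1L, round(record_dt_min / dt))
  rec_steps <- seq(0L, n_steps, by = rec_every)
  rec_times <- rec_steps * dt

  ev <- scenario$events
  ev_step <- round(ev$time_h * 60 / dt)

  # state: (n_cells * n_runs) x 12, runs stacked blockwise
  S <- scenario$init[rep(seq_len(n_cells), times = n_runs), , drop = FALSE]
  env <- resolve_env(graph, params)
  Wv <- rep(env$W, times = n_runs)
  th <- rep(env$theta2, times = n_runs)
  rho <- rep(env$rho_APC, times = n_runs)

  set.seed(seed)
  noise_scale <- if (mode == "wiener") sigma * sqrt(dt) else sigma * dt
  h1_col <- match("H1", sp)

  rec <- array(NA_real_,
               dim = c(length(rec_times), n_cells, 12L, n_runs),
               dimnames = list(NULL, cells, sp, NULL))
  rec[1, , , ] <- aperm(array(S, dim = c(n_cells, n_runs, 12L)),
                        c(1, 3, 2))
  ri <- 1L
  for (step in seq_len(n_steps)) {
    Dmat <- matrix(S[, "D"], nrow = n_cells)     # cells x runs
    Dbar <- as.vector(M %*% Dmat)
    d <- rhs_matrix(S, Dbar = Dbar, W = Wv, params = params,
                    theta2 = th, rho_APC = rho)
    if (length(frozen)) d[, frozen] <- 0
    S <- S + dt * d
    if (sigma > 0 && !(h1_col %in% frozen)) {
      S[, h1_col] <- S[, h1_col] +
        noise_scale * stats::rnorm(n_cells * n_runs)
    }
    S[S < 0] <- 0
    if (length(ev_step) && any(ev_step == step)) {
      hits <- which(ev_step == step)
      for (i in hits) {
        j <- which(cells == ev$cell[i])
        idx <- j + n_cells * (seq_len(n_runs) - 1L)
        switch(ev$field[i],
               W = { Wv[idx] <- ev$value[i] },
               theta2 = { th[idx] <- ev$value[i] },
               rho_APC = { rho[idx] <- ev$value[i] })
      }
    }
    if (step %% rec_every == 0L) {
      ri <- ri + 1L
      rec[ri, , , ] <- aperm(array(S, dim = c(n_cells, n_runs, 12L)),
                             c(1, 3, 2))
    }
  }

  lapply(seq_len(n_runs), function(r) {
    new_trajectory(times = rec_times, conc = rec[, , , r, drop = FALSE][, , , 1],
                   events = ev, params = params, scenario = scenario,
                   meta = list(kind = "stochastic", sigma = sigma, dt = dt,
                               seed = seed, run = r, mode = mode))
  })
}
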
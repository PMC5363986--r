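# Steady-state machinery: the decoupled Wnt solution, multistart
# root-finding on the homogeneous system, and linear stability.

#' Decoupled Wnt-submodel steady state of beta-catenin
#'
#' Solves the implicit scalar equation for the beta-catenin steady state
#' `B*` of the five-species Wnt submodel, with the remaining species
#' eliminated explicitly: Axin follows `A* = (alpha_A/mu_A) act(B*)`, the
#' destruction-complex pool distributes according to the assembly/release
#' balance, and `B*` balances production `alpha3 + alpha4 W` against
#' complex-mediated consumption.  NICD enters as a fixed input `F_fix`
#' (zero for the fully decoupled submodel).
#'
#' @param params A [crypt_params()] object.
#' @param W Wnt stimulus, non-negative.
#' @param F_fix Fixed NICD concentration coupling into the B equation (nM).
#' @param gsk_total Total `G + C + I2` pool (nM).
#' @return `B*` in nM (the unique positive root).
#' @export
bstar_decoupled <- function(params, W, F_fix = 0, gsk_total = 50) {
  if (W < 0) stop("'W' must be non-negative", call. = FALSE)
  resid <- function(B) {
    wnt_b_residual(B, params, W, F_fix, gsk_total)
  }
  upper <- (params$alpha3 + params$alpha4 * W + 1e-12) /
    max(params$mu_B, 1e-12) + 1
  if (resid(upper) > 0) {
    stop("no positive beta-catenin steady state found (model inconsistency)",
         call. = FALSE)
  }
  stats::uniroot(resid, c(0, upper), tol = 1e-12)$root
}

wnt_b_residual <- function(B, params, W, F_fix, gsk_total) {
  st <- wnt_pool_split(B, params, W, gsk_total)
  params$alpha3 + params$alpha4 * W - params$k3 * F_fix * B -
    params$k_CB * st[["C"]] * B - params$mu_B * B
}

# Distribution of the conserved GSK pool (G, C, I2) and the Axin level for
# a given beta-catenin concentration, at the within-pool steady state.
wnt_pool_split <- function(B, params, W, gsk_total) {
  A <- params$alpha_A / params$mu_A * hill_act(B, params$kappa_A, params$n)
  assembly <- params$rho_APC * params$c_GC *
    hill_act(A, params$kappa_GA, params$n) *
    hill_inh(W, params$kappa_GW, params$n)
  q <- params$k_CB / params$k_I2
  if (assembly <= 0) {
    G <- gsk_total; C <- 0; I2 <- 0
  } else {
    r <- assembly / params$k_rev
    C <- gsk_total * r / (1 + r + r * q * B)
    G <- C / r
    I2 <- q * C * B
  }
  c(A = A, G = G, C = C, I2 = I2)
}

# Full decoupled Wnt steady state vector (the 5 Wnt species).
wnt_steady_state <- function(params, W, F_fix = 0, gsk_total = 50) {
  B <- bstar_decoupled(params, W, F_fix = F_fix, gsk_total = gsk_total)
  st <- wnt_pool_split(B, params, W, gsk_total)
  c(B = B, A = st[["A"]], G = st[["G"]], C = st[["C"]], I2 = st[["I2"]])
}

# Residual of the homogeneous system restricted to a submodel choice,
# with the GSK conservation law replaced by the pool-sum constraint so
# steady states are isolated points.
homogeneous_residual <- function(x, params, W, theta2, rho_APC, act,
                                 gsk_total, frozen_state) {
  ai <- match(act, crypt_species())
  full <- unname(frozen_state)
  full[ai] <- x
  d <- rhs_vec(full, Dbar = full[2L], W = W, params = params,
               theta2 = theta2, rho_APC = rho_APC)
  r <- d[ai]
  gpos <- match(10L, ai)
  if (!params$gsk_open && !is.na(gpos)) {
    r[gpos] <- (full[10L] + full[11L] + full[12L]) - gsk_total
  }
  stats::setNames(r, act)
}

# Long-time integration of the homogeneous system restricted to an active
# species set (frozen species held at frozen_state); returns the endpoint.
homogeneous_endpoint <- function(ic, params, W, theta2, rho_APC, act,
                                 frozen_state, hours) {
  ai <- match(act, crypt_species())
  base <- unname(frozen_state)
  derivs <- function(t, y, parms) {
    full <- base
    full[ai] <- y
    list(rhs_vec(full, Dbar = max(full[2L], 0), W = W, params = params,
                 theta2 = theta2, rho_APC = rho_APC)[ai])
  }
  sol <- tryCatch(
    suppressWarnings(
      deSolve::ode(y = unname(ic), times = c(0, hours * 60), func = derivs,
                   parms = NULL, method = "lsoda", rtol = 1e-7,
                   atol = 1e-9)),
    error = function(e) NULL)
  if (is.null(sol) || attr(sol, "istate")[1L] < 0) return(NULL)
  pmax(sol[nrow(sol), -1], 1e-8)
}

#' Multistart steady-state search on the homogeneous system
#'
#' Finds the non-negative steady states of the homogeneous single-cell
#' system (`Dbar = D`) by damped least-squares root-finding
#' (Levenberg-Marquardt on log-concentrations) from many starting points:
#' log-uniform draws over a physiological box plus the endpoints of a few
#' long-time integrations.  Under the closed GSK pool, steady states are
#' sought on the stoichiometric compatibility class `G + C + I2 =
#' gsk_total`, where they are isolated.  Converged roots are deduplicated
#' at relative tolerance `dedup_tol` and checked to satisfy
#' `max |rhs| < resid_tol`.
#'
#' @param params A [crypt_params()] object.
#' @param W Wnt stimulus (environment).
#' @param theta2,rho_APC Optional overrides.
#' @param submodel `"full"`, `"notch"` (Wnt species frozen at the standard
#'   state) or `"wnt"` (Notch species frozen).
#' @param n_starts Number of random starts.
#' @param seed Seed for the multistart draws.
#' @param dedup_tol Relative per-coordinate deduplication tolerance.
#' @param resid_tol Acceptance threshold on `max |rhs|` (nM/min).
#' @param gsk_total Conserved GSK pool (closed configuration).
#' @param box Log10 bounds of the search box (applied to every active
#'   species).
#' @param frozen_state Full 12-species state supplying the frozen species'
#'   values (default: [standard_state()] at the given `W`).
#' @param traj_starts How many of the random starts are refined by a
#'   long-time integration before root polishing (cheaper settings are
#'   useful in large parameter sweeps).
#' @param traj_hours Horizon of those integrations (h).
#' @param active Optional character vector naming the species treated as
#'   dynamic, overriding the submodel's default set (used e.g. by
#'   [multistability_probe()], where a decoupled network carries a
#'   crosstalk species as a full reactant).
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A `steady_state_report`: list with `states` (matrix, one row per
#'   distinct steady state), `eigenvalues` (list of complex spectra of the
#'   reduced Jacobian), `stability` (labels `"stable"`, `"unstable"`, with
#'   `"-focus"` suffix when the leading eigenvalues are a complex pair),
#'   `basin_counts` (starts converged to each), and `n_converged`.  With no
#'   converged starts, `states` has zero rows (no error).
#' @export
find_steady_states <- function(params, W = 1, theta2 = params$theta2,
                               rho_APC = params$rho_APC,
                               submodel = c("full", "notch", "wnt"),
                               n_starts = 100, seed = 1, dedup_tol = 1e-4,
                               resid_tol = 1e-10, gsk_total = 50,
                               box = c(-3, 2), frozen_state = NULL,
                               traj_starts = 5, traj_hours = 72,
                               active = NULL, maxiter = 200) {
  submodel <- match.arg(submodel)
  if (n_starts < 1) stop("'n_starts' must be >= 1", call. = FALSE)
  sp <- crypt_species()
  if (is.null(frozen_state)) {
    frozen_state <- tryCatch(standard_state(params, W = W,
                                            gsk_total = gsk_total),
                             error = function(e) {
                               stats::setNames(rep(1, 12), sp)
                             })
  }
  act <- if (is.null(active)) active_species(submodel) else active
  if (!all(act %in% sp)) stop("'active' contains unknown species",
                              call. = FALSE)
  n_act <- length(act)

  set.seed(seed)
  starts <- matrix(10^stats::runif(n_starts * n_act, box[1], box[2]),
                   ncol = n_act, dimnames = list(NULL, act))
  # a few integration endpoints as extra, well-informed starts
  n_traj <- min(as.integer(traj_starts), n_starts)
  for (i in seq_len(n_traj)) {
    endpt <- homogeneous_endpoint(starts[i, ], params, W, theta2, rho_APC,
                                  act, frozen_state, traj_hours)
    if (!is.null(endpt)) starts[i, ] <- endpt
  }

  resid_log <- function(u) {
    homogeneous_residual(exp(u), params, W, theta2, rho_APC, act,
                         gsk_total, frozen_state)
  }

  roots <- NULL
  counts <- integer(0)
  n_conv <- 0L
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(pmax(starts[i, ], 1e-10)),
                         fn = resid_log,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    x <- exp(fit$par)
    r <- homogeneous_residual(x, params, W, theta2, rho_APC, act,
                              gsk_total, frozen_state)
    if (max(abs(r)) >= resid_tol) next
    n_conv <- n_conv + 1L
    matched <- FALSE
    if (!is.null(roots)) {
      for (j in seq_len(nrow(roots))) {
        scale <- pmax(abs(roots[j, ]), 1e-3)
        if (all(abs(x - roots[j, ]) / scale < dedup_tol)) {
          counts[j] <- counts[j] + 1L
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) {
      roots <- rbind(roots, x)
      counts <- c(counts, 1L)
    }
  }

  if (is.null(roots)) {
    return(structure(list(states = matrix(numeric(0), 0, n_act,
                                          dimnames = list(NULL, act)),
                          eigenvalues = list(), stability = character(0),
                          basin_counts = integer(0), n_converged = 0L,
                          submodel = submodel, W = W),
                     class = "steady_state_report"))
  }
  rownames(roots) <- NULL
  colnames(roots) <- act
  eig <- vector("list", nrow(roots))
  stab <- character(nrow(roots))
  for (j in seq_len(nrow(roots))) {
    full <- frozen_state
    full[act] <- roots[j, ]
    eig[[j]] <- jacobian_eigenvalues(full, params, W = W, theta2 = theta2,
                                     rho_APC = rho_APC, submodel = submodel,
                                     resid_tol = Inf, active = act)
    lead <- eig[[j]][which.max(Re(eig[[j]]))]
    label <- if (Re(lead) < 0) "stable" else "unstable"
    if (abs(Im(lead)) > 1e-12) label <- paste0(label, "-focus")
    stab[j] <- label
  }
  ord <- order(roots[, if ("H1" %in% act) "H1" else 1])
  structure(list(states = roots[ord, , drop = FALSE],
                 eigenvalues = eig[ord], stability = stab[ord],
                 basin_counts = counts[ord], n_converged = n_conv,
                 submodel = submodel, W = W),
            class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat("steady_state_report (", x$submodel, ", W = ", x$W, "): ",
      nrow(x$states), " state(s), ", x$n_converged,
      " converged starts\n", sep = "")
  if (nrow(x$states)) {
    tab <- cbind(signif(x$states, 5), starts = x$basin_counts)
    print(data.frame(tab, stability = x$stability,
                     check.names = FALSE), row.names = FALSE)
  }
  invisible(x)
}

#' Jacobian spectrum at a steady state
#'
#' Eigenvalues of the Jacobian of the homogeneous system at a steady state,
#' computed by central finite differences with step
#' `max(1e-6, 1e-6 |x|)`.  Under the closed GSK pool the Jacobian is
#' evaluated on the reduced system in which `G = gsk_total - C - I2`, so
#' the structural zero mode of the conservation law is removed and the
#' stability label reflects dynamics within the compatibility class.
#'
#' @param state Full named 12-species state; must satisfy
#'   `max |rhs| < resid_tol`.
#' @param params A [crypt_params()] object.
#' @param W,theta2,rho_APC Environment.
#' @param submodel Which subsystem the spectrum refers to.
#' @param resid_tol Steady-state precondition tolerance (nM/min).
#' @param active Optional explicit dynamic-species set overriding the
#'   submodel default.
#' @return Complex eigenvalue vector (1/min).
#' @export
jacobian_eigenvalues <- function(state, params, W = 1,
                                 theta2 = params$theta2,
                                 rho_APC = params$rho_APC,
                                 submodel = "full", resid_tol = 1e-8,
                                 active = NULL) {
  sp <- crypt_species()
  state <- state[sp]
  act <- if (is.null(active)) active_species(submodel) else active
  if (is.finite(resid_tol)) {
    d <- full_rhs(state, Dbar = state[["D"]], W = W, params = params,
                  theta2 = theta2, rho_APC = rho_APC)
    if (max(abs(d[act])) >= resid_tol) {
      stop("'state' is not a steady state (max |rhs| = ",
           signif(max(abs(d[act])), 3), ")", call. = FALSE)
    }
  }
  reduce <- !params$gsk_open && all(c("G", "C", "I2") %in% act)
  vars <- if (reduce) setdiff(act, "G") else act
  vi <- match(vars, sp)
  total <- state[["G"]] + state[["C"]] + state[["I2"]]
  base <- unname(state)
  fn <- function(x) {
    full <- base
    full[vi] <- x
    if (reduce) full[10L] <- max(total - full[11L] - full[12L], 0)
    rhs_vec(full, Dbar = full[2L], W = W, params = params,
            theta2 = theta2, rho_APC = rho_APC)[vi]
  }
  x0 <- state[vars]
  nv <- length(vars)
  J <- matrix(0, nv, nv)
  for (j in seq_len(nv)) {
    h <- max(1e-6, 1e-6 * abs(x0[j]))
    xp <- x0; xp[j] <- x0[j] + h
    xm <- x0; xm[j] <- max(x0[j] - h, 0)
    J[, j] <- (fn(xp) - fn(xm)) / (xp[j] - xm[j])
  }
  eigen(J, only.values = TRUE)$values
}
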
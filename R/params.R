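#' Species names of the per-cell model
#'
#' The twelve per-cell state variables, in canonical order: the seven Notch
#' species N (Notch receptor), D (Delta ligand), F (NICD), I1
#' (NICD:beta-catenin complex), H1 (Hes1), H2 (Hath1), P (Ngn3); and the
#' five Wnt species B (beta-catenin), A (Axin), G (free GSK3beta), C
#' (destruction complex), I2 (destruction-complex:beta-catenin complex).
#' All concentrations are in nM.
#'
#' @return Character vector of length 12.
#' @export
crypt_species <- function() {
  c("N", "D", "F", "I1", "H1", "H2", "P", "B", "A", "G", "C", "I2")
}

NOTCH_SPECIES <- c("N", "D", "F", "I1", "H1", "H2", "P")
WNT_SPECIES <- c("B", "A", "G", "C", "I2")

#' Model parameter set
#'
#' Constructs a validated parameter set for the coupled Notch-Wnt model.
#' Called with no arguments it returns the package's fitted defaults (see the
#' methods vignette for the calibration targets: a 2 h homogeneous Hes1
#' oscillation period and the beta-catenin fold-change response to Wnt
#' hyperstimulation).  Time is in minutes, concentrations in nM; the Wnt
#' stimulus `W` is dimensionless with `W = 1` equivalent to 100 ng/ml.
#'
#' @param ... Named overrides of individual parameters.
#' @param gsk_open If `TRUE`, free GSK3beta and the destruction complex are
#'   additionally subject to first-order decay at rates `mu_G`, `mu_C`,
#'   `mu_I2` (an open GSK pool).  The default (`FALSE`) treats the GSK pool
#'   as closed, so `G + C + I2` is conserved along trajectories.
#' @return An object of class `crypt_params` (a named list).
#' @section Parameter groups:
#' \describe{
#'   \item{Production rates (nM/min)}{`alpha_N`, `alpha_D`, `alpha_P`,
#'     `alpha_H1`, `alpha_H2`, `alpha_A`, and the beta-catenin production
#'     coefficients `alpha3` (basal) and `alpha4` (per unit Wnt stimulus).}
#'   \item{Decay rates (1/min)}{`mu_N`, `mu_D`, `mu_F`, `mu_I1`, `mu_H1`,
#'     `mu_H2`, `mu_P`, `mu_B`, `mu_A`.}
#'   \item{Binding / conversion rates}{`k3` (NICD + B -> I1, 1/(nM min)),
#'     `k_CB` (C + B -> I2, 1/(nM min)), `k_cl` (Notch cleavage, 1/min),
#'     `k_rev` (C -> G, 1/min), `k_I2` (I2 -> C, 1/min), `c_GC` (scale of
#'     the destruction-complex assembly rate, 1/min).}
#'   \item{Hill constants (nM unless stated)}{`kappa1` (Dbar -> N),
#'     `kappa2` (H1 -| P), `kappa3` (P -> D), `kappa4` (I1 -> H1),
#'     `kappa5` (H1 autorepression), `kappa6` (H1 -| H2), `kappa7`
#'     (B -> H1), `kappa_A` (B -> A), `kappa_GA` (Axin dependence of
#'     complex assembly), and the dimensionless-W constants `kappa_psi`,
#'     `kappa_GW`.}
#'   \item{Exponents and switches}{`m`, `n` (default 3); `theta2` in [0, 1],
#'     the proportion of Notch-mediated Hes1 transcription; `rho_APC` in
#'     [0, 1], scaling destruction-complex formation (1 healthy, 0.5 single
#'     APC hit, 0 two-hit mutant).}
#' }
#' @examples
#' p <- crypt_params(theta2 = 1, rho_APC = 0.5)
#' p$theta2
#' @export
crypt_params <- function(..., gsk_open = FALSE) {
  p <- default_param_values()
  p$gsk_open <- isTRUE(gsk_open)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_params(p)
  structure(p, class = "crypt_params")
}

# Fitted default values. Calibration: the Notch block is fitted (sequential
# 1D grid search, most-sensitive-first) so that a homogeneous cell pair
# oscillates in Hes1 with a 2 h period; the Wnt block so that the
# hyperstimulated (W = 2) beta-catenin steady state sits 2.2x above the
# W = 1 state and 8.3x above the W = 0 state. See the methods vignette.
default_param_values <- function() {
  list(
    # Notch block
    alpha_N = 0.144673157, kappa1 = 0.6850067106,
    k_cl = 0.04210861118, mu_N = 0.03890835673,
    mu_F = 0.08101696792, k3 = 8.421722237e-06,
    mu_I1 = 0.08101696792, kappa4 = 1.469892908e-04,
    alpha_H1 = 0.19689163, kappa5 = 3.001125704,
    mu_H1 = 0.08101696792, kappa7 = 9.0,
    kappa_psi = 1.5,
    alpha_H2 = 0.03368688895, kappa6 = 1.0, mu_H2 = 0.01684344447,
    alpha_P = 0.1157385256, kappa2 = 1.094879785, mu_P = 0.08101696792,
    alpha_D = 0.144673157, kappa3 = 0.5480053685, mu_D = 0.08101696792,
    theta2 = 0.75,
    # Wnt block
    alpha3 = 7.496114253e-05, alpha4 = 0.4715879316, mu_B = 6.36e-06,
    alpha_A = 0.02, mu_A = 0.02, kappa_A = 9.6,
    c_GC = 0.04686581064, k_rev = 0.05,
    kappa_GA = 0.5808523653, kappa_GW = 3.181678038,
    k_CB = 0.003, k_I2 = 0.05659090909,
    rho_APC = 1.0,
    # exponents
    m = 3, n = 3,
    # open-pool decay rates (used only when gsk_open = TRUE)
    mu_G = 1e-04, mu_C = 1e-04, mu_I2 = 1e-04,
    gsk_open = FALSE
  )
}

validate_params <- function(p) {
  rates <- setdiff(names(p), c("theta2", "rho_APC", "m", "n", "gsk_open"))
  num <- unlist(p[rates])
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("all rates and constants must be finite and non-negative",
         call. = FALSE)
  }
  if (p$theta2 < 0 || p$theta2 > 1) {
    stop("'theta2' must lie in [0, 1]", call. = FALSE)
  }
  if (p$rho_APC < 0 || p$rho_APC > 1) {
    stop("'rho_APC' must lie in [0, 1]", call. = FALSE)
  }
  if (p$m < 1 || p$n < 1) stop("exponents must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.crypt_params <- function(x, ...) {
  cat("Notch-Wnt model parameters (", if (x$gsk_open) "open" else "closed",
      " GSK pool)\n", sep = "")
  cat("  theta2 =", x$theta2, " rho_APC =", x$rho_APC,
      " m =", x$m, " n =", x$n, "\n")
  nm <- setdiff(names(x), c("theta2", "rho_APC", "m", "n", "gsk_open"))
  v <- unlist(x[nm])
  print(signif(v, 4))
  invisible(x)
}

#' Read or write a parameter set as a YAML config
#'
#' A round-trippable plain-text representation of a [crypt_params()] object.
#' The canonical defaults ship with the package at
#' `system.file("extdata", "defaults.yaml", package = "notchwnt")`.
#'
#' @param path File path.
#' @param params A `crypt_params` object (for writing).
#' @return `read_params()` returns a `crypt_params` object.
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  gsk_open <- isTRUE(vals$gsk_open)
  vals$gsk_open <- NULL
  do.call(crypt_params, c(vals, list(gsk_open = gsk_open)))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "crypt_params"))
  yaml::write_yaml(lapply(unclass(params), identity), path,
                   precision = 15L)
  invisible(path)
}
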
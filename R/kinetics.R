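#' Hill activation function
#'
#' Saturating activation kinetics \eqn{x^n / (\kappa^n + x^n)} used for all
#' transcriptional upregulation events in the model (Delta-dependent Notch
#' production, Ngn3-dependent Delta production, promoter activation by the
#' NICD:beta-catenin complex and by beta-catenin, and beta-catenin-dependent
#' Axin induction).
#'
#' @param x Activator concentration (nM), non-negative. Vectorised.
#' @param kappa Half-saturation constant (nM), strictly positive.
#' @param n Hill exponent, >= 1.
#' @return Dimensionless response in `[0, 1)`, strictly increasing in `x`.
#' @examples
#' hill_act(0, 1, 3)       # 0
#' hill_act(1, 1, 3)       # 0.5 at half-saturation
#' hill_act(2, 1, 3)       # 8/9
#' @seealso [hill_inh()] for the complementary inhibition form.
#' @export
hill_act <- function(x, kappa, n) {
  check_hill_args(x, kappa, n)
  xn <- (x / kappa)^n
  xn / (1 + xn)
}

#' Hill inhibition function (hyperbolic repression)
#'
#' Repression kinetics \eqn{1 / (1 + (x/\kappa)^m)} used for all inhibition
#' events: Hes1 autorepression, Hes1 repression of Ngn3 and Hath1, and the
#' Wnt-dependent factors.  For matching arguments,
#' `hill_act(x, k, n) + hill_inh(x, k, n) == 1`.
#'
#' @param x Inhibitor concentration (nM), non-negative. Vectorised.
#' @param kappa Half-repression constant (nM), strictly positive.
#' @param m Exponent, >= 1.
#' @return Dimensionless response in `(0, 1]`, strictly decreasing in `x`.
#' @export
hill_inh <- function(x, kappa, m) {
  check_hill_args(x, kappa, m)
  1 / (1 + (x / kappa)^m)
}

# Unchecked variants for the right-hand-side hot path, where the state is
# already clamped non-negative and the parameter object was validated at
# construction time.
ha_ <- function(x, kappa, n) {
  xn <- (x / kappa)^n
  xn / (1 + xn)
}
hi_ <- function(x, kappa, m) 1 / (1 + (x / kappa)^m)

check_hill_args <- function(x, kappa, n) {
  if (any(!is.finite(kappa)) || any(kappa <= 0)) {
    stop("'kappa' must be strictly positive", call. = FALSE)
  }
  if (any(n < 1)) stop("Hill exponent must be >= 1", call. = FALSE)
  if (any(x < 0)) stop("concentration must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Dishevelled-mediated repression of Hes1 production
#'
#' A high extracellular Wnt stimulus recruits Dishevelled, which lowers the
#' levels of the NICD coactivator CSL and thereby downregulates Hes1
#' transcription.  Dishevelled is not an explicit state variable; the effect
#' is represented by the multiplicative factor
#' \eqn{\Psi_W(W) = 1/(1 + (W/\kappa_\Psi)^n)} applied to Hes1 production.
#'
#' @param W Extracellular Wnt stimulus (dimensionless; `W = 1` corresponds to
#'   the 100 ng/ml reference used for nondimensionalisation).
#' @param params A [crypt_params()] object (uses `kappa_psi` and `n`).
#' @return Factor in `(0, 1]`; equals 1 at `W = 0`.
#' @export
psi_w <- function(W, params) {
  if (any(W < 0)) stop("'W' must be non-negative", call. = FALSE)
  hill_inh(W, params$kappa_psi, params$n)
}

#' Wnt- and Axin-dependent destruction complex assembly rate
#'
#' Rate (min^-1) at which free GSK3beta is incorporated into the
#' beta-catenin destruction complex, \eqn{\Psi_{W,A}(W, A) = c_{GC}\,
#' \mathrm{act}(A; \kappa_{GA}) \, \mathrm{inh}(W; \kappa_{GW})}.  Assembly
#' requires the Axin scaffold (zero when `A = 0`) and is suppressed by the
#' Wnt stimulus, which is the route by which Wnt elevates beta-catenin.
#'
#' @param W Extracellular Wnt stimulus, non-negative.
#' @param A Axin concentration (nM), non-negative.
#' @param params A [crypt_params()] object (uses `c_GC`, `kappa_GA`,
#'   `kappa_GW`, `n`).
#' @return Per-capita conversion rate of G into C (min^-1).
#' @export
psi_wa <- function(W, A, params) {
  if (any(W < 0) || any(A < 0)) {
    stop("'W' and 'A' must be non-negative", call. = FALSE)
  }
  params$c_GC * hill_act(A, params$kappa_GA, params$n) *
    hill_inh(W, params$kappa_GW, params$n)
}

#' Hes1 production rate at the crosstalk promoter hub
#'
#' The Hes1 promoter integrates two transcription routes: a Notch-mediated
#' route driven by the NICD:beta-catenin complex `I1` (weight `theta2`) and a
#' Wnt-mediated route driven by direct beta-catenin binding (weight
#' `1 - theta2`; beta-catenin is not consumed by this route).  The summed
#' activation is scaled by Dishevelled-mediated repression [psi_w()] and by
#' Hes1 autorepression.
#'
#' @param I1 NICD:beta-catenin complex concentration (nM).
#' @param B beta-catenin concentration (nM).
#' @param H1 Hes1 concentration (nM).
#' @param W Extracellular Wnt stimulus.
#' @param params A [crypt_params()] object.
#' @param theta2 Optional override of `params$theta2`, the proportion of
#'   Notch-mediated control of the promoter (0 = wholly Wnt-mediated,
#'   1 = entirely Notch-mediated).
#' @return Production rate of Hes1 (nM min^-1).
#' @export
hes1_production <- function(I1, B, H1, W, params, theta2 = params$theta2) {
  if (any(theta2 < 0) || any(theta2 > 1)) {
    stop("'theta2' must lie in [0, 1]", call. = FALSE)
  }
  if (any(I1 < 0) || any(B < 0) || any(H1 < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  route <- theta2 * hill_act(I1, params$kappa4, params$n) +
    (1 - theta2) * hill_act(B, params$kappa7, params$n)
  params$alpha_H1 * route * psi_w(W, params) *
    hill_inh(H1, params$kappa5, params$m)
}
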
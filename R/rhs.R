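#' Right-hand side of the twelve-species per-cell model
#'
#' Time derivatives (nM/min) of the coupled Notch-Wnt reaction network for a
#' single cell, given the mean Delta concentration presented by its
#' neighbours.  Decays are first-order; upregulation uses Hill activation;
#' inhibition uses hyperbolas; the two binding reactions (NICD +
#' beta-catenin, destruction complex + beta-catenin) are mass action.  Under
#' the default closed GSK pool the sum `G + C + I2` has zero net derivative.
#'
#' @param state Named numeric vector of the 12 species (see
#'   [crypt_species()]), non-negative.
#' @param Dbar Mean neighbouring Delta concentration (nM), non-negative.
#' @param W Extracellular Wnt stimulus for this cell.
#' @param params A [crypt_params()] object.
#' @param theta2,rho_APC Optional per-cell overrides of the corresponding
#'   parameters (used by mutation scenarios).
#' @return Named numeric vector of 12 derivatives.
#' @export
full_rhs <- function(state, Dbar, W, params,
                     theta2 = params$theta2, rho_APC = params$rho_APC) {
  sp <- crypt_species()
  if (length(state) != 12L) {
    stop("'state' must have 12 entries", call. = FALSE)
  }
  if (is.null(names(state))) {
    names(state) <- sp
  } else if (!identical(names(state), sp)) {
    if (!setequal(names(state), sp)) {
      stop("'state' names must be the 12 model species", call. = FALSE)
    }
    state <- state[sp]
  }
  if (Dbar < 0) stop("'Dbar' must be non-negative", call. = FALSE)
  d <- rhs_matrix(matrix(state, nrow = 1, dimnames = list(NULL, sp)),
                  Dbar = Dbar, W = W, params = params,
                  theta2 = theta2, rho_APC = rho_APC)
  stats::setNames(drop(d), sp)
}

# Scalar fast path over an unnamed positional state vector (canonical
# species order), used by the steady-state machinery where the right-hand
# side is evaluated many thousands of times per search.
rhs_vec <- function(sv, Dbar, W, params, theta2, rho_APC) {
  params <- unclass(params)  # avoid S3 dispatch cost on every `$` access
  sv[sv < 0] <- 0
  n <- params$n; m <- params$m
  N <- sv[1L]; D <- sv[2L]; F <- sv[3L]; I1 <- sv[4L]
  H1 <- sv[5L]; H2 <- sv[6L]; P <- sv[7L]; B <- sv[8L]
  A <- sv[9L]; G <- sv[10L]; C <- sv[11L]; I2 <- sv[12L]
  hes1 <- params$alpha_H1 *
    (theta2 * ha_(I1, params$kappa4, n) +
       (1 - theta2) * ha_(B, params$kappa7, n)) *
    hi_(W, params$kappa_psi, n) * hi_(H1, params$kappa5, m)
  assembly <- rho_APC * params$c_GC *
    ha_(A, params$kappa_GA, n) * hi_(W, params$kappa_GW, n)
  bindNB <- params$k3 * F * B
  bindCB <- params$k_CB * C * B
  out <- c(
    params$alpha_N * ha_(Dbar, params$kappa1, n) -
      (params$k_cl + params$mu_N) * N,
    params$alpha_D * ha_(P, params$kappa3, n) - params$mu_D * D,
    params$k_cl * N - bindNB - params$mu_F * F,
    bindNB - params$mu_I1 * I1,
    hes1 - params$mu_H1 * H1,
    params$alpha_H2 * hi_(H1, params$kappa6, m) - params$mu_H2 * H2,
    params$alpha_P * hi_(H1, params$kappa2, m) - params$mu_P * P,
    params$alpha3 + params$alpha4 * W - bindNB - bindCB - params$mu_B * B,
    params$alpha_A * ha_(B, params$kappa_A, n) - params$mu_A * A,
    params$k_rev * C - assembly * G,
    assembly * G - params$k_rev * C - bindCB + params$k_I2 * I2,
    bindCB - params$k_I2 * I2)
  if (isTRUE(params$gsk_open)) {
    out[10L] <- out[10L] - params$mu_G * G
    out[11L] <- out[11L] - params$mu_C * C
    out[12L] <- out[12L] - params$mu_I2 * I2
  }
  out
}

# Vectorised core: `states` is an n x 12 matrix (rows = cells or ensemble
# members); Dbar, W, theta2, rho_APC recycle along rows. Negative state
# entries (transient integrator excursions) are clamped to zero for rate
# evaluation only.
rhs_matrix <- function(states, Dbar, W, params,
                       theta2 = params$theta2, rho_APC = params$rho_APC) {
  params <- unclass(params)  # avoid S3 dispatch cost on every `$` access
  s <- pmax(states, 0)
  n <- params$n
  m <- params$m
  N <- s[, 1L]; D <- s[, 2L]; F <- s[, 3L]; I1 <- s[, 4L]
  H1 <- s[, 5L]; H2 <- s[, 6L]; P <- s[, 7L]; B <- s[, 8L]
  A <- s[, 9L]; G <- s[, 10L]; C <- s[, 11L]; I2 <- s[, 12L]

  hes1 <- params$alpha_H1 *
    (theta2 * ha_(I1, params$kappa4, n) +
       (1 - theta2) * ha_(B, params$kappa7, n)) *
    hi_(W, params$kappa_psi, n) *
    hi_(H1, params$kappa5, m)
  assembly <- rho_APC * params$c_GC *
    ha_(A, params$kappa_GA, n) * hi_(W, params$kappa_GW, n)

  bindNB <- params$k3 * F * B
  bindCB <- params$k_CB * C * B

  out <- cbind(
    N  = params$alpha_N * ha_(Dbar, params$kappa1, n) -
      (params$k_cl + params$mu_N) * N,
    D  = params$alpha_D * ha_(P, params$kappa3, n) - params$mu_D * D,
    F  = params$k_cl * N - bindNB - params$mu_F * F,
    I1 = bindNB - params$mu_I1 * I1,
    H1 = hes1 - params$mu_H1 * H1,
    H2 = params$alpha_H2 * hi_(H1, params$kappa6, m) -
      params$mu_H2 * H2,
    P  = params$alpha_P * hi_(H1, params$kappa2, m) - params$mu_P * P,
    B  = params$alpha3 + params$alpha4 * W - bindNB - bindCB -
      params$mu_B * B,
    A  = params$alpha_A * ha_(B, params$kappa_A, n) - params$mu_A * A,
    G  = params$k_rev * C - assembly * G,
    C  = assembly * G - params$k_rev * C - bindCB + params$k_I2 * I2,
    I2 = bindCB - params$k_I2 * I2
  )
  if (isTRUE(params$gsk_open)) {
    out[, "G"] <- out[, "G"] - params$mu_G * G
    out[, "C"] <- out[, "C"] - params$mu_C * C
    out[, "I2"] <- out[, "I2"] - params$mu_I2 * I2
  }
  out
}
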
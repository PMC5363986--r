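#' Machine-readable model description
#'
#' Exports the per-cell model as structured JSON: the species list, the
#' parameter values, and one record per rate term (production, conversion,
#' binding or decay) with its symbolic rate expression and influence
#' annotations.  The reaction records correspond one-to-one with the
#' reactions of [build_network()] for the full variant, so the structural
#' module can be driven from this document.
#'
#' @param params A [crypt_params()] object.
#' @param path Optional file to write the JSON to.
#' @return The description as a list (invisibly when `path` is given).
#' @export
model_description <- function(params = crypt_params(), path = NULL) {
  term <- function(label, rate, reactants = character(0),
                   products = character(0), promoters = character(0),
                   inhibitors = character(0)) {
    list(label = label, rate = rate, reactants = as.list(reactants),
         products = as.list(products), promoters = as.list(promoters),
         inhibitors = as.list(inhibitors))
  }
  reactions <- list(
    term("notch_production", "alpha_N * Dbar^n / (kappa1^n + Dbar^n)",
         products = "N", promoters = "D"),
    term("notch_cleavage", "k_cl * N", reactants = "N", products = "F"),
    term("nicd_bcat_binding", "k3 * F * B", reactants = c("F", "B"),
         products = "I1"),
    term("hes1_transcription_notch",
         paste("alpha_H1 * theta2 * I1^n / (kappa4^n + I1^n)",
               "* 1/(1 + (W/kappa_psi)^n) * 1/(1 + (H1/kappa5)^m)"),
         products = "H1", promoters = "I1", inhibitors = "H1"),
    term("hes1_transcription_wnt",
         paste("alpha_H1 * (1 - theta2) * B^n / (kappa7^n + B^n)",
               "* 1/(1 + (W/kappa_psi)^n) * 1/(1 + (H1/kappa5)^m)"),
         products = "H1", promoters = "B", inhibitors = "H1"),
    term("hath1_production", "alpha_H2 / (1 + (H1/kappa6)^m)",
         products = "H2", inhibitors = "H1"),
    term("ngn3_production", "alpha_P / (1 + (H1/kappa2)^m)",
         products = "P", inhibitors = "H1"),
    term("delta_production", "alpha_D * P^n / (kappa3^n + P^n)",
         products = "D", promoters = "P"),
    term("bcat_basal_production", "alpha3", products = "B"),
    term("bcat_wnt_production", "alpha4 * W", products = "B"),
    term("axin_production", "alpha_A * B^n / (kappa_A^n + B^n)",
         products = "A", promoters = "B"),
    term("complex_assembly",
         paste("rho_APC * c_GC * A^n / (kappa_GA^n + A^n)",
               "* 1/(1 + (W/kappa_GW)^n) * G"),
         reactants = "G", products = "C", promoters = "A"),
    term("complex_release", "k_rev * C", reactants = "C", products = "G"),
    term("complex_bcat_binding", "k_CB * C * B", reactants = c("C", "B"),
         products = "I2"),
    term("i2_release", "k_I2 * I2", reactants = "I2", products = "C")
  )
  for (s in c("N", "D", "F", "I1", "H1", "H2", "P", "B", "A")) {
    mu <- paste0("mu_", if (s == "I1") "I1" else s)
    reactions[[length(reactions) + 1L]] <-
      term(paste0("decay_", s), paste0(mu, " * ", s), reactants = s)
  }
  desc <- list(
    species = as.list(crypt_species()),
    units = list(concentration = "nM", time = "min",
                 wnt_reference = "W = 1 corresponds to 100 ng/ml"),
    parameters = unclass(params),
    reactions = reactions,
    coupling = "Dbar = mean Delta over graph neighbours (0 if isolated)",
    conservation = "G + C + I2 constant (closed pool configuration)"
  )
  if (!is.null(path)) {
    jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(desc))
  }
  desc
}
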
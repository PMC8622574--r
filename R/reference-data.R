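#' Bundled reference tables from a human mastication panel
#'
#' Curated reference values reported for selected fast and slow chewers in a
#' 17-person mastication panel of differently processed cooked black beans
#' (sample A: pulsed-electric-field treated then cooked without CaCl2;
#' sample B: PEF treated then cooked with 300 ppm CaCl2; sample C: cooked
#' with CaCl2 only). They serve as worked-example inputs: generator settings
#' for the synthetic-data module and ground truth for arithmetic identities
#' such as the starch-fraction balance.
#'
#' Available tables:
#' * `"starch_kinetics"` — fractional conversion parameters (`s0_mg`,
#'   `sf_mg`, `ks_e2_per_min`, i.e. ks x 10^-2 min^-1) per participant and
#'   sample.
#' * `"protein_rates"` — zero-order protein digestion rates
#'   (`kp_e2_per_min`).
#' * `"starch_fractions"` — RDS/SDS/RS percentages.
#' * `"rr_parameters"` — panel-average Rosin-Rammler `x50` (mm^2) and `b`
#'   per sample and colour class.
#' * `"pef_treatments"` — pulse settings and specific energy of the three
#'   bean treatments.
#'
#' @param name One of the table names above.
#' @return A tibble.
#' @examples
#' reference_table("pef_treatments")
#' @export
reference_table <- function(name = c("starch_kinetics", "protein_rates",
                                     "starch_fractions", "rr_parameters",
                                     "pef_treatments")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".csv"),
                      package = "beanbolus", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
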
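ref_path <- function(file) {
  p <- system.file("extdata", file, package = "skinflux")
  if (p == "") stop("packaged reference file not found: ", file, call. = FALSE)
  p
}

#' Packaged reference datasets: the PER solvent screen
#'
#' Published summary data for the model permeant 4-phenylethyl-resorcinol
#' (PER) screened in 13 cosmetic solvents (coded S1-S13): solvent panel
#' with approximate and equilibrium solubilities, per-solvent Skin-PAMPA
#' permeation metrics (13 solvents, 6 h assay), ex vivo pig-ear-skin
#' permeation metrics (9 solvents, 16 h assay) and the compound's
#' physico-chemical properties. These serve as worked-example inputs and
#' as regression anchors for the analysis operations.
#'
#' In the skin table the donor concentration for S8 is shipped in two
#' variants: `cd_mg_ml` carries the value as printed in the source
#' summary (51 mg/mL), `cd_corrected_mg_ml` the value consistent with the
#' solvent panel's equilibrium solubility and with back-calculation of the
#' printed logK_p (5.1 mg/mL) - an apparent decimal typo in the source,
#' preserved rather than silently fixed.
#'
#' @return `ref_solvents()`, `ref_pampa()`, `ref_pigskin()` and
#'   `ref_compound()` each return a `data.frame`; `ref_tables()` returns
#'   all four in a named list.
#' @examples
#' nrow(ref_pampa())    # 13 solvents
#' nrow(ref_pigskin())  # 9 solvents
#' @export
ref_solvents <- function() {
  utils::read.csv(ref_path("per_solvents.csv"), stringsAsFactors = FALSE,
                  colClasses = c(mw = "character",
                                 approx_solubility = "character"))
}

#' @rdname ref_solvents
#' @export
ref_pampa <- function() {
  utils::read.csv(ref_path("per_pampa_metrics.csv"), stringsAsFactors = FALSE)
}

#' @rdname ref_solvents
#' @export
ref_pigskin <- function() {
  utils::read.csv(ref_path("per_pigskin_metrics.csv"), stringsAsFactors = FALSE)
}

#' @rdname ref_solvents
#' @export
ref_compound <- function() {
  utils::read.csv(ref_path("per_compound.csv"), stringsAsFactors = FALSE)
}

#' @rdname ref_solvents
#' @export
ref_tables <- function() {
  list(solvents = ref_solvents(), pampa = ref_pampa(),
       pigskin = ref_pigskin(), compound = ref_compound())
}

#' Pair the packaged reference tables
#'
#' Convenience wrapper joining the packaged screen and skin metric tables
#' with [pair_models()] (9 paired solvents).
#'
#' @return A `paired_permeability` frame.
#' @export
ref_paired <- function() {
  pampa <- ref_pampa(); skin <- ref_pigskin()
  pair_models(
    data.frame(code = pampa$code, logPm_mean = pampa$logpm_mean,
               auc_norm_mean = pampa$auc_norm, J_mean = pampa$j_mean,
               stringsAsFactors = FALSE),
    data.frame(code = skin$code, logKp_mean = skin$logkp_mean,
               Q_mean = skin$q16h_mean, J_mean = skin$j_mean,
               stringsAsFactors = FALSE))
}
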
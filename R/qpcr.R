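#' qPCR amplification efficiency from a standard-curve slope
#'
#' `efficiency = 10^(-1/slope)`; a perfect doubling assay has slope
#' -3.3219 and efficiency 2.  Efficiencies outside (1, 2.2] are chemically
#' implausible and trigger a warning.
#'
#' @param slope Standard-curve slope (Ct per log10 dilution), `< 0`.
#' @return Amplification efficiency.
#' @export
qpcr_efficiency <- function(slope) {
  if (!is.numeric(slope) || any(slope >= 0))
    stop("standard-curve slope must be negative")
  e <- 10^(-1 / slope)
  if (any(e <= 1 | e > 2.2))
    warning("efficiency outside (1, 2.2]: implausible chemistry")
  e
}

#' Relative qPCR quantification against a reference gene
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, with each delta-Ct taken
#' as calibrator Ct minus sample Ct, so higher expression than the
#' calibrator gives a ratio above 1.
#'
#' @param E_target,E_ref Amplification efficiencies, `> 1`.
#' @param dCt_target,dCt_ref Delta-Ct (calibrator - sample) for the target
#'   and the reference gene.
#' @return Relative expression ratio.
#' @export
qpcr_relative_ratio <- function(E_target, dCt_target, E_ref, dCt_ref) {
  if (any(c(E_target, E_ref) <= 1))
    stop("efficiencies must exceed 1")
  E_target^dCt_target / E_ref^dCt_ref
}
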
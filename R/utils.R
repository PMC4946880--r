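#' Molecular-weight fold change implied by a diffusion fold change
#'
#' For a globular particle the diffusion coefficient scales inversely with
#' the cube root of molecular weight (Stokes-Einstein with volume
#' proportional to mass), so a fold reduction `r` in the diffusion
#' coefficient implies a `r^3` fold increase in molecular weight.
#'
#' @param dc_fold_change fold reduction in the diffusion coefficient
#'   (e.g. 3 for a three-fold slower protein).
#' @param reference_mw optional reference molecular weight (kDa); when
#'   given, the implied molecular weight is returned as attribute
#'   `implied_mw`.
#' @return the molecular-weight fold change `dc_fold_change^3`.
#' @examples
#' mw_fold_change(3, reference_mw = 27)  # 27-fold, i.e. 729 kDa
#' @export
mw_fold_change <- function(dc_fold_change, reference_mw = NULL) {
  stopifnot(dc_fold_change > 0)
  out <- dc_fold_change^3
  if (!is.null(reference_mw))
    attr(out, "implied_mw") <- out * reference_mw
  out
}

#' @keywords internal
"_PACKAGE"

#' @useDynLib scanfcs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
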
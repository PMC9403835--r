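#' Built-in laminar specifications for the four anterior DLPFC areas
#'
#' Synthetic laminar patterns for areas SFS1, SFS2, MFG1 and MFG2, loosely
#' modelled on their qualitative cytoarchitectonic contrasts: SFS1 with a
#' dense, well-developed layer IV; SFS2 with a thin, blurry layer IV and a
#' prominent, cell-rich layer VI; MFG1 with large deep-III pyramids, a
#' visible but modest layer IV and broad infragranular layers; MFG2 with a
#' broad, dense layer IV and homogeneous packing. These are synthetic
#' stand-ins for testing and demonstration — no quantitative laminar
#' densities of the real areas are published, so no fidelity is claimed.
#'
#' @return named list of four [laminar_spec()]s.
#' @export
#' @examples
#' specs <- dlpfc_area_specs()
#' plot_profile(setNames(make_laminar_profile(specs$SFS1, 101),
#'                       c("depth", "gli")))
dlpfc_area_specs <- function() {
  list(
    SFS1 = laminar_spec(c(0.10, 0.10, 0.30, 0.11, 0.19, 0.20),
                        c(0.08, 0.50, 0.32, 0.55, 0.30, 0.42), name = "SFS1"),
    SFS2 = laminar_spec(c(0.10, 0.10, 0.32, 0.05, 0.21, 0.22),
                        c(0.08, 0.38, 0.30, 0.35, 0.34, 0.50), name = "SFS2"),
    MFG1 = laminar_spec(c(0.10, 0.10, 0.30, 0.08, 0.20, 0.22),
                        c(0.08, 0.40, 0.34, 0.45, 0.36, 0.52), name = "MFG1"),
    MFG2 = laminar_spec(c(0.10, 0.10, 0.28, 0.14, 0.18, 0.20),
                        c(0.08, 0.45, 0.32, 0.58, 0.30, 0.40), name = "MFG2")
  )
}
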
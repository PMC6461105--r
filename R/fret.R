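#' Forster transfer efficiency
#'
#' `E = 1 / (1 + (r/R0)^6)`. When the distance equals the Forster radius
#' the efficiency is exactly 0.5 — the definition of `R0`. Defaults reflect the modelled
#' mean inter-dye distances of the activation-loop reporter and the
#' Alexa488/Alexa568 pair (`R0 = 62` angstrom): 45 angstrom (active loop)
#' gives 87% and 18 angstrom (inactive loop) rounds to 100%.
#'
#' @param r donor-acceptor distance (angstrom); vectorized.
#' @param r0 Forster radius (angstrom).
#' @return Transfer efficiency in (0, 1).
#' @examples
#' round(100 * fret_efficiency(c(45, 18), 62))  # 87, 100
#' @export
fret_efficiency <- function(r, r0 = 62) {
  stopifnot(all(r > 0), r0 > 0)
  1 / (1 + (r / r0)^6)
}

#' Classify a residue-residue distance against the quench band
#'
#' The quenching reporter switches from quenched to fully fluorescent over
#' a short residue-residue distance band (about 16-21 angstrom): below
#' the band the dyes quench, above it they fluoresce, inside it the
#' response is in transition.
#'
#' @param residue_distance residue-residue distance (angstrom); vectorized.
#' @param band length-2 interval (angstrom), lower < upper.
#' @return Factor with levels `quenched`, `transition`, `fluorescent`.
#' @examples
#' quench_classification(c(15, 18, 40))
#' @export
quench_classification <- function(residue_distance, band = c(16, 21)) {
  stopifnot(all(residue_distance > 0), length(band) == 2,
            band[1] < band[2])
  out <- ifelse(residue_distance < band[1], "quenched",
                ifelse(residue_distance > band[2], "fluorescent",
                       "transition"))
  factor(out, levels = c("quenched", "transition", "fluorescent"))
}

#' Reporter geometry of the two-dye conformational assay
#'
#' Bundles the modelled mean inter-dye distances for the two
#' activation-loop conformations, the residue-residue distances, the
#' quench band and the Forster radius used in the expected-FRET
#' calculation, and derives the expected efficiencies and quench classes.
#'
#' @param distance_active,distance_inactive mean inter-dye distances
#'   (angstrom).
#' @param residue_distance_active,residue_distance_inactive
#'   residue-residue distances (angstrom).
#' @param quench_band length-2 interval (angstrom).
#' @param r0 Forster radius (angstrom).
#' @return List with the geometry, `efficiency` (named, active/inactive)
#'   and `quench_class` (named factor).
#' @export
reporter_geometry <- function(distance_active = 45, distance_inactive = 18,
                              residue_distance_active = 40,
                              residue_distance_inactive = 15,
                              quench_band = c(16, 21), r0 = 62) {
  stopifnot(distance_active > 0, distance_inactive > 0,
            residue_distance_active > 0, residue_distance_inactive > 0)
  eff <- fret_efficiency(c(active = distance_active,
                           inactive = distance_inactive), r0)
  qc <- quench_classification(c(active = residue_distance_active,
                                inactive = residue_distance_inactive),
                              quench_band)
  names(qc) <- c("active", "inactive")
  list(distance_active = distance_active,
       distance_inactive = distance_inactive,
       residue_distance_active = residue_distance_active,
       residue_distance_inactive = residue_distance_inactive,
       quench_band = quench_band, r0 = r0,
       efficiency = eff, quench_class = qc)
}
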
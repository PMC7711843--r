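# Biophysical calculators for the reconstituted SNARE/Syt1 fusion system:
# reconstitution copy numbers, partially-zippered SNAREpin bridging spans,
# and the steric-exclusion predicate for intermembrane protein complexes.

#' Protein copies per vesicle from reconstitution concentrations
#'
#' Converts bulk protein and lipid concentrations into the expected number
#' of protein copies per vesicle of a given diameter. Lipids are counted on
#' a single spherical surface of the stated (outer) diameter at a fixed area
#' per lipid; protein copies follow the bulk protein:lipid molar ratio, and
#' the number presented on the outer (cytoplasm-mimicking) face is the
#' configured orientation fraction, rounded to the nearest integer. With the
#' defaults, 140 nM VAMP2 / 50 uM lipid in an 80 nm SUV gives ~43 outward
#' copies, 70 nM Syt1 gives ~22, and 250 nM t-SNARE / 250 uM lipid gives
#' ~15 in an equivalent area of GUV membrane.
#'
#' @param protein_conc protein concentration (molar).
#' @param lipid_conc lipid concentration (molar).
#' @param vesicle_diameter vesicle diameter in nm (default 80, the mean SUV
#'   diameter of the system being modelled).
#' @param area_per_lipid membrane area per lipid in nm^2 (default 0.65,
#'   typical for phospholipids).
#' @param outward_fraction fraction of reconstituted protein facing outward
#'   (default 0.5: random orientation on reconstitution).
#' @return list with `lipids` (lipids counted on the surface), `total`
#'   (protein copies, unrounded) and `outward` (outward-facing copies,
#'   rounded).
#' @examples
#' copy_number(140e-9, 50e-6, 80)$outward   # v-SNAREs per SUV
#' @export
copy_number <- function(protein_conc, lipid_conc, vesicle_diameter = 80,
                        area_per_lipid = 0.65, outward_fraction = 0.5) {
  stopifnot(protein_conc >= 0, lipid_conc > 0, vesicle_diameter > 0,
            area_per_lipid > 0,
            outward_fraction > 0, outward_fraction <= 1)
  lipids <- pi * vesicle_diameter^2 / area_per_lipid
  total <- lipids * (protein_conc / lipid_conc)
  list(lipids = lipids, total = total,
       outward = round(total * outward_fraction))
}

#' Membrane separation bridgeable by a partially zippered SNAREpin
#'
#' The maximal span equals the summed contour length of the unfolded
#' (extended-chain) residues of the v- and t-SNARE plus any rigid folded
#' offset, at 0.365 nm of contour per amino acid. With the ~38 VAMP2 and
#' ~39 t-SNARE residues C-terminal of the zero layer left unfolded this
#' gives 28.1 nm, an upper bound consistent with the longest observed
#' docking separations (~27 nm); entropic compaction of real chains makes
#' the realised span shorter.
#'
#' @param unfolded_residues_v unfolded v-SNARE residues.
#' @param unfolded_residues_t unfolded t-SNARE residues.
#' @param contour_per_residue contour length per residue in nm
#'   (default 0.365).
#' @param folded_offset additional rigid span in nm (default 0).
#' @return span in nm.
#' @examples
#' bridging_span(38, 39)
#' @export
bridging_span <- function(unfolded_residues_v, unfolded_residues_t,
                          contour_per_residue = 0.365, folded_offset = 0) {
  stopifnot(unfolded_residues_v >= 0, unfolded_residues_t >= 0,
            contour_per_residue > 0, folded_offset >= 0)
  (unfolded_residues_v + unfolded_residues_t) * contour_per_residue +
    folded_offset
}

#' Intermembrane protein complex geometries
#'
#' Diameter presets for the complexes expected in the intermembrane space:
#' the SNAREpin-CpxII complex (~3 nm across) and the
#' SNAREpin-CpxII-Syt1-Syt1 complex measured across its flanking Syt1 C2B
#' domains (~8 nm). Presets use the upper end of the structural estimates so
#' that [is_excluded()] reproduces the < 3 nm and < 8 nm exclusion
#' thresholds exactly.
#'
#' @param name preset name, or `"custom"` together with `diameter`.
#' @param diameter complex diameter in nm for `"custom"`.
#' @return list with `name` and `diameter` (nm).
#' @export
snare_complex <- function(name = c("SNAREpin-CpxII",
                                   "SNAREpin-CpxII-Syt1-Syt1", "custom"),
                          diameter = NULL) {
  name <- match.arg(name)
  d <- switch(name,
              "SNAREpin-CpxII" = 3.0,
              "SNAREpin-CpxII-Syt1-Syt1" = 8.0,
              "custom" = diameter)
  if (is.null(d) || !is.finite(d) || d <= 0)
    stop("complex diameter must be a positive number of nm")
  list(name = name, diameter = d)
}

#' Steric exclusion of a complex from the intermembrane space
#'
#' A complex is sterically excluded when the membrane separation is strictly
#' smaller than its diameter (a separation exactly equal to the diameter is
#' not excluded).
#'
#' @param complex a [snare_complex()] or a diameter in nm.
#' @param separation membrane separation(s) in nm (>= 0).
#' @return logical vector.
#' @examples
#' is_excluded(snare_complex("SNAREpin-CpxII-Syt1-Syt1"), 7)  # TRUE
#' @export
is_excluded <- function(complex, separation) {
  d <- if (is.list(complex)) complex$diameter else complex
  stopifnot(is.finite(d), d > 0, all(separation >= 0))
  separation < d
}
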
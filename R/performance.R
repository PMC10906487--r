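#' Annular chase swimming speed
#'
#' Swim speed during an exhaustive chase in a circular raceway: total laps
#' (fractional allowed) times the raceway circumference, divided by the
#' chase duration, optionally standardised to body lengths per second.
#'
#' @param laps Laps swum until exhaustion (>= 0).
#' @param chase_duration_s Chase duration, s (> 0).
#' @param body_length_cm Body length, cm, for BL s^-1 (optional).
#' @param circumference_cm Raceway circumference, cm (default 176, a
#'   55 cm bucket with a 24 cm inner bucket).
#' @return List: `u_chase_cms`, `u_chase_bls` (NA without body length).
#' @examples
#' compute_u_chase(10, 120, body_length_cm = 8.8)
#' @export
compute_u_chase <- function(laps, chase_duration_s, body_length_cm = NULL,
                            circumference_cm = 176) {
  if (chase_duration_s <= 0) stop("chase_duration_s must be positive")
  if (laps < 0) stop("laps must be >= 0")
  cms <- laps * circumference_cm / chase_duration_s
  list(u_chase_cms = cms,
       u_chase_bls = if (is.null(body_length_cm)) NA_real_
                     else cms / body_length_cm)
}

#' Exhaustive exercise effort
#'
#' Body lengths swum until exhaustion: the product of the mean exhaustive
#' chase duration and the mean chase swim speed at a temperature. Defined
#' at the group-mean level because duration and swim speed are measured on
#' different fish (different experiments), so individual effort values do
#' not exist; a per-individual product can be formed with the same
#' function but is non-canonical.
#'
#' @param mean_chase_duration_s Mean chase duration at the temperature, s.
#' @param mean_u_chase_bls Mean chase swim speed at the same temperature,
#'   BL s^-1.
#' @return Effort in body lengths.
#' @examples
#' compute_effort(300, 2)  # 600 BL
#' @export
compute_effort <- function(mean_chase_duration_s, mean_u_chase_bls) {
  if (mean_chase_duration_s < 0 || mean_u_chase_bls < 0)
    stop("effort inputs must be >= 0")
  mean_chase_duration_s * mean_u_chase_bls
}

#' Enzyme assay specification
#'
#' Constants of a kinetic microplate assay: wavelength-specific millimolar
#' extinction coefficient (6.22 (mmol L^-1)^-1 cm^-1 for pyridine
#' dinucleotides at 340 nm, 13.6 for TNB at 412 nm), the optical pathlength
#' of the filled well, the final well volume, and the protein / wet-tissue
#' content per well used for normalisation.
#'
#' @param enzyme One of `"LDH"`, `"CS"`, `"CK"` (or any label).
#' @param extinction_mM Millimolar extinction coefficient,
#'   (mmol L^-1)^-1 cm^-1 (> 0).
#' @param pathlength_cm Optical pathlength, cm (> 0; depends on well
#'   geometry and fill volume, so it is a required input).
#' @param well_volume_ul Final well volume, uL (default 200).
#' @param protein_per_well_mg Protein per well, mg.
#' @param tissue_per_well_mg Wet tissue per well, mg.
#' @return An object of class `enzyme_assay_spec`.
#' @export
enzyme_assay_spec <- function(enzyme, extinction_mM, pathlength_cm,
                              well_volume_ul = 200,
                              protein_per_well_mg = NA_real_,
                              tissue_per_well_mg = NA_real_) {
  if (extinction_mM <= 0) stop("extinction_mM must be positive")
  if (pathlength_cm <= 0) stop("pathlength_cm must be positive")
  if (well_volume_ul <= 0) stop("well_volume_ul must be positive")
  structure(list(enzyme = enzyme, extinction_mM = extinction_mM,
                 pathlength_cm = pathlength_cm,
                 well_volume_ul = well_volume_ul,
                 protein_per_well_mg = protein_per_well_mg,
                 tissue_per_well_mg = tissue_per_well_mg),
            class = "enzyme_assay_spec")
}

#' Enzyme activity from absorbance rates
#'
#' Beer-Lambert conversion of a background-corrected absorbance rate into
#' catalytic activity. The net rate (sample minus substrate-free control)
#' over the extinction coefficient and pathlength gives a concentration
#' rate (mmol L^-1 min^-1); times the well volume it becomes moles of
#' substrate converted per minute, normalised to protein (nmol min^-1
#' mg^-1 protein) and wet tissue mass (umol min^-1 g^-1 ww). Negative net
#' rates are reported as 0 with a flag.
#'
#' @param delta_A_per_min Mean sample absorbance rate (duplicates averaged
#'   upstream), absorbance min^-1.
#' @param control_delta_A Absorbance rate of the substrate-omitted control.
#' @param spec An [enzyme_assay_spec()].
#' @return List: `activity_nmol_min_mg_protein`,
#'   `activity_umol_min_g_ww` (NA when the respective normaliser is NA),
#'   `rate_mM_per_min`, `nmol_per_min_well`, `clamped`.
#' @examples
#' sp <- enzyme_assay_spec("LDH", 6.22, pathlength_cm = 1,
#'                         protein_per_well_mg = 0.1)
#' compute_enzyme_activity(0.0622, 0, sp)  # 20 nmol min^-1 mg^-1 protein
#' @export
compute_enzyme_activity <- function(delta_A_per_min, control_delta_A, spec) {
  stopifnot(inherits(spec, "enzyme_assay_spec"))
  net <- delta_A_per_min - control_delta_A
  clamped <- net < 0
  if (clamped) {
    warning("net absorbance rate below control; activity reported as 0")
    net <- 0
  }
  rate_mM <- net / (spec$extinction_mM * spec$pathlength_cm)  # mmol/L/min
  nmol_per_min <- rate_mM * spec$well_volume_ul               # 1e-3 mmol/L * 1e-6 L = nmol
  list(
    activity_nmol_min_mg_protein =
      if (is.na(spec$protein_per_well_mg)) NA_real_
      else nmol_per_min / spec$protein_per_well_mg,
    activity_umol_min_g_ww =
      if (is.na(spec$tissue_per_well_mg)) NA_real_
      else nmol_per_min / spec$tissue_per_well_mg,
    rate_mM_per_min = rate_mM,
    nmol_per_min_well = nmol_per_min,
    clamped = clamped)
}
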
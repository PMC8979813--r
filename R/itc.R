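# isothermal titration calorimetry: injection-heat series with perfusion-cell
# dilution accounting, blank subtraction, total-heat normalization, and the
# delta-delta-H magnesium-release comparison

#' ITC injection series
#'
#' Per-injection heats with cell/syringe metadata. The first 0.2 ul priming
#' injection is excluded per protocol: pass it with
#' \code{first_injection_discarded = FALSE} and it is dropped (and recorded),
#' or pass data already without it. The molar-ratio axis (cumulative titrant
#' over cell analyte, both dilution-corrected) uses the standard
#' perfusion/overflow model: each injection of volume v displaces cell
#' content, diluting analyte and previously injected titrant by
#' \code{(1 - v/V_cell)}.
#'
#' @param volumes_ul injection volumes, ul.
#' @param heats_uJ per-injection heats, uJ (same length).
#' @param syringe_mM titrant concentration in the syringe, mM.
#' @param cell_mM analyte concentration in the cell, mM monomer units.
#' @param cell_volume_ul working cell volume, ul.
#' @param first_injection_discarded has the 0.2 ul priming injection already
#'   been removed?
#' @param analyte_dilution starting dilution factor of the cell analyte
#'   (carried across syringe refills; 1 for a fresh experiment).
#' @param titrant_nmol_start titrant already in the cell at series start, mmol
#'   (0 for a fresh experiment).
#' @return object of class \code{itc_series} with a computed
#'   \code{molar_ratio} axis (strictly increasing).
#' @export
itc_series <- function(volumes_ul, heats_uJ, syringe_mM, cell_mM,
                       cell_volume_ul, first_injection_discarded = TRUE,
                       analyte_dilution = 1, titrant_nmol_start = 0) {
  if (length(volumes_ul) != length(heats_uJ)) {
    stop_coac("volumes and heats must have the same length")
  }
  check_pos(syringe_mM, "syringe_mM")
  check_pos(cell_mM, "cell_mM")
  check_pos(cell_volume_ul, "cell_volume_ul")
  discarded <- NULL
  if (!first_injection_discarded) {
    discarded <- c(volume_ul = volumes_ul[1], heat_uJ = heats_uJ[1])
    volumes_ul <- volumes_ul[-1]
    heats_uJ <- heats_uJ[-1]
  }
  n <- length(volumes_ul)
  if (n < 1L) stop_coac("empty injection schedule")
  # perfusion model recursion; titrant bookkeeping in nmol (mM * ul)
  dil <- analyte_dilution
  titrant <- titrant_nmol_start            # nmol (mM * ul)
  ratio <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1 - volumes_ul[i] / cell_volume_ul
    dil <- dil * f
    titrant <- titrant * f + syringe_mM * volumes_ul[i]  # mM*ul = nmol
    ratio[i] <- titrant / (cell_mM * dil * cell_volume_ul)
  }
  structure(list(volumes_ul = volumes_ul, heats_uJ = heats_uJ,
                 syringe_mM = syringe_mM, cell_mM = cell_mM,
                 cell_volume_ul = cell_volume_ul, molar_ratio = ratio,
                 analyte_dilution_end = dil, titrant_nmol_end = titrant,
                 discarded_first = discarded),
            class = "itc_series")
}

#' @export
print.itc_series <- function(x, ...) {
  cat(sprintf(
    "<itc_series> %d injection(s), molar ratio %.3g-%.3g, cell %g mM x %g ul\n",
    length(x$heats_uJ), min(x$molar_ratio), max(x$molar_ratio), x$cell_mM,
    x$cell_volume_ul))
  invisible(x)
}

#' Subtract a blank titration
#'
#' Removes the dilution-heat component measured by titrating into pure buffer.
#' Injection schedules must align within tolerance; metadata of the sample is
#' preserved.
#'
#' @param sample,blank \code{itc_series} with matched injection schedules.
#' @param tol volume match tolerance, ul.
#' @return an \code{itc_series} of per-injection heat differences.
#' @export
subtract_blank <- function(sample, blank, tol = 1e-6) {
  stopifnot(inherits(sample, "itc_series"), inherits(blank, "itc_series"))
  if (length(sample$volumes_ul) != length(blank$volumes_ul)) {
    stop_coac("injection counts differ (%d vs %d)",
              length(sample$volumes_ul), length(blank$volumes_ul))
  }
  mism <- which(abs(sample$volumes_ul - blank$volumes_ul) > tol)
  if (length(mism)) {
    stop_coac("injection schedules diverge first at injection %d", mism[1])
  }
  out <- sample
  out$heats_uJ <- sample$heats_uJ - blank$heats_uJ
  out
}

#' Total heat of a titration
#'
#' Sum of the (blank-subtracted) injection heats normalized by the moles of
#' analyte monomer in the cell:
#' \code{sum(q_uJ) / (cell_mM * cell_volume_ul)} which is directly kJ/mol.
#'
#' @param series an \code{itc_series}, blank-subtracted.
#' @return total enthalpy, kJ per mol of cell analyte monomer.
#' @export
total_heat <- function(series) {
  stopifnot(inherits(series, "itc_series"))
  nmol <- series$cell_mM * series$cell_volume_ul   # nmol
  if (nmol == 0) stop_coac("zero analyte in the cell")
  # uJ / nmol = kJ/mol
  sum(series$heats_uJ) / nmol
}

#' Stitch syringe-refill parts into one series
#'
#' When a titration is continued by refilling the syringe without changing
#' the cell content, the parts are concatenated with cumulative titrant and
#' analyte-dilution accounting carried across the seam, so the molar-ratio
#' axis keeps increasing.
#'
#' @param parts list of \code{itc_series} sharing cell metadata, in
#'   chronological order (each with its priming injection already discarded).
#' @return a single \code{itc_series}.
#' @export
stitch_refills <- function(parts) {
  if (length(parts) == 1L) return(parts[[1]])
  ref <- parts[[1]]
  for (p in parts[-1]) {
    if (abs(p$cell_mM - ref$cell_mM) > 1e-9 ||
        abs(p$cell_volume_ul - ref$cell_volume_ul) > 1e-9 ||
        abs(p$syringe_mM - ref$syringe_mM) > 1e-9) {
      stop_coac("inconsistent cell/syringe metadata across parts")
    }
  }
  out <- itc_series(
    volumes_ul = unlist(lapply(parts, `[[`, "volumes_ul")),
    heats_uJ = unlist(lapply(parts, `[[`, "heats_uJ")),
    syringe_mM = ref$syringe_mM, cell_mM = ref$cell_mM,
    cell_volume_ul = ref$cell_volume_ul)
  if (is.unsorted(out$molar_ratio, strictly = TRUE)) {
    stop_coac("molar ratio not strictly increasing: parts out of order?")
  }
  out
}

#' Magnesium-release enthalpy comparison
#'
#' \code{ddH = dH_pep_minus_mg - dH_pep_plus_mg}: the enthalpic difference
#' between peptide binding to bare RNA and to Mg-preincubated RNA. Under the
#' competitive-replacement model, ddH equals dH_mg (the heat of Mg binding to
#' the RNA) when the peptide releases all of the magnesium; the release
#' fraction is \code{ddH / dH_mg}.
#'
#' @param dH_pep_minus_mg,dH_pep_plus_mg,dH_mg total heats, kJ/mol monomer,
#'   all on the same per-mol basis.
#' @param se optional named numeric of standard errors
#'   (pep_minus, pep_plus, mg) for first-order uncertainty propagation.
#' @return list(ddH, release_fraction, se_ddH, se_release_fraction).
#' @export
delta_delta_H <- function(dH_pep_minus_mg, dH_pep_plus_mg, dH_mg, se = NULL) {
  if (dH_mg == 0) stop_coac("dH_mg = 0: release fraction undefined")
  ddH <- dH_pep_minus_mg - dH_pep_plus_mg
  frac <- ddH / dH_mg
  se_ddH <- se_frac <- NA_real_
  if (!is.null(se)) {
    se_ddH <- sqrt(se[["pep_minus"]]^2 + se[["pep_plus"]]^2)
    se_frac <- abs(frac) * sqrt((se_ddH / ddH)^2 + (se[["mg"]] / dH_mg)^2)
    if (ddH == 0) se_frac <- se_ddH / abs(dH_mg)
  }
  list(ddH = ddH, release_fraction = frac, se_ddH = se_ddH,
       se_release_fraction = se_frac)
}
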
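# Spectroscopy helpers: circular-dichroism mean-residue-ellipticity
# conversion and paramagnetic (Gd-DTPA) titration normalisation.

#' A circular dichroism spectrum
#'
#' @param wavelength wavelengths (nm).
#' @param signal CD signal in millidegrees.
#' @param concentration peptide concentration (mol/L, > 0).
#' @param path_length cell path length (cm, > 0).
#' @param n_residues number of residues (> 0).
#' @return object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength, signal, concentration, path_length,
                        n_residues) {
  if (length(wavelength) != length(signal))
    stop("wavelength and signal must have equal length")
  if (concentration <= 0 || path_length <= 0 || n_residues <= 0)
    stop("concentration, path length and residue count must be positive")
  structure(list(wavelength = wavelength, signal = signal,
                 concentration = concentration, path_length = path_length,
                 n_residues = n_residues), class = "cd_spectrum")
}

#' Mean residue ellipticity
#'
#' MRE = CD_mdeg / (c x 10 x L x N_r), in deg cm^2 dmol^-1 per residue,
#' with c in mol/L and L in cm.
#'
#' @param s a [cd_spectrum()].
#' @return data frame with `wavelength` and `mre`.
#' @export
mre_convert <- function(s) {
  if (!inherits(s, "cd_spectrum")) stop("`s` must be a cd_spectrum")
  denom <- s$concentration * 10 * s$path_length * s$n_residues
  if (denom == 0) stop("zero denominator in MRE conversion")
  data.frame(wavelength = s$wavelength, mre = s$signal / denom)
}

#' A paramagnetic-titration series for one residue
#'
#' @param residue residue label.
#' @param gd_conc titrant (Gd3+) concentrations (mM); the first point must
#'   be the Gd-free reference (0).
#' @param peak_volume integrated resonance volumes (> 0).
#' @param added_volume cumulative titrant volume added at each point (same
#'   units as `initial_volume`; 0 at the reference point).
#' @param initial_volume initial sample volume (> 0).
#' @return object of class `pre_titration`.
#' @export
pre_titration <- function(residue, gd_conc, peak_volume, added_volume,
                          initial_volume) {
  n <- length(gd_conc)
  if (length(peak_volume) != n || length(added_volume) != n)
    stop("titration columns must have equal length")
  if (gd_conc[1] != 0 || added_volume[1] != 0)
    stop("first point must be the Gd-free reference")
  if (any(peak_volume <= 0) || initial_volume <= 0)
    stop("volumes must be positive")
  structure(list(residue = residue, gd_conc = gd_conc,
                 peak_volume = peak_volume, added_volume = added_volume,
                 initial_volume = initial_volume), class = "pre_titration")
}

#' Dilution-corrected, normalised titration intensities
#'
#' Each integrated volume is multiplied by its cumulative dilution factor
#' (V0 + V_added) / V0 and divided by the (corrected) Gd-free reference,
#' so the reference point is exactly 1.
#'
#' @param t a [pre_titration()].
#' @return numeric vector of normalised intensities.
#' @export
pre_normalize <- function(t) {
  if (!inherits(t, "pre_titration")) stop("`t` must be a pre_titration")
  dil <- (t$initial_volume + t$added_volume) / t$initial_volume
  corrected <- t$peak_volume * dil
  corrected / corrected[1]
}

#' Read a CD spectrum from CSV
#'
#' Expects columns `wavelength` (nm) and `signal` (mdeg).
#'
#' @param path CSV file.
#' @inheritParams cd_spectrum
#' @return a [cd_spectrum()].
#' @export
read_cd <- function(path, concentration, path_length, n_residues) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength", "signal") %in% names(d)))
    stop("CD file needs `wavelength` and `signal` columns")
  cd_spectrum(d$wavelength, d$signal, concentration, path_length,
              n_residues)
}

#' Read a PRE titration table from CSV
#'
#' Expects columns `gd_conc` (mM), `peak_volume`, `added_volume`, one row
#' per titration point, first row the Gd-free reference.
#'
#' @param path CSV file.
#' @param residue residue label.
#' @param initial_volume initial sample volume.
#' @return a [pre_titration()].
#' @export
read_pre <- function(path, residue, initial_volume) {
  d <- utils::read.csv(path)
  need <- c("gd_conc", "peak_volume", "added_volume")
  if (!all(need %in% names(d)))
    stop("titration file needs columns: ", paste(need, collapse = ", "))
  pre_titration(residue, d$gd_conc, d$peak_volume, d$added_volume,
                initial_volume)
}
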
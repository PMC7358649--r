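#' @useDynLib memreflect, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd quantile optim setNames
#' @importFrom utils read.table write.table modifyList packageVersion
NULL

.pkg <- new.env(parent = emptyenv())

.extdata <- function(file) {
  system.file("extdata", file, package = "memreflect", mustWork = TRUE)
}

#' Coherent neutron scattering lengths
#'
#' Returns the bundled table of bound coherent scattering lengths, in
#' Angstrom (1 fm = 1e-5 A).  Note the sign difference between hydrogen
#' (b = -3.741e-5 A) and deuterium (b = +6.667e-5 A) that makes isotopic
#' contrast variation work.
#'
#' @return Named numeric vector, isotope symbol -> b (A).
#' @export
scattering_table <- function() {
  if (is.null(.pkg$scattering)) {
    tab <- read.table(.extdata("scattering_lengths.tsv"), header = TRUE,
                      stringsAsFactors = FALSE)
    .pkg$scattering <- setNames(tab$b, tab$isotope)
  }
  .pkg$scattering
}

residue_table <- function() {
  if (is.null(.pkg$residues)) {
    tab <- read.table(.extdata("residues.tsv"), header = TRUE,
                      stringsAsFactors = FALSE)
    rownames(tab) <- tab$aa
    .pkg$residues <- tab
  }
  .pkg$residues
}

#' Atomic composition with a molecular volume
#'
#' @param counts named non-negative numeric vector of isotope counts,
#'   e.g. `c(D = 2, O = 1)` for heavy water.
#' @param volume molecular volume in cubic Angstrom, > 0.
#' @return An object of class `composition`.
#' @export
composition <- function(counts, volume) {
  counts <- counts[counts != 0]
  if (length(counts) && (is.null(names(counts)) || any(names(counts) == "")))
    stop("composition counts must be named by isotope symbol")
  if (any(counts < 0)) stop("isotope counts must be non-negative")
  if (!is.numeric(volume) || length(volume) != 1 || !is.finite(volume) ||
      volume <= 0)
    stop("molecular volume must be a single positive number")
  structure(list(counts = counts, volume = volume), class = "composition")
}

#' Scattering length density of a composition
#'
#' SLD = sum(n_i * b_i) / V_m, in inverse square Angstrom.
#'
#' @param comp a [composition()].
#' @param table named vector of scattering lengths (A); defaults to the
#'   bundled [scattering_table()].
#' @return SLD in A^-2.
#' @export
compute_sld <- function(comp, table = scattering_table()) {
  if (!inherits(comp, "composition")) stop("`comp` must be a composition")
  counts <- comp$counts
  if (!length(counts)) return(0)
  unknown <- setdiff(names(counts), names(table))
  if (length(unknown))
    stop("unknown isotope symbol(s): ", paste(unknown, collapse = ", "))
  sum(counts * table[names(counts)]) / comp$volume
}

#' Volume-fraction mixing of scattering length densities
#'
#' The SLD of a mixed layer is the volume-fraction weighted sum of its
#' component SLDs.
#'
#' @param sld numeric vector of component SLDs (A^-2).
#' @param phi numeric vector of volume fractions in `[0, 1]`.
#' @param tol warn if `sum(phi)` deviates from 1 by more than this.
#' @return mixed SLD (A^-2).
#' @export
mix_sld <- function(sld, phi, tol = 0.01) {
  if (length(sld) != length(phi)) stop("sld and phi must have equal length")
  if (any(phi < 0)) stop("volume fractions must be non-negative")
  if (any(phi > 1 + 1e-9)) stop("volume fractions must not exceed 1")
  s <- sum(phi)
  if (s > 1 + tol) stop("volume fractions sum to ", signif(s, 4), " > 1")
  if (abs(s - 1) > tol)
    warning("volume fractions sum to ", signif(s, 4), ", not 1")
  sum(sld * phi)
}

# ---- labelled peptides -----------------------------------------------------

#' A peptide with an explicit deuteration scheme
#'
#' Captures everything needed to compute segment SLDs of a (partially)
#' deuterated peptide: per-residue atomic composition, which residues carry
#' methyl deuterons (non-exchangeable), and how many hydrogens are labile
#' (backbone amides plus exchangeable side-chain and terminal hydrogens).
#' Labile hydrogens are assumed to equilibrate fully with the solvent.
#'
#' Neutral side-chain protonation states are used throughout; the N-terminus
#' contributes one extra (labile) amine hydrogen and an amidated C-terminus
#' contributes NH2 (two labile hydrogens) in place of the acid OH.
#'
#' @param sequence one-letter amino-acid sequence.
#' @param d_positions integer positions of methyl-deuterated residues.
#' @param c_amide logical; is the C-terminus amidated?
#' @param volume total molecular volume (A^3); defaults to the sum of
#'   tabulated residue volumes.
#' @return An object of class `labeled_peptide`.
#' @export
labeled_peptide <- function(sequence, d_positions = integer(),
                            c_amide = FALSE, volume = NULL) {
  res <- residue_table()
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!length(aa)) stop("empty sequence")
  bad <- setdiff(aa, rownames(res))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  n <- length(aa)
  d_positions <- as.integer(d_positions)
  if (length(d_positions) &&
      (any(d_positions < 1) || any(d_positions > n)))
    stop("deuterated positions must lie within the sequence")
  per <- res[aa, c("C", "H", "N", "O", "S", "labile", "methyl", "volume")]
  deut <- integer(n)
  deut[d_positions] <- per$methyl[d_positions]
  if (any(deut[d_positions] == 0))
    warning("some deuterated positions carry no methyl hydrogens")
  structure(list(sequence = aa, d_positions = sort(unique(d_positions)),
                 per_residue = per, deuterons = deut, c_amide = c_amide,
                 volume = if (is.null(volume)) sum(per$volume) else volume),
            class = "labeled_peptide")
}

#' The maculatin 1.1 peptide, optionally half-deuterated
#'
#' Maculatin 1.1 (GLFGVLAKVAAHVVPAIAEHF-NH2) from Australian tree-frog skin
#' secretions.  The `"d6_nterm"` scheme deuterates the methyl groups of the
#' six methyl-bearing residues in the N-terminal half (L2, V5, L6, A7, V9,
#' A10), giving the two halves of the peptide distinguishable SLDs.
#'
#' @param scheme `"none"` for the hydrogenous peptide or `"d6_nterm"` for
#'   the half-labelled variant.
#' @return A [labeled_peptide()].
#' @export
maculatin1 <- function(scheme = c("d6_nterm", "none")) {
  scheme <- match.arg(scheme)
  pos <- if (scheme == "d6_nterm") c(2L, 5L, 6L, 7L, 9L, 10L) else integer()
  labeled_peptide("GLFGVLAKVAAHVVPAIAEHF", d_positions = pos, c_amide = TRUE)
}

segment_indices <- function(n, segment = c("whole", "n_half", "c_half")) {
  segment <- match.arg(segment)
  half <- floor(n / 2)  # 21-mer: residues 1-10 vs 11-21
  switch(segment,
         whole  = seq_len(n),
         n_half = seq_len(half),
         c_half = seq.int(half + 1, n))
}

#' Segment SLD of a labelled peptide
#'
#' Computes the scattering length density of the whole peptide or of its
#' N- or C-terminal half (a 21-mer splits 1-10 / 11-21, midpoint residue in
#' the C-half).  Labile hydrogens scatter with
#' b = (1 - f) b_H + f b_D where `f` is the solvent deuterium fraction;
#' methyl deuterons of labelled residues always use b_D.  The segment uses
#' its tabulated-volume share of the total molecular volume.
#'
#' @param peptide a [labeled_peptide()].
#' @param solvent_d_fraction deuterium fraction of the solvent, in `[0, 1]`.
#' @param segment `"whole"`, `"n_half"` or `"c_half"`.
#' @param table scattering-length table.
#' @return SLD in A^-2.
#' @export
peptide_sld <- function(peptide, solvent_d_fraction = 0,
                        segment = c("whole", "n_half", "c_half"),
                        table = scattering_table()) {
  if (!inherits(peptide, "labeled_peptide"))
    stop("`peptide` must be a labeled_peptide")
  f <- solvent_d_fraction
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f > 1)
    stop("solvent_d_fraction must be a single number in [0, 1]")
  n <- length(peptide$sequence)
  idx <- segment_indices(n, segment)
  if (!length(idx)) stop("empty peptide segment")
  per <- peptide$per_residue[idx, ]
  atoms <- colSums(per[, c("C", "H", "N", "O", "S")])
  labile <- sum(per$labile)
  deut <- sum(peptide$deuterons[idx])
  # terminal corrections, assigned to whichever segment holds the terminus
  if (1L %in% idx) {            # free amine: one extra labile H
    atoms["H"] <- atoms["H"] + 1; labile <- labile + 1
  }
  if (n %in% idx) {
    if (peptide$c_amide) {      # C(=O)NH2: two labile H, one extra N
      atoms["H"] <- atoms["H"] + 2; atoms["N"] <- atoms["N"] + 1
      labile <- labile + 2
    } else {                    # COOH: one labile H, one extra O
      atoms["H"] <- atoms["H"] + 1; atoms["O"] <- atoms["O"] + 1
      labile <- labile + 1
    }
  }
  n_h <- atoms["H"] - deut      # hydrogens left after methyl deuteration
  if (n_h < labile) stop("deuteration scheme conflicts with labile count")
  b_h_eff <- (1 - f) * table[["H"]] + f * table[["D"]]
  b <- sum(atoms[c("C", "N", "O", "S")] * table[c("C", "N", "O", "S")]) +
    deut * table[["D"]] + labile * b_h_eff + (n_h - labile) * table[["H"]]
  vol <- peptide$volume * sum(per$volume) / sum(peptide$per_residue$volume)
  unname(b / vol)
}

# ---- materials -------------------------------------------------------------

#' A membrane-building material
#'
#' Either a fixed SLD, or an atomic composition (with molecular volume and a
#' count of labile hydrogens) whose SLD then depends on the solvent
#' deuterium fraction through H/D exchange.
#'
#' @param name label used in reports.
#' @param sld fixed SLD (A^-2), mutually exclusive with `comp`.
#' @param comp a [composition()].
#' @param labile number of exchangeable hydrogens (counted within `comp`).
#' @return An object of class `nr_material`.
#' @export
material <- function(name, sld = NULL, comp = NULL, labile = 0) {
  if (is.null(sld) == is.null(comp))
    stop("give exactly one of `sld` or `comp`")
  if (!is.null(comp) && !inherits(comp, "composition"))
    stop("`comp` must be a composition")
  structure(list(name = name, sld = sld, comp = comp, labile = labile),
            class = "nr_material")
}

#' SLD of a material in a solvent of given deuterium fraction
#'
#' @param mat an [material()].
#' @param d_fraction solvent deuterium fraction in `[0, 1]`.
#' @param table scattering-length table.
#' @return SLD in A^-2.
#' @export
material_sld <- function(mat, d_fraction = 0, table = scattering_table()) {
  if (!inherits(mat, "nr_material")) stop("`mat` must be an nr_material")
  if (!is.null(mat$sld)) return(mat$sld)
  base <- compute_sld(mat$comp, table)
  # swap `labile` hydrogens for the solvent H/D mix
  base + mat$labile * d_fraction * (table[["D"]] - table[["H"]]) /
    mat$comp$volume
}

#' Default material set for DMPC/DMPG (3:1) bilayers on silicon
#'
#' Literature-typical compositions and molecular volumes (headgroups:
#' phosphocholine C10H18NO8P, 319 A^3; phosphoglycerol C8H12O10P, 289 A^3,
#' two exchangeable glycerol hydroxyls; di-myristoyl tails C26H54 or C26D54,
#' 782 A^3).  All entries are overridable via the run configuration.
#'
#' @param pg_fraction mole fraction of PG in the headgroup mix.
#' @return Named list of [material()] objects plus solvent definitions.
#' @export
default_materials <- function(pg_fraction = 0.25) {
  x <- pg_fraction
  head_counts <- c(C = 10 * (1 - x) + 8 * x, H = 18 * (1 - x) + 12 * x,
                   N = 1 - x, O = 8 * (1 - x) + 10 * x, P = 1)
  head_vol <- 319 * (1 - x) + 289 * x
  list(
    si        = material("silicon", sld = 2.07e-6),
    sio2      = material("silicon oxide", sld = 3.47e-6),
    heads     = material("PC/PG heads",
                         comp = composition(head_counts, head_vol),
                         labile = 2 * x),
    tails_h   = material("h-myristoyl tails",
                         comp = composition(c(C = 26, H = 54), 782)),
    tails_d54 = material("d54-myristoyl tails",
                         comp = composition(c(C = 26, D = 54), 782)),
    d2o       = material("D2O", comp = composition(c(D = 2, O = 1), 30.0)),
    h2o       = material("H2O", comp = composition(c(H = 2, O = 1), 30.0))
  )
}

#' A solvent contrast
#'
#' @param name contrast label (e.g. `"d2o"`).
#' @param solvent_sld bulk solvent SLD (A^-2).
#' @param d_fraction solvent deuterium fraction, drives labile-H exchange.
#' @return An object of class `nr_contrast`.
#' @export
contrast <- function(name, solvent_sld, d_fraction) {
  if (d_fraction < 0 || d_fraction > 1)
    stop("d_fraction must be in [0, 1]")
  structure(list(name = name, solvent_sld = solvent_sld,
                 d_fraction = d_fraction), class = "nr_contrast")
}

#' The standard two-contrast (D2O / H2O) set
#'
#' @param materials material set providing `d2o` and `h2o` entries.
#' @return Named list of [contrast()] objects.
#' @export
default_contrasts <- function(materials = default_materials()) {
  list(
    d2o = contrast("d2o", material_sld(materials$d2o), 1.0),
    h2o = contrast("h2o", material_sld(materials$h2o), 0.0)
  )
}
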
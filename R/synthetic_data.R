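# Ground-truth generator: two-contrast reflectivity of peptide-free and
# peptide-bound DMPC/DMPG (3:1) bilayers at two temperatures, with
# heteroscedastic counting-like noise.  Every fixture carries the model
# that generated it, so recovery tests compare against exact truth.

#' Default instrument-like Q grid
#'
#' Log-spaced, matching a constant relative resolution instrument.
#'
#' @param n number of points.
#' @param qmin,qmax grid limits (A^-1).
#' @return numeric vector.
#' @export
default_q_grid <- function(n = 120, qmin = 0.012, qmax = 0.30) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

#' Noise model for simulated reflectivity
#'
#' One-sigma uncertainty sigma = max(amplitude * R, floor): fractional
#' counting noise with a background-limited floor at high Q.
#'
#' @param amplitude fractional noise level.
#' @param floor absolute noise floor in reflectivity units.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(amplitude = 0.05, floor = 1e-8) {
  if (amplitude < 0 || floor < 0) stop("noise parameters must be >= 0")
  structure(list(amplitude = amplitude, floor = floor),
            class = "noise_spec")
}

#' Simulate one reflectivity curve from a membrane model
#'
#' Evaluates the resolution-smeared model on the Q grid and adds Gaussian
#' noise of width `max(amplitude * R, floor)`; the same width is reported
#' in the dR column.  Deterministic for a given seed.
#'
#' @param model a [membrane_model()] (the ground truth).
#' @param contrast_name which of the model's contrasts to simulate.
#' @param Q momentum-transfer grid.
#' @param noise a [noise_spec()].
#' @param seed integer random seed.
#' @return a [reflectivity_curve()] with dR and dQ (FWHM) columns.
#' @export
generate_curve <- function(model, contrast_name, Q = default_q_grid(),
                           noise = noise_spec(), seed) {
  if (missing(seed)) stop("`seed` is required")
  template <- reflectivity_curve(Q, rep(0, length(Q)),
                                 dQ = model$resolution * Q,
                                 contrast = contrast_name)
  r_true <- model_curve(model, template)
  sig <- pmax(noise$amplitude * r_true, noise$floor)
  r_obs <- if (noise$amplitude == 0) r_true else
    with_seed(seed, pmax(r_true + rnorm(length(Q), 0, sig), 0))
  reflectivity_curve(Q, r_obs,
                     dR = if (all(sig > 0)) sig else NULL,
                     dQ = model$resolution * Q, contrast = contrast_name)
}

#' Ground-truth membrane model for one study condition
#'
#' Builds the generating model for one sample: tail labelling (`"d54"` or
#' `"h"`), peptide-free (three-layer) or peptide-bound (four-layer), fluid
#' (30C) or gel (15C).  Gel-phase truths have thicker tails, hence smaller
#' areas per lipid, than fluid-phase truths.  Peptide-bound truths are
#' generated under a stated scenario: `"uneven"` (whole peptide, unequal
#' leaflet fractions) or `"n_in"` / `"n_out"` (membrane-spanning with the
#' N-terminal half in the inner / outer leaflet, one shared fraction).
#'
#' @param lipid `"d54"` or `"h"` tail labelling.
#' @param bound is the peptide bound?
#' @param temperature `"30C"` (fluid) or `"15C"` (gel).
#' @param scenario generating scenario for bound samples.
#' @param contrasts,materials see [membrane_model()].
#' @return a [membrane_model()] carrying the truth parameter values.
#' @export
study_truth <- function(lipid = c("d54", "h"), bound = FALSE,
                        temperature = c("30C", "15C"),
                        scenario = c("n_in", "n_out", "uneven"),
                        contrasts = default_contrasts(),
                        materials = default_materials()) {
  lipid <- match.arg(lipid)
  temperature <- match.arg(temperature)
  scenario <- match.arg(scenario)
  tails <- if (lipid == "d54") "tails_d54" else "tails_h"
  oxide <- if (lipid == "d54") c(d = 8.3, r = 3.2) else c(d = 10.7, r = 2.6)
  common <- c(oxide_d = unname(oxide["d"]), oxide_phi = 0,
              rough_oxide = unname(oxide["r"]), rough_bilayer = 3,
              heads_d = 9, heads_phi = 0.35, heads_pep = 0)
  if (!bound) {
    m <- membrane_model("three_layer", contrasts, materials, tails)
    vals <- c(common,
              tails_d = if (temperature == "30C") 30 else 36,
              tails_phi = 0.05, tails_pep = 0)
  } else {
    mode <- if (scenario == "uneven") "whole" else scenario
    m <- membrane_model("four_layer", contrasts, materials, tails,
                        peptide = maculatin1(), peptide_mode = mode)
    half <- if (temperature == "30C") 15.5 else 18
    pep <- if (scenario == "uneven")
      c(tails_in_pep = 0.17, tails_out_pep = 0.21)
    else c(tails_in_pep = 0.18, tails_out_pep = 0.18)
    vals <- c(common, tails_in_d = half, tails_out_d = half,
              tails_in_phi = 0.08, tails_out_phi = 0.08, pep)
  }
  model_set_params(m, vals)
}

#' Generate the full 16-curve study fixture
#'
#' 2 tail labellings x 2 sample states (peptide-free / peptide-bound) x
#' 2 temperatures x 2 solvent contrasts, each sample carrying its
#' generating model.
#'
#' @param seed integer random seed.
#' @param scenario generating scenario for the peptide-bound samples.
#' @param Q momentum-transfer grid.
#' @param noise a [noise_spec()].
#' @param dir optional directory: curves are written as 4-column ASCII and
#'   truths as YAML.
#' @return named list of samples, each with `model`, `curves` (one per
#'   contrast), and `meta`.
#' @export
generate_study_fixture <- function(seed, scenario = "n_in",
                                   Q = default_q_grid(),
                                   noise = noise_spec(), dir = NULL) {
  if (missing(seed)) stop("`seed` is required")
  grid <- expand.grid(lipid = c("d54", "h"), bound = c(FALSE, TRUE),
                      temperature = c("30C", "15C"),
                      stringsAsFactors = FALSE)
  out <- list()
  idx <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    truth <- study_truth(g$lipid, g$bound, g$temperature,
                         scenario = scenario)
    curves <- list()
    for (cn in names(truth$contrasts)) {
      idx <- idx + 1L
      curves[[cn]] <- generate_curve(truth, cn, Q, noise,
                                     seed = seed + idx)
    }
    id <- sprintf("%s_%s_%s", g$lipid,
                  if (g$bound) "bound" else "free", g$temperature)
    out[[id]] <- list(model = truth, curves = curves,
                      meta = list(id = id, lipid = g$lipid,
                                  bound = g$bound,
                                  temperature = g$temperature,
                                  scenario = if (g$bound) scenario
                                             else "none",
                                  seed = seed, noise = unclass(noise)))
  }
  if (!is.null(dir)) write_fixture(out, dir)
  invisible(out)
}

write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(fixture)) {
    s <- fixture[[id]]
    for (cn in names(s$curves))
      write_reflectivity(s$curves[[cn]],
                         file.path(dir, sprintf("%s_%s.dat", id, cn)))
    truth <- s$meta
    truth$parameters <- as.list(setNames(s$model$params$value,
                                         s$model$params$name))
    truth$template <- s$model$template
    yaml::write_yaml(truth, file.path(dir, sprintf("%s_truth.yml", id)))
  }
  invisible(dir)
}
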
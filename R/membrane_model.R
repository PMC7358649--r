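# Parameterised solid-supported bilayer models.  The measurement is made
# through the silicon block, so the fronting medium is silicon and the
# backing medium is the bulk solvent; "inner" layers are those nearest the
# oxide surface.  Structural parameters (thicknesses, roughnesses, volume
# fractions) are shared across solvent contrasts; only solvent SLDs and
# labile-H exchange differ between contrasts.

#' Model-fitting generics
#'
#' Any model that implements these three generics can be refined with
#' [co_refine()] and [monte_carlo_errors()]: `model_params()` returns the
#' parameter table (name, value, min, max, vary, tie), `model_set_params()`
#' returns a copy with the named values replaced, and `model_curve()`
#' evaluates the (resolution-smeared) model prediction on a curve's grid.
#'
#' @param model a model object.
#' @param values named numeric vector of parameter values to set.
#' @param curve a [reflectivity_curve()] (or analogous data object).
#' @name model-generics
NULL

#' @rdname model-generics
#' @export
model_params <- function(model) UseMethod("model_params")

#' @rdname model-generics
#' @export
model_set_params <- function(model, values) UseMethod("model_set_params")

#' @rdname model-generics
#' @export
model_curve <- function(model, curve) UseMethod("model_curve")

default_param_table <- function(template) {
  p <- function(name, value, min, max)
    data.frame(name = name, value = value, min = min, max = max,
               vary = FALSE, tie = NA_character_, stringsAsFactors = FALSE)
  common <- rbind(
    p("oxide_d",       10,  3, 25),
    p("oxide_phi",      0,  0, 0.5),
    p("heads_d",        9,  5, 16),
    p("heads_phi",    0.3,  0, 0.8),
    p("heads_pep",      0,  0, 0.5),
    p("rough_oxide",    3,  1, 8),
    p("rough_bilayer",  3,  1, 8))
  tails <- if (template == "three_layer") rbind(
    p("tails_d",     26, 16, 44),
    p("tails_phi", 0.05,  0, 0.6),
    p("tails_pep",    0,  0, 0.5))
  else rbind(
    p("tails_in_d",   13,  8, 24),
    p("tails_out_d",  13,  8, 24),
    p("tails_in_phi", 0.05, 0, 0.6),
    p("tails_out_phi", 0.05, 0, 0.6),
    p("tails_in_pep",  0,  0, 0.5),
    p("tails_out_pep", 0,  0, 0.5))
  out <- rbind(common, tails)
  rownames(out) <- out$name
  out
}

#' Build a solid-supported bilayer model
#'
#' `three_layer` splits the bilayer into inner heads | tails | outer heads;
#' `four_layer` further splits the tails into inner and outer sub-layers
#' whose SLDs may differ (the configuration that reveals leaflet asymmetry
#' with a half-deuterated peptide).  The expanded stack per contrast is
#' silicon | oxide | inner heads | tails (1 or 2) | outer heads | solvent.
#'
#' @param template `"three_layer"` or `"four_layer"`.
#' @param contrasts named list of [contrast()] objects.
#' @param materials material set, see [default_materials()].
#' @param tails which tail material to use: `"tails_h"` or `"tails_d54"`.
#' @param peptide optional [labeled_peptide()] occupying the layers'
#'   `*_pep` volume fractions.
#' @param peptide_mode `"whole"` uses the whole-peptide SLD in every layer
#'   ("uneven distribution" bookkeeping); `"n_in"` / `"n_out"` place the
#'   N-terminal-half SLD in the inner / outer tail sub-layer respectively
#'   (membrane-spanning, oriented peptide).
#' @param resolution constant relative dQ/Q FWHM used when a curve carries
#'   no per-point dQ column.
#' @return object of class `membrane_model`.
#' @export
membrane_model <- function(template = c("three_layer", "four_layer"),
                           contrasts = default_contrasts(),
                           materials = default_materials(),
                           tails = c("tails_h", "tails_d54"),
                           peptide = NULL,
                           peptide_mode = c("whole", "n_in", "n_out"),
                           resolution = 0.084) {
  template <- match.arg(template)
  peptide_mode <- match.arg(peptide_mode)
  if (is.character(tails)) tails <- materials[[match.arg(tails)]]
  if (peptide_mode != "whole" && template != "four_layer")
    stop("oriented peptide modes need the four_layer template")
  if (peptide_mode != "whole" && is.null(peptide))
    stop("oriented peptide modes need a peptide")
  m <- structure(list(template = template, contrasts = contrasts,
                      materials = materials, tails = tails,
                      peptide = peptide, peptide_mode = peptide_mode,
                      resolution = resolution,
                      params = default_param_table(template)),
                 class = "membrane_model")
  m$cache <- precompute_slds(m)
  m
}

# contrast-dependent dry SLDs, fixed for the life of the model
precompute_slds <- function(m) {
  lapply(m$contrasts, function(ct) {
    f <- ct$d_fraction
    pep <- if (!is.null(m$peptide)) {
      list(whole  = peptide_sld(m$peptide, f, "whole"),
           n_half = peptide_sld(m$peptide, f, "n_half"),
           c_half = peptide_sld(m$peptide, f, "c_half"))
    }
    list(solvent = ct$solvent_sld,
         si = material_sld(m$materials$si, f),
         sio2 = material_sld(m$materials$sio2, f),
         heads = material_sld(m$materials$heads, f),
         tails = material_sld(m$tails, f),
         pep = pep)
  })
}

#' @export
model_params.membrane_model <- function(model) model$params

#' @export
model_set_params.membrane_model <- function(model, values) {
  if (length(values)) {
    nm <- names(values)
    bad <- setdiff(nm, model$params$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    model$params[nm, "value"] <- as.numeric(values)
  }
  tied <- which(!is.na(model$params$tie))
  if (length(tied))
    model$params$value[tied] <- model$params[model$params$tie[tied], "value"]
  model
}

#' Choose which parameters a refinement varies
#'
#' @param model a model implementing [model_params()].
#' @param names parameter names to vary.
#' @param lower,upper optional named bound overrides.
#' @param only if `TRUE` (default) all other parameters are frozen.
#' @return updated model.
#' @export
set_vary <- function(model, names, lower = NULL, upper = NULL, only = TRUE) {
  p <- model$params
  bad <- setdiff(names, p$name)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (only) p$vary <- FALSE
  p[names, "vary"] <- TRUE
  for (nm in names(lower)) p[nm, "min"] <- lower[[nm]]
  for (nm in names(upper)) p[nm, "max"] <- upper[[nm]]
  if (any(p$min > p$max)) stop("lower bound exceeds upper bound")
  model$params <- p
  model
}

# mixed layer SLD with explicit fraction bookkeeping
layer_mix <- function(dry, pep_sld, solv, phi_pep, phi_solv, tol = 1e-6) {
  if (phi_pep < 0 || phi_solv < 0 || phi_pep + phi_solv > 1 + tol)
    stop("layer volume fractions violate sum(phi) = 1")
  phi_lip <- max(0, 1 - phi_pep - phi_solv)
  dry * phi_lip + (if (phi_pep > 0) pep_sld * phi_pep else 0) +
    solv * phi_solv
}

# fast expansion to thickness/SLD/roughness vectors (fitting hot path)
expand_vectors <- function(model, contrast_name) {
  cs <- model$cache[[contrast_name]]
  if (is.null(cs)) stop("unknown contrast: ", contrast_name)
  v <- model$params$value
  names(v) <- model$params$name
  solv <- cs$solvent
  pep <- cs$pep
  pw <- if (!is.null(pep)) pep$whole else NA_real_
  heads <- layer_mix(cs$heads, pw, solv, v[["heads_pep"]], v[["heads_phi"]])
  oxide <- cs$sio2 * (1 - v[["oxide_phi"]]) + solv * v[["oxide_phi"]]
  rb <- v[["rough_bilayer"]]
  if (model$template == "three_layer") {
    tails <- layer_mix(cs$tails, pw, solv, v[["tails_pep"]], v[["tails_phi"]])
    d <- c(0, v[["oxide_d"]], v[["heads_d"]], v[["tails_d"]],
           v[["heads_d"]], 0)
    s <- c(cs$si, oxide, heads, tails, heads, solv)
    r <- c(0, v[["rough_oxide"]], rb, rb, rb, rb)
    nm <- c("si", "oxide", "heads_in", "tails", "heads_out", "solvent")
  } else {
    p_in <- switch(model$peptide_mode, whole = pw, n_in = pep$n_half,
                   n_out = pep$c_half)
    p_out <- switch(model$peptide_mode, whole = pw, n_in = pep$c_half,
                    n_out = pep$n_half)
    t_in <- layer_mix(cs$tails, p_in, solv, v[["tails_in_pep"]],
                      v[["tails_in_phi"]])
    t_out <- layer_mix(cs$tails, p_out, solv, v[["tails_out_pep"]],
                       v[["tails_out_phi"]])
    d <- c(0, v[["oxide_d"]], v[["heads_d"]], v[["tails_in_d"]],
           v[["tails_out_d"]], v[["heads_d"]], 0)
    s <- c(cs$si, oxide, heads, t_in, t_out, heads, solv)
    r <- c(0, v[["rough_oxide"]], rb, rb, rb, rb, rb)
    nm <- c("si", "oxide", "heads_in", "tails_in", "tails_out",
            "heads_out", "solvent")
  }
  list(thickness = d, sld = s, rough = r, name = nm)
}

#' Expand a membrane model into a slab stack for one contrast
#'
#' @param model a [membrane_model()].
#' @param contrast_name name of one of the model's contrasts.
#' @return a [slab_stack()] from semi-infinite silicon to semi-infinite
#'   solvent.
#' @export
expand_model <- function(model, contrast_name) {
  ev <- expand_vectors(model, contrast_name)
  slab_stack(ev$thickness, ev$sld, ev$rough, ev$name)
}

#' Per-contrast SLD of selected layers
#'
#' Convenience accessor used by the decomposition layer: the expanded,
#' solvent-mixed SLD of each requested layer in every contrast.
#'
#' @param model a [membrane_model()].
#' @param layers layer names as in [expand_model()] output.
#' @return matrix, layers x contrasts.
#' @export
layer_slds <- function(model, layers = c("tails_in", "tails_out")) {
  out <- sapply(names(model$contrasts), function(cn) {
    ev <- expand_vectors(model, cn)
    idx <- match(layers, ev$name)
    if (anyNA(idx)) stop("unknown layer name")
    ev$sld[idx]
  })
  matrix(out, nrow = length(layers),
         dimnames = list(layers, names(model$contrasts)))
}

#' @export
model_curve.membrane_model <- function(model, curve) {
  cn <- attr(curve, "contrast")
  ev <- expand_vectors(model, cn)
  res <- if (!is.null(curve$dQ)) curve$dQ else model$resolution
  smear(function(q) abeles_c(q, ev$thickness, ev$sld, ev$rough),
        curve$Q, res)
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("<membrane_model> %s, %d contrasts (%s)%s\n", x$template,
              length(x$contrasts), paste(names(x$contrasts), collapse = ", "),
              if (is.null(x$peptide)) "" else
                sprintf(", peptide mode %s", x$peptide_mode)))
  print(x$params[, c("value", "min", "max", "vary")])
  invisible(x)
}
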
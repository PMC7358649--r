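# Interpretation layer: area per lipid and phase state, contrast-variation
# decomposition of fitted layer SLDs into lipid/peptide/solvent volume
# fractions, and orientation inference from a half-deuterated peptide.

#' Area per lipid from the fitted tail layer
#'
#' A_lipid = V_m / (tau * phi_lipid), where tau is the thickness of the
#' lipid tail region occupied by one lipid (one leaflet) and phi_lipid the
#' lipid volume fraction of that layer.
#'
#' @param V_m molecular volume of the tails of one lipid (A^3).
#' @param tau tail-layer thickness (A, > 0).
#' @param phi_lipid lipid volume fraction in (0, 1].
#' @return area per lipid in A^2.
#' @export
area_per_lipid <- function(V_m, tau, phi_lipid) {
  if (any(V_m <= 0)) stop("V_m must be positive")
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(phi_lipid <= 0) || any(phi_lipid > 1))
    stop("phi_lipid must be in (0, 1]")
  V_m / (tau * phi_lipid)
}

#' Assign the bilayer phase from the area per lipid
#'
#' Fluid (liquid-crystalline, L-alpha) bilayers pack at larger areas than
#' gel (L-beta) bilayers.  The default 47 A^2 threshold sits midway
#' between typical fluid (>= ~49 A^2) and gel (<= ~45.4 A^2) di-C14 PC/PG
#' values; an area exactly at the threshold is classified
#' liquid-crystalline.
#'
#' @param A_lipid area per lipid (A^2, > 0).
#' @param threshold decision boundary (A^2).
#' @return `"liquid_crystalline"` or `"gel"`.
#' @export
assign_phase <- function(A_lipid, threshold = 47) {
  if (any(A_lipid <= 0)) stop("A_lipid must be positive")
  ifelse(A_lipid >= threshold, "liquid_crystalline", "gel")
}

#' Ideal alpha-helix length
#'
#' @param n_residues number of residues (>= 0).
#' @param rise_per_residue helical rise per residue (A); canonical
#'   alpha-helix value 1.5 A.
#' @return helix length in nm.
#' @export
helix_length <- function(n_residues, rise_per_residue = 1.5) {
  if (any(n_residues < 0)) stop("n_residues must be non-negative")
  n_residues * rise_per_residue / 10
}

#' Decompose a layer's per-contrast SLD into component volume fractions
#'
#' Solves SLD_layer(c) = phi_lipid SLD_lipid(c) + phi_peptide
#' SLD_peptide(c) + phi_solvent SLD_solvent(c), with the fractions summing
#' to 1, by least squares over all contrasts (exactly determined with two
#' contrasts, over-determined with more).  Fractions are clipped to
#' `[0, 1]` and clipping is flagged.
#'
#' @param layer_slds named numeric vector: measured layer SLD per contrast.
#' @param sld_lipid,sld_peptide,sld_solvent component SLDs per contrast
#'   (same names/order as `layer_slds`).
#' @return list: `phi_peptide`, `phi_solvent`, `phi_lipid`, `residual`
#'   (rms misfit in A^-2), `clipped`, `condition` (condition number of the
#'   design).
#' @export
peptide_volume_fraction <- function(layer_slds, sld_lipid, sld_peptide,
                                    sld_solvent) {
  nc <- length(layer_slds)
  if (nc < 2) stop("need at least 2 contrasts to decompose")
  if (length(sld_lipid) != nc || length(sld_peptide) != nc ||
      length(sld_solvent) != nc)
    stop("component SLDs must cover every contrast")
  # substitute phi_lipid = 1 - phi_pep - phi_solv
  A <- cbind(pep = sld_peptide - sld_lipid, solv = sld_solvent - sld_lipid)
  y <- layer_slds - sld_lipid
  cond <- kappa(A, exact = TRUE)
  if (!is.finite(cond) || cond > 1e10) {
    nm <- names(layer_slds)
    stop("degenerate contrast pair: components indistinguishable",
         if (!is.null(nm)) paste0(" (", paste(nm, collapse = ", "), ")"))
  }
  x <- qr.solve(A, y)
  raw <- c(pep = unname(x[1]), solv = unname(x[2]))
  phi <- pmin(pmax(raw, 0), 1)
  phi_lip <- min(max(1 - sum(phi), 0), 1)
  clipped <- any(abs(phi - raw) > 1e-12) ||
    abs(phi_lip - (1 - sum(raw))) > 1e-12
  resid <- y - A %*% c(phi[1], phi[2])
  list(phi_peptide = unname(phi[1]), phi_solvent = unname(phi[2]),
       phi_lipid = phi_lip,
       residual = sqrt(mean(resid^2)), clipped = clipped,
       condition = cond)
}

# shared-fraction ("oriented, membrane-spanning") least squares: one
# phi_peptide across both leaflets, leaflet-specific solvent fractions
oriented_solve <- function(sld_in, sld_out, pep_in, pep_out,
                           sld_lipid, sld_solvent) {
  y <- c(sld_in - sld_lipid, sld_out - sld_lipid)
  nc <- length(sld_lipid)
  A <- rbind(
    cbind(pep = pep_in - sld_lipid, s_in = sld_solvent - sld_lipid,
          s_out = 0),
    cbind(pep = pep_out - sld_lipid, s_in = 0,
          s_out = sld_solvent - sld_lipid))
  x <- qr.solve(A, y)
  raw <- x
  phi <- pmin(pmax(x, 0), 1)
  resid <- y - A %*% phi
  list(phi_peptide = unname(phi[1]), phi_solvent_in = unname(phi[2]),
       phi_solvent_out = unname(phi[3]),
       clipped = any(abs(phi - raw) > 1e-12),
       residual = sqrt(mean(resid^2)))
}

#' Compare interpretation scenarios for leaflet SLD asymmetry
#'
#' With a peptide whose N- and C-terminal halves have different SLDs,
#' leaflet SLD asymmetry admits two readings: an *uneven distribution* of
#' whole peptides between the leaflets (scenario `uneven`: independent
#' per-leaflet fractions), or a *membrane-spanning, oriented* peptide
#' (scenarios `n_in` / `n_out`: one shared peptide fraction, with the
#' N-terminal-half SLD in the inner or outer leaflet).  Each scenario is
#' solved by least squares over both leaflets and all contrasts and ranked
#' by residual.
#'
#' With only two contrasts the uneven scenario has as many unknowns as
#' equations and fits any leaflet SLD pair exactly, so selection prefers
#' the more parsimonious oriented scenarios whenever their residual is
#' within `tol` of the minimum; `tol` defaults to the propagated leaflet
#' SLD uncertainty when supplied.  When the two oriented residuals differ
#' by less than `tol` the orientations are flagged indistinguishable.
#'
#' @param sld_inner,sld_outer measured leaflet SLDs per contrast (named
#'   numeric, one entry per contrast).
#' @param peptide a [labeled_peptide()] with asymmetric labelling.
#' @param sld_lipid lipid (tail) SLD per contrast.
#' @param sld_solvent solvent SLD per contrast.
#' @param d_fraction solvent deuterium fraction per contrast (drives the
#'   peptide's labile-H exchange).
#' @param sld_inner_err,sld_outer_err optional 1-sigma uncertainties.
#' @param tol residual tolerance (A^-2) for scenario selection; default
#'   from the uncertainties if given, else 0.
#' @return list of class `orientation_scenarios`: per-scenario fractions
#'   and residuals, `best` (smallest residual), `selected` (parsimony
#'   rule), `indistinguishable`.
#' @export
orientation_scenarios <- function(sld_inner, sld_outer, peptide,
                                  sld_lipid, sld_solvent, d_fraction,
                                  sld_inner_err = NULL,
                                  sld_outer_err = NULL, tol = NULL) {
  nc <- length(sld_inner)
  if (length(sld_outer) != nc || length(sld_lipid) != nc ||
      length(sld_solvent) != nc || length(d_fraction) != nc)
    stop("all per-contrast inputs must have the same length")
  pep_n <- vapply(d_fraction, function(f) peptide_sld(peptide, f, "n_half"), 0)
  pep_c <- vapply(d_fraction, function(f) peptide_sld(peptide, f, "c_half"), 0)
  pep_w <- vapply(d_fraction, function(f) peptide_sld(peptide, f, "whole"), 0)
  n <- length(peptide$sequence)
  n_idx <- segment_indices(n, "n_half")
  d_n <- sum(peptide$deuterons[n_idx])
  d_c <- sum(peptide$deuterons) - d_n
  if (d_n == d_c)
    stop("peptide labelling is symmetric between the halves; ",
         "orientations are indistinguishable by construction")
  if (is.null(tol)) {
    tol <- if (!is.null(sld_inner_err) || !is.null(sld_outer_err))
      sqrt(mean(c(sld_inner_err, sld_outer_err)^2)) else 0
  }
  uneven_in <- peptide_volume_fraction(sld_inner, sld_lipid, pep_w,
                                       sld_solvent)
  uneven_out <- peptide_volume_fraction(sld_outer, sld_lipid, pep_w,
                                        sld_solvent)
  uneven <- list(inner = uneven_in, outer = uneven_out,
                 residual = sqrt((uneven_in$residual^2 +
                                  uneven_out$residual^2) / 2))
  n_in <- oriented_solve(sld_inner, sld_outer, pep_n, pep_c,
                         sld_lipid, sld_solvent)
  n_out <- oriented_solve(sld_inner, sld_outer, pep_c, pep_n,
                          sld_lipid, sld_solvent)
  res <- c(n_in = n_in$residual, n_out = n_out$residual,
           uneven = uneven$residual)
  best <- names(res)[which.min(res)]
  # parsimony: oriented scenarios (3 unknowns) are preferred over the
  # uneven scenario (4 unknowns) when not meaningfully worse
  oriented_best <- if (n_in$residual <= n_out$residual) "n_in" else "n_out"
  selected <- if (res[[oriented_best]] <= min(res) + tol)
    oriented_best else "uneven"
  structure(list(uneven = uneven, n_in = n_in, n_out = n_out,
                 residuals = res, best = best, selected = selected,
                 tol = tol,
                 indistinguishable = abs(n_in$residual - n_out$residual)
                   <= tol),
            class = "orientation_scenarios")
}

#' @export
print.orientation_scenarios <- function(x, ...) {
  cat("<orientation_scenarios>\n")
  cat(sprintf("  uneven : phi_pep in/out = %.3f / %.3f, residual %.3g\n",
              x$uneven$inner$phi_peptide, x$uneven$outer$phi_peptide,
              x$uneven$residual))
  cat(sprintf("  N-in   : phi_pep = %.3f, residual %.3g\n",
              x$n_in$phi_peptide, x$n_in$residual))
  cat(sprintf("  N-out  : phi_pep = %.3f, residual %.3g\n",
              x$n_out$phi_peptide, x$n_out$residual))
  cat(sprintf("  selected: %s%s\n", x$selected,
              if (isTRUE(x$indistinguishable))
                " (orientations indistinguishable within tolerance)" else ""))
  invisible(x)
}

#' Linearized parameter covariance of a fit
#'
#' Gauss-Newton covariance (J^T J)^-1 from the dR-weighted residual
#' Jacobian at the best fit; the cheap alternative to
#' [monte_carlo_errors()] when only error propagation (not full
#' distributions) is needed.
#'
#' @param fit an `nr_fit` with varied parameters.
#' @param rel step size for the central-difference Jacobian.
#' @return covariance matrix of the varied parameters.
#' @export
linearized_param_cov <- function(fit, rel = 1e-4) {
  vp <- fit$params[fit$params$vary & is.na(fit$params$tie), ]
  resid_vec <- function(vals) {
    m <- model_set_params(fit$model, setNames(vals, vp$name))
    unlist(lapply(fit$curves, function(cv)
      (model_curve(m, cv) - cv$R) / cv$dR))
  }
  x0 <- fit$best[vp$name]
  J <- sapply(seq_along(x0), function(j) {
    h <- rel * max(abs(x0[j]), 1e-3)
    xp <- x0; xp[j] <- x0[j] + h
    xm <- x0; xm[j] <- x0[j] - h
    (resid_vec(xp) - resid_vec(xm)) / (2 * h)
  })
  cov <- tryCatch(solve(crossprod(J)), error = function(e) {
    warning("singular Jacobian; covariance regularised")
    solve(crossprod(J) + diag(1e-10, ncol(J)))
  })
  dimnames(cov) <- list(vp$name, vp$name)
  cov
}

# 1-sigma uncertainties of the tail-leaflet SLDs, from MC draws when
# available, else linear propagation of the Gauss-Newton covariance
leaflet_sld_errors <- function(fit) {
  model <- fit$model
  if (!is.null(fit$draws)) {
    sl_draws <- apply(fit$draws, 1, function(row) {
      m <- model_set_params(model, row)
      as.numeric(layer_slds(m, c("tails_in", "tails_out")))
    })
    return(matrix(apply(sl_draws, 1, sd), nrow = 2))
  }
  cov <- linearized_param_cov(fit)
  vp <- rownames(cov)
  x0 <- fit$best[vp]
  sl_fun <- function(vals)
    as.numeric(layer_slds(model_set_params(model, setNames(vals, vp)),
                          c("tails_in", "tails_out")))
  G <- sapply(seq_along(x0), function(j) {
    h <- 1e-4 * max(abs(x0[j]), 1e-3)
    xp <- x0; xp[j] <- x0[j] + h
    xm <- x0; xm[j] <- x0[j] - h
    (sl_fun(xp) - sl_fun(xm)) / (2 * h)
  })
  matrix(sqrt(pmax(diag(G %*% cov %*% t(G)), 0)), nrow = 2)
}

#' Full decomposition report for a fitted four-layer model
#'
#' Extracts the fitted tail sub-layer SLDs per contrast, decomposes both
#' leaflets, computes areas per lipid and phase labels, and runs the
#' orientation-scenario comparison.
#'
#' @param fit an `nr_fit` of a four-layer [membrane_model()] with a
#'   peptide.
#' @param V_m tail molecular volume per lipid (A^3).
#' @param phase_threshold see [assign_phase()].
#' @param tol passed to [orientation_scenarios()].
#' @return list of class `decomposition_result`.
#' @export
decompose_fit <- function(fit, V_m = 782, phase_threshold = 47, tol = NULL) {
  model <- fit$model
  if (model$template != "four_layer")
    stop("decomposition needs a four-layer fit")
  if (is.null(model$peptide)) stop("model has no peptide")
  sl <- layer_slds(model, c("tails_in", "tails_out"))
  cs <- model$cache
  lip <- vapply(cs, function(z) z$tails, 0)
  solv <- vapply(cs, function(z) z$solvent, 0)
  f <- vapply(model$contrasts, function(ct) ct$d_fraction, 0)
  errs <- leaflet_sld_errors(fit)
  sc <- orientation_scenarios(sl["tails_in", ], sl["tails_out", ],
                              model$peptide, lip, solv, f,
                              sld_inner_err = errs[1, ],
                              sld_outer_err = errs[2, ],
                              tol = tol)
  v <- model$params$value
  names(v) <- model$params$name
  leaflets <- data.frame(
    leaflet = c("inner", "outer"),
    tau = c(v[["tails_in_d"]], v[["tails_out_d"]]),
    phi_lipid = c(sc$uneven$inner$phi_lipid, sc$uneven$outer$phi_lipid),
    phi_peptide = c(sc$uneven$inner$phi_peptide,
                    sc$uneven$outer$phi_peptide),
    phi_solvent = c(sc$uneven$inner$phi_solvent,
                    sc$uneven$outer$phi_solvent))
  leaflets$area_per_lipid <- area_per_lipid(V_m, leaflets$tau,
                                            pmax(leaflets$phi_lipid, 1e-6))
  leaflets$phase <- assign_phase(leaflets$area_per_lipid, phase_threshold)
  structure(list(leaflets = leaflets, scenarios = sc,
                 phase_threshold = phase_threshold),
            class = "decomposition_result")
}
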
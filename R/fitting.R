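# Simultaneous multi-contrast refinement: bounded differential-evolution
# global search followed by an L-BFGS-B least-squares polish, plus
# Monte-Carlo resampling of the data for parameter uncertainties.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Weighted least-squares objective over all contrasts
#'
#' chi^2 = sum over curves and points of ((R_model - R) / dR)^2, with the
#' model smeared to each curve's resolution.
#'
#' @param model a model implementing [model_curve()].
#' @param curves list of [reflectivity_curve()]s, each with a `dR` column.
#' @param log_space if `TRUE`, residuals are formed on log10(R) with
#'   propagated uncertainties (fit-space option; default linear R).
#' @return total chi-squared (>= 0).
#' @export
chi2_objective <- function(model, curves, log_space = FALSE) {
  sum(vapply(curves, function(cv) chi2_one(model, cv, log_space), 0))
}

chi2_one <- function(model, cv, log_space = FALSE) {
  if (is.null(cv$dR))
    stop("curve has no dR column; supply synthetic errors, e.g. via ",
         "read_reflectivity(..., synth_error = 0.05)")
  pred <- model_curve(model, cv)
  if (log_space) {
    keep <- cv$R > 0 & pred > 0
    r <- (log10(pred[keep]) - log10(cv$R[keep])) /
      (cv$dR[keep] / (cv$R[keep] * log(10)))
  } else {
    r <- (pred - cv$R) / cv$dR
  }
  sum(r * r)
}

#' Refinement settings
#'
#' Differential-evolution hyper-parameters (DE/rand/1/bin) and polish
#' control.  Population defaults to 15 x n_varied; iteration stops when the
#' population cost spread falls below `tol` relative to the best cost.
#'
#' @param pop_factor population size per varied parameter.
#' @param max_gen maximum DE generations.
#' @param F,CR DE mutation weight and crossover probability.
#' @param tol relative convergence tolerance on the population costs.
#' @param polish run an L-BFGS-B polish from the DE best?
#' @param log_space fit in log10(R) space instead of linear R.
#' @return list of class `refine_control`.
#' @export
refine_control <- function(pop_factor = 15, max_gen = 200, F = 0.7,
                           CR = 0.9, tol = 1e-8, polish = TRUE,
                           log_space = FALSE) {
  structure(list(pop_factor = pop_factor, max_gen = max_gen, F = F,
                 CR = CR, tol = tol, polish = polish,
                 log_space = log_space), class = "refine_control")
}

varied_params <- function(model) {
  p <- model_params(model)
  p <- p[p$vary & is.na(p$tie), , drop = FALSE]
  p
}

make_cost <- function(model, curves, names, log_space) {
  function(x) {
    # infeasible combinations (e.g. layer fractions summing past 1) get a
    # large finite penalty so bounded searches can move off them
    val <- tryCatch({
      m <- model_set_params(model, setNames(x, names))
      chi2_objective(m, curves, log_space)
    }, error = function(e) 1e30)
    if (!is.finite(val)) 1e30 else val
  }
}

de_minimize <- function(cost, lower, upper, control) {
  np <- length(lower)
  pop_n <- max(control$pop_factor * np, 15)
  pop <- matrix(runif(pop_n * np, lower, upper), nrow = pop_n, byrow = TRUE)
  costs <- apply(pop, 1, cost)
  for (gen in seq_len(control$max_gen)) {
    for (i in seq_len(pop_n)) {
      r <- sample(seq_len(pop_n)[-i], 3)
      trial <- pop[r[1], ] + control$F * (pop[r[2], ] - pop[r[3], ])
      cross <- runif(np) < control$CR
      cross[sample.int(np, 1)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      tc <- cost(trial)
      if (tc <= costs[i]) {
        pop[i, ] <- trial
        costs[i] <- tc
      }
    }
    if (max(costs) - min(costs) <= control$tol * (abs(min(costs)) + 1e-12))
      break
  }
  best <- which.min(costs)
  list(par = pop[best, ], value = costs[best], generations = gen)
}

polish_fit <- function(cost, start, lower, upper, maxit = 200) {
  res <- tryCatch(
    optim(start, cost, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = maxit, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(res) || res$value > cost(start))
    list(par = start, value = cost(start))
  else {
    par <- pmin(pmax(res$par, lower), upper)
    if (any(par != res$par))
      warning("polish stepped outside bounds; clipped")
    list(par = par, value = res$value)
  }
}

#' Co-refine a model against multi-contrast reflectivity data
#'
#' Bounded global search (differential evolution) over all varied
#' parameters, minimising the summed chi-squared across every contrast
#' simultaneously, followed by a local least-squares polish.  The result is
#' deterministic for a given seed.
#'
#' @param model a model implementing the [model-generics].
#' @param curves list of [reflectivity_curve()]s with `dR`.
#' @param seed integer random seed (mandatory; no hidden global state).
#' @param control a [refine_control()].
#' @return object of class `nr_fit`: refined model, parameter table,
#'   per-curve and total chi-squared, model curves.
#' @export
co_refine <- function(model, curves, seed, control = refine_control()) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(inherits(control, "refine_control"))
  vp <- varied_params(model)
  if (nrow(vp) == 0)   # nothing to search: evaluate chi2 only
    return(finish_fit(model, curves, seed, control,
                      setNames(numeric(0), character(0))))
  if (any(!is.finite(vp$min)) || any(!is.finite(vp$max)))
    stop("varied parameters need finite bounds")
  cost <- make_cost(model, curves, vp$name, control$log_space)
  res <- with_seed(seed, {
    de <- de_minimize(cost, vp$min, vp$max, control)
    if (control$polish) polish_fit(cost, de$par, vp$min, vp$max) else de
  })
  best <- setNames(res$par, vp$name)
  model <- model_set_params(model, best)
  finish_fit(model, curves, seed, control, best)
}

finish_fit <- function(model, curves, seed, control, best) {
  per <- vapply(curves, function(cv) chi2_one(model, cv, control$log_space), 0)
  names(per) <- vapply(curves, function(cv)
    as.character(attr(cv, "contrast")), "")
  structure(list(model = model, params = model_params(model),
                 best = best, chi2 = sum(per), chi2_per_curve = per,
                 curves = curves, seed = seed, control = control,
                 predicted = lapply(curves, function(cv)
                   model_curve(model, cv)),
                 draws = NULL, ci = NULL),
            class = "nr_fit")
}

#' Monte-Carlo resampling uncertainties
#'
#' Perturbs every data point by a Gaussian of width dR, refits from the
#' best-fit starting point (local polish only by default, full global
#' search behind `refit = "global"`), and collects the distribution of
#' fitted values; the reported uncertainty is the 95% confidence interval
#' (2.5th-97.5th percentiles) of that distribution.
#'
#' @param fit an [co_refine()] result.
#' @param n number of resampled refits (>= 2); 1008 by default.
#' @param seed integer random seed (mandatory).
#' @param refit `"polish"` or `"global"`.
#' @return the fit with `draws` (n x n_params matrix) and `ci`
#'   (data frame: parameter, lower, upper) filled in.
#' @export
monte_carlo_errors <- function(fit, n = 1008, seed,
                               refit = c("polish", "global")) {
  if (missing(seed)) stop("`seed` is required")
  refit <- match.arg(refit)
  if (n < 2) stop("need at least 2 resampling replicates")
  stopifnot(inherits(fit, "nr_fit"))
  vp <- varied_params(fit$model)
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, n, nrow(vp))
    for (i in seq_len(n)) {
      pert <- lapply(fit$curves, function(cv) {
        cv$R <- pmax(cv$R + rnorm(nrow(cv), 0, cv$dR), 0)
        cv
      })
      cost <- make_cost(fit$model, pert, vp$name, fit$control$log_space)
      out[i, ] <- if (refit == "polish")
        polish_fit(cost, fit$best[vp$name], vp$min, vp$max, maxit = 100)$par
      else
        de_minimize(cost, vp$min, vp$max, fit$control)$par
    }
    out
  })
  colnames(draws) <- vp$name
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  fit$draws <- draws
  fit$ci <- data.frame(parameter = vp$name, value = fit$best[vp$name],
                       lower = qs[1, ], upper = qs[2, ],
                       row.names = NULL)
  fit
}

#' @export
print.nr_fit <- function(x, ...) {
  cat(sprintf("<nr_fit> chi2 = %.4g over %d curves (seed %d)\n",
              x$chi2, length(x$curves), x$seed))
  p <- x$params[x$params$vary, c("name", "value", "min", "max")]
  if (!is.null(x$ci)) p <- merge(p, x$ci[, c("parameter", "lower", "upper")],
                                 by.x = "name", by.y = "parameter",
                                 all.x = TRUE, sort = FALSE)
  print(p, row.names = FALSE)
  invisible(x)
}

#' Write a structured fit report
#'
#' JSON report with parameters, bounds, confidence intervals, per-contrast
#' chi-squared, seeds and package version, for provenance.
#'
#' @param fit an `nr_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(
    package = "memreflect",
    version = as.character(packageVersion("memreflect")),
    seed = fit$seed,
    chi2_total = fit$chi2,
    chi2_per_curve = as.list(fit$chi2_per_curve),
    parameters = fit$params[, c("name", "value", "min", "max", "vary")],
    ci = fit$ci)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
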
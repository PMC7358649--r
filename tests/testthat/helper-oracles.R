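# Independent oracles and small fixtures used across the suite.

# Parratt recursive reflectivity with Nevot-Croce roughness: an
# implementation independent of the transfer-matrix kernel.
parratt_reflectivity <- function(stack, Q) {
  vapply(Q, function(q) {
    k <- sqrt(as.complex((q / 2)^2 - 4 * pi * (stack$sld - stack$sld[1])))
    n <- nrow(stack)
    r <- 0 + 0i
    for (j in (n - 1):1) {
      rj <- (k[j] - k[j + 1]) / (k[j] + k[j + 1]) *
        exp(-2 * k[j] * k[j + 1] * stack$rough[j + 1]^2)
      phase <- if (j + 1 < n) exp(2i * k[j + 1] * stack$thickness[j + 1])
               else 0 + 0i
      r <- (rj + r * phase) / (1 + rj * r * phase)
    }
    min(Mod(r)^2, 1)
  }, 0)
}

random_stack <- function(n_layers) {
  slab_stack(
    thickness = c(0, runif(n_layers, 5, 150), 0),
    sld = c(runif(1, -0.5e-6, 4e-6), runif(n_layers, -2e-6, 8e-6),
            runif(1, -0.56e-6, 6.4e-6)),
    rough = c(0, runif(n_layers + 1, 0, 6)))
}

# hand atom-count SLD for a 2-residue peptide, the brute-force route:
# every atom summed explicitly, no shared code with peptide_sld()
hand_peptide_sld <- function(f, table = scattering_table()) {
  # "GA" free acid, no deuteration: G(C2 H3 N O) + A(C3 H5 N O)
  # + N-terminal H + C-terminal OH
  b <- 5 * table[["C"]] + 2 * table[["N"]] + 3 * table[["O"]]
  labile <- 1 + 1 + 1 + 1   # two backbone NH, amine H, acid OH
  nonlabile <- (3 + 5 + 1 + 1) - labile
  b <- b + nonlabile * table[["H"]] +
    labile * ((1 - f) * table[["H"]] + f * table[["D"]])
  unname(b / (60.1 + 88.6))
}

# linear toy model y = a * x through the generic fitting interface
toy_model <- function(a = 1, lower = -100, upper = 100) {
  p <- data.frame(name = "a", value = a, min = lower, max = upper,
                  vary = TRUE, tie = NA_character_,
                  stringsAsFactors = FALSE)
  rownames(p) <- "a"
  structure(list(params = p), class = "toy_model")
}
model_params.toy_model <- function(model) model$params
model_set_params.toy_model <- function(model, values) {
  if (length(values)) model$params[names(values), "value"] <-
      as.numeric(values)
  model
}
model_curve.toy_model <- function(model, curve) {
  model$params["a", "value"] * curve$Q
}
registerS3method("model_params", "toy_model", model_params.toy_model,
                 envir = asNamespace("memreflect"))
registerS3method("model_set_params", "toy_model",
                 model_set_params.toy_model,
                 envir = asNamespace("memreflect"))
registerS3method("model_curve", "toy_model", model_curve.toy_model,
                 envir = asNamespace("memreflect"))

toy_data <- function(a, x, sigma, seed) {
  y <- memreflect:::with_seed(seed, a * x + rnorm(length(x), 0, sigma))
  structure(data.frame(Q = x, R = y, dR = sigma),
            contrast = "toy")
}

# shared analyst-side fit of one synthetic sample: oxide parameters are
# taken as characterised on the bare wafer (the truth values), bilayer
# parameters are searched
fit_sample <- function(sample, seed,
                       control = refine_control(pop_factor = 8,
                                                max_gen = 100)) {
  truth <- sample$model
  tails <- if (sample$meta$lipid == "d54") "tails_d54" else "tails_h"
  fixed <- truth$params$value
  names(fixed) <- truth$params$name
  if (truth$template == "three_layer") {
    m <- membrane_model("three_layer", tails = tails)
    m <- model_set_params(m, fixed[c("oxide_d", "rough_oxide",
                                     "rough_bilayer", "heads_d")])
    m <- set_vary(m, c("tails_d", "tails_phi", "heads_phi", "heads_d"))
  } else {
    m <- membrane_model("four_layer", tails = tails,
                        peptide = maculatin1(), peptide_mode = "whole")
    m <- model_set_params(m, fixed[c("oxide_d", "rough_oxide",
                                     "rough_bilayer", "heads_d",
                                     "heads_phi")])
    m <- set_vary(m, c("tails_in_d", "tails_out_d", "tails_in_phi",
                       "tails_out_phi", "tails_in_pep", "tails_out_pep"))
  }
  co_refine(m, unname(sample$curves), seed = seed, control = control)
}
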
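make_toy <- function(a = 2, n = 40, sigma = 0.05, seed = 1) {
  x <- seq(0.1, 2, length.out = n)
  list(model = toy_model(a = 1, lower = 0, upper = 10),
       data = toy_data(a, x, sigma, seed), x = x, a = a, sigma = sigma)
}

test_that("chi-squared is the dR-weighted sum of squares", {
  m <- study_truth("h", FALSE, "30C")
  cv <- generate_curve(m, "d2o", noise = noise_spec(0, 1e-4), seed = 1)
  # model generated the data: exact zero
  expect_equal(chi2_objective(m, list(cv)), 0)
  # one point moved by +1 dR raises chi2 by exactly 1
  cv1 <- cv
  cv1$R[10] <- cv1$R[10] + cv1$dR[10]
  expect_equal(chi2_objective(m, list(cv1)), 1)
  # additivity across contrasts
  cv2 <- generate_curve(m, "h2o", seed = 2)
  expect_equal(chi2_objective(m, list(cv1, cv2)),
               chi2_objective(m, list(cv1)) + chi2_objective(m, list(cv2)))
  # missing dR is an instructive error
  cv3 <- cv[, c("Q", "R")]
  attr(cv3, "contrast") <- "d2o"
  expect_error(chi2_objective(m, list(cv3)), "dR")
})

test_that("co_refine with all parameters fixed only evaluates chi-squared", {
  m <- study_truth("h", FALSE, "30C")   # nothing varies
  cv <- generate_curve(m, "d2o", seed = 3)
  fit <- co_refine(m, list(cv), seed = 1)
  expect_s3_class(fit, "nr_fit")
  expect_length(fit$best, 0)
  expect_equal(fit$chi2, chi2_objective(m, list(cv)))
})

test_that("co_refine recovers a one-layer film thickness from noisy data", {
  m <- study_truth("h", FALSE, "30C")
  cvs <- lapply(c("d2o", "h2o"), function(cn)
    generate_curve(m, cn, noise = noise_spec(0.01, 1e-9),
                   seed = match(cn, c("d2o", "h2o"))))
  start <- model_set_params(m, c(tails_d = 24))
  start <- set_vary(start, "tails_d")
  fit <- co_refine(start, cvs, seed = 5,
                   control = refine_control(pop_factor = 8, max_gen = 60))
  expect_equal(unname(fit$best["tails_d"]), 30, tolerance = 1 / 30)
  # the polish never leaves chi2 above the starting point
  expect_lte(fit$chi2, chi2_objective(start, cvs))
})

test_that("co_refine is deterministic for a fixed seed", {
  toy <- make_toy()
  f1 <- co_refine(toy$model, list(toy$data), seed = 9,
                  control = refine_control(pop_factor = 5, max_gen = 30))
  f2 <- co_refine(toy$model, list(toy$data), seed = 9,
                  control = refine_control(pop_factor = 5, max_gen = 30))
  expect_identical(f1$best, f2$best)
  expect_error(co_refine(toy$model, list(toy$data)), "seed")
})

test_that("monte_carlo_errors matches the analytic slope error", {
  toy <- make_toy(a = 2, n = 40, sigma = 0.05, seed = 21)
  fit <- co_refine(toy$model, list(toy$data), seed = 1,
                   control = refine_control(pop_factor = 6, max_gen = 40))
  fit <- monte_carlo_errors(fit, n = 200, seed = 2)
  se_analytic <- toy$sigma / sqrt(sum(toy$x^2))
  half_width <- (fit$ci$upper - fit$ci$lower) / 2
  expect_equal(unname(half_width), 1.96 * se_analytic, tolerance = 0.15)
  expect_true(fit$ci$lower < fit$ci$value & fit$ci$value < fit$ci$upper)
  expect_error(monte_carlo_errors(fit, n = 1, seed = 1), "replicates")
})

test_that("confidence intervals widen when the data get noisier", {
  widths <- vapply(c(0.05, 0.1), function(sig) {
    toy <- make_toy(sigma = sig, seed = 33)
    fit <- co_refine(toy$model, list(toy$data), seed = 1,
                     control = refine_control(pop_factor = 6, max_gen = 40))
    fit <- monte_carlo_errors(fit, n = 120, seed = 3)
    fit$ci$upper - fit$ci$lower
  }, 0)
  expect_gt(widths[2], widths[1])
})

test_that("near-zero dR collapses the resampled distributions", {
  toy <- make_toy(sigma = 1e-9, seed = 4)
  fit <- co_refine(toy$model, list(toy$data), seed = 1,
                   control = refine_control(pop_factor = 5, max_gen = 30))
  fit <- monte_carlo_errors(fit, n = 50, seed = 5)
  expect_lt(fit$ci$upper - fit$ci$lower, 1e-7)
})

test_that("linearized covariance agrees with Monte-Carlo on the toy model", {
  toy <- make_toy(sigma = 0.05, seed = 12)
  fit <- co_refine(toy$model, list(toy$data), seed = 1,
                   control = refine_control(pop_factor = 6, max_gen = 40))
  se_lin <- sqrt(linearized_param_cov(fit)[1, 1])
  se_analytic <- toy$sigma / sqrt(sum(toy$x^2))
  expect_equal(unname(se_lin), se_analytic, tolerance = 0.02)
})

test_that("fit reports serialise parameters, chi2 and CIs", {
  toy <- make_toy()
  fit <- co_refine(toy$model, list(toy$data), seed = 1,
                   control = refine_control(pop_factor = 5, max_gen = 30))
  fit <- monte_carlo_errors(fit, n = 50, seed = 2)
  path <- tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$chi2_total, fit$chi2)
  expect_equal(rep$ci$lower, fit$ci$lower)
  expect_equal(rep$seed, 1)
})
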
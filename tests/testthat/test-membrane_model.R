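test_that("templates expand to the documented media counts", {
  m3 <- membrane_model("three_layer")
  st3 <- expand_model(m3, "d2o")
  expect_equal(nrow(st3), 6)
  expect_equal(st3$name, c("si", "oxide", "heads_in", "tails",
                           "heads_out", "solvent"))
  m4 <- membrane_model("four_layer")
  st4 <- expand_model(m4, "d2o")
  expect_equal(nrow(st4), 7)
  # split tails conserve the total tail thickness
  v <- m4$params$value
  names(v) <- m4$params$name
  expect_equal(sum(st4$thickness[st4$name %in% c("tails_in", "tails_out")]),
               v[["tails_in_d"]] + v[["tails_out_d"]])
  expect_error(membrane_model("five_layer"), "arg")
})

test_that("stacks run from semi-infinite silicon to semi-infinite solvent", {
  for (tpl in c("three_layer", "four_layer")) {
    m <- membrane_model(tpl)
    for (cn in c("d2o", "h2o")) {
      st <- expand_model(m, cn)
      expect_equal(st$sld[1], 2.07e-6)
      expect_equal(st$sld[nrow(st)], m$contrasts[[cn]]$solvent_sld)
    }
  }
})

test_that("hydration limits bracket the layer SLDs", {
  m <- membrane_model("three_layer")
  # fully hydrated: every mixed layer becomes solvent
  m1 <- model_set_params(m, c(oxide_phi = 0.5, heads_phi = 1, tails_phi = 1))
  m1$params["oxide_phi", "value"] <- 1  # beyond the default bound on purpose
  st <- expand_model(m1, "d2o")
  expect_equal(st$sld[2:5], rep(m$contrasts$d2o$solvent_sld, 4))
  # dry: layer SLD equals the dry component SLD
  m0 <- model_set_params(m, c(oxide_phi = 0, heads_phi = 0, tails_phi = 0))
  st0 <- expand_model(m0, "h2o")
  expect_equal(st0$sld[st0$name == "tails"],
               material_sld(default_materials()$tails_h, 0))
})

test_that("contrast change touches only solvent- and exchange-dependent SLDs", {
  m <- model_set_params(membrane_model("four_layer"),
                        c(tails_in_phi = 0.1, tails_out_phi = 0.2))
  a <- expand_model(m, "d2o")
  b <- expand_model(m, "h2o")
  expect_equal(a$thickness, b$thickness)
  expect_equal(a$rough, b$rough)
  # silicon and the dry oxide are contrast-independent; hydrated and
  # exchanging layers are not
  expect_equal(a$sld[1:2], b$sld[1:2])
  expect_false(any(a$sld[3:7] == b$sld[3:7]))
})

test_that("layer mixing agrees with mix_sld bookkeeping", {
  m <- membrane_model("three_layer", peptide = maculatin1())
  m <- model_set_params(m, c(tails_phi = 0.15, tails_pep = 0.2))
  st <- expand_model(m, "d2o")
  lip <- material_sld(default_materials()$tails_h, 1)
  pep <- peptide_sld(maculatin1(), 1, "whole")
  expect_equal(st$sld[st$name == "tails"],
               mix_sld(c(lip, pep, m$contrasts$d2o$solvent_sld),
                       c(0.65, 0.2, 0.15)))
  # fraction bookkeeping beyond unity is an error
  bad <- model_set_params(m, c(tails_phi = 0.6, tails_pep = 0.5))
  expect_error(expand_model(bad, "d2o"), "fractions")
})

test_that("a composed layer round-trips through the decomposition", {
  m <- membrane_model("four_layer", peptide = maculatin1(),
                      peptide_mode = "whole")
  m <- model_set_params(m, c(tails_in_pep = 0.2, tails_in_phi = 0.1))
  sl <- layer_slds(m, "tails_in")
  lip <- vapply(m$cache, function(z) z$tails, 0)
  pep <- vapply(m$cache, function(z) z$pep$whole, 0)
  solv <- vapply(m$cache, function(z) z$solvent, 0)
  dec <- peptide_volume_fraction(sl["tails_in", ], lip, pep, solv)
  expect_equal(dec$phi_peptide, 0.2, tolerance = 1e-10)
  expect_equal(dec$phi_solvent, 0.1, tolerance = 1e-10)
  expect_equal(dec$phi_lipid, 0.7, tolerance = 1e-10)
})

test_that("parameter machinery enforces names, ties and bounds", {
  m <- membrane_model("three_layer")
  expect_error(model_set_params(m, c(nonsense = 1)), "unknown")
  expect_error(set_vary(m, "nonsense"), "unknown")
  m$params["heads_phi", "tie"] <- "tails_phi"
  m <- model_set_params(m, c(tails_phi = 0.33))
  expect_equal(m$params["heads_phi", "value"], 0.33)
  expect_error(set_vary(m, "tails_d", lower = c(tails_d = 50),
                        upper = c(tails_d = 40)), "bound")
})

test_that("oriented peptide modes place the labelled half per leaflet", {
  base <- c(tails_in_pep = 0.18, tails_out_pep = 0.18,
            tails_in_phi = 0.08, tails_out_phi = 0.08)
  m_in <- model_set_params(
    membrane_model("four_layer", peptide = maculatin1(),
                   peptide_mode = "n_in"), base)
  m_out <- model_set_params(
    membrane_model("four_layer", peptide = maculatin1(),
                   peptide_mode = "n_out"), base)
  a <- layer_slds(m_in); b <- layer_slds(m_out)
  # swapping the orientation swaps the leaflet SLD pattern
  expect_equal(a["tails_in", ], b["tails_out", ])
  expect_equal(a["tails_out", ], b["tails_in", ])
  # the deuterated N-half makes its leaflet denser
  expect_gt(a["tails_in", "h2o"], a["tails_out", "h2o"])
})
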
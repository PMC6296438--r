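core_gfp_model <- function() {
  reg <- new_registry()
  woven <- weave(fixture_circuit("CodingGFP", reg), list(design_rules_aspect()), reg)
  generate_model(build_regulation_map(woven), "shea_ackers_rna")
}

test_that("growth contexts add population species and keep every core reaction", {
  core <- core_gfp_model()
  ctx <- growth_context("lag_logistic", mu = 0.03, K = 2, d = 0.05,
                        N0 = 0.01, N0_dead = 0.02)
  full <- apply_growth_context(core, ctx)
  expect_true(all(c("N", "N_dead") %in% full$species$name))
  expect_true(all(core$species$name %in% full$species$name))
  expect_true(all(reaction_fingerprints(core) %in% reaction_fingerprints(full)))
  expect_setequal(names(full$observables), c("OD", "total_fluorescence"))
  # promoter-state species are not diluted by default
  expect_false(any(grepl("dilute_.*P", full$reactions$name) &
                     full$reactions$category == "dilution" &
                     grepl("free|bound", full$reactions$name)))
})

test_that("zero-growth exponential context reproduces the core trajectories exactly", {
  core <- core_gfp_model()
  ctx <- growth_context("exponential", mu = 0, N0 = 0.5)
  full <- apply_growth_context(core, ctx)
  sc <- scenario(60, times = seq(0, 60, by = 0.5))
  tr_core <- simulate_ode(core, sc)
  tr_full <- simulate_ode(full, sc)
  for (s in core$species$name) {
    expect_equal(tr_full[[s]], tr_core[[s]], tolerance = 1e-10)
  }
  expect_equal(tr_full$N, rep(0.5, nrow(tr_full)))
})

test_that("decoupled logistic growth matches the closed-form solution to 1e-6", {
  core <- core_gfp_model()
  ctx <- growth_context("logistic", mu = 0.05, K = 3, N0 = 0.01)
  full <- apply_growth_context(core, ctx)
  sc <- scenario(400, times = seq(0, 400, by = 1))
  tr <- simulate_ode(full, sc)
  t <- tr$time
  closed <- ctx$K / (1 + ((ctx$K - ctx$N0) / ctx$N0) * exp(-ctx$mu * t))
  expect_lt(max(abs(tr$N - closed) / closed), 1e-6)
})

test_that("lag-logistic OD dips before growing into a sigmoid when dead cells are present", {
  core <- core_gfp_model()
  ctx <- growth_context("lag_logistic", mu = 0.05, K = 3, d = 0.1,
                        N0 = 0.01, N0_dead = 0.2)
  full <- apply_growth_context(core, ctx)
  tr <- simulate_ode(full, scenario(400, times = seq(0, 400, by = 1)))
  dod <- diff(tr$OD)
  expect_lt(dod[[1]], 0)                         # initial dip
  expect_gt(max(dod), 0)                         # then growth
  sign_changes <- sum(diff(sign(dod[dod != 0])) != 0)
  expect_equal(sign_changes, 1L)                 # negative then positive only
  expect_lt(abs(dod[[length(dod)]]), 1e-3)       # saturating at the end
  expect_equal(tr$OD[[1]], ctx$N0 + ctx$N0_dead)
})

test_that("growth context validates its inputs and the fluorescence observable", {
  core <- core_gfp_model()
  expect_error(growth_context("lag_logistic", mu = 0.05, d = 0), "death rate")
  expect_error(apply_growth_context(core, growth_context("exponential", mu = 0.01),
                                    fluorescence = "mCherry"), "mCherry")
  no_protein <- circuitweaver:::empty_model("shea_ackers_rna")
  expect_error(apply_growth_context(no_protein,
                                    growth_context("exponential", mu = 0.01)),
               "protein")
})

test_that("protease coupling merges namespaces and only rewrites the tagged degradations", {
  sw <- switch_model()
  os <- oscillator_model()
  cp <- protease_coupling("A", "AraC", V = 100, Km = 10, delta = 1, gamma = 0.1)
  cm <- apply_protease_coupling(sw, os, cp)
  expect_equal(nrow(cm$species), nrow(sw$species) + nrow(os$species))
  expect_true(all(c("sw_A", "osc_AraC") %in% cm$species$name))
  cpl <- cm$reactions[cm$reactions$category == "coupled_degradation", ]
  expect_equal(sort(unlist(lapply(cpl$reactants, names))), c("osc_AraC", "sw_A"))
  # everything else untouched up to prefixing
  n_changed <- sum(!cm$reactions$mass_action & cm$reactions$category ==
                     "coupled_degradation")
  expect_equal(nrow(cpl), 2L)
  expect_error(apply_protease_coupling(sw, os,
                 protease_coupling("A", "GFP", V = 1, Km = 1, delta = 1,
                                   gamma = 1) |>
                   (\(x) { x$tag_oscillator <- "NoSuch"; x })()),
               "missing")
})

test_that("competitive degradation is monotone decreasing in the competitor", {
  cp <- protease_coupling("A", "AraC", V = 50, Km = 5, delta = 2, gamma = 0.5)
  cm <- apply_protease_coupling(switch_model(), oscillator_model(), cp)
  law <- cm$reactions$rate_law[[which(cm$reactions$name == "osc_deg_AraC")]]
  rate_at <- function(a_level, x_level = 3) {
    eval(parse(text = law), envir = c(as.list(cm$parameters),
                                      list(sw_A = a_level, osc_AraC = x_level)))
  }
  vals <- vapply(seq(0, 100, by = 5), rate_at, numeric(1))
  expect_true(all(diff(vals) < 0))  # more competitor, less degradation
})

test_that("the uncoupled merge reproduces the two separate models' dynamics", {
  sw <- switch_model()
  os <- oscillator_model()
  merged <- circuitweaver:::empty_model("merged")
  swp <- circuitweaver:::prefix_model(sw, "sw_")
  osp <- circuitweaver:::prefix_model(os, "osc_")
  merged$species <- dplyr::bind_rows(swp$species, osp$species)
  merged$reactions <- dplyr::bind_rows(swp$reactions, osp$reactions)
  merged$parameters <- c(swp$parameters,
                         osp$parameters[setdiff(names(osp$parameters),
                                                names(swp$parameters))])
  sc_m <- scenario(60, times = seq(0, 60, by = 0.5),
                   init = c(sw_B = 5, osc_AraC = 0.1, osc_LacI = 10))
  sc_o <- scenario(60, times = seq(0, 60, by = 0.5),
                   init = c(AraC = 0.1, LacI = 10))
  tr_m <- simulate_ode(merged, sc_m)
  tr_o <- simulate_ode(os, sc_o)
  expect_equal(tr_m$osc_GFP, tr_o$GFP, tolerance = 1e-8)
})
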
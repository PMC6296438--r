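rep_map <- function() {
  reg <- new_registry()
  build_regulation_map(linearize(fixture_circuit("AbstractRepressilator", reg), reg))
}

test_that("regulation map pairs promoters, regulators and coded products", {
  map <- rep_map()
  expect_equal(nrow(map), 3L)
  expect_equal(vapply(map$regulators, length, integer(1)), rep(1L, 3))
  expect_equal(unlist(map$products), c("TF1", "TF2", "TF3"))

  reg <- new_registry()
  gfp <- weave(fixture_circuit("CodingGFP", reg), list(design_rules_aspect()), reg)
  m2 <- build_regulation_map(gfp)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$products[[1]], "GFP")

  declare_molecule_type(reg, "Orphan", "Protein")
  bad <- circuit("Bad") |> declare_molecule("Orphan") |>
    add_part(part(reg, "CodingRegion", "cO", codes_for = "Orphan"))
  expect_error(build_regulation_map(linearize(bad, reg)), "orphan coding region")
})

test_that("terminators bound transcription units so operons are supported", {
  reg <- new_registry()
  declare_molecule_type(reg, "Px", "Protein")
  declare_molecule_type(reg, "Py", "Protein")
  op <- circuit("Operon") |>
    declare_molecule("Px") |> declare_molecule("Py") |>
    add_part(part(reg, "ConstitutivePromoter", "pOp")) |>
    add_part(part(reg, "CodingRegion", "c1", codes_for = "Px")) |>
    add_part(part(reg, "CodingRegion", "c2", codes_for = "Py")) |>
    add_part(part(reg, "Terminator", "t1")) |>
    add_part(part(reg, "ConstitutivePromoter", "pSolo")) |>
    add_part(part(reg, "CodingRegion", "c3", codes_for = "Px"))
  map <- build_regulation_map(linearize(op, reg))
  expect_equal(map$products[[1]], c("Px", "Py"))
  expect_equal(map$products[[2]], "Px")
})

test_that("repressilator model sizes match the enumeration oracle for all strategies", {
  map <- rep_map()
  m1 <- generate_model(map, "mass_action_protein")
  expect_equal(nrow(m1$reactions), 12L)
  expect_equal(nrow(m1$species), 9L)
  m2 <- generate_model(map, "mass_action_rna")
  expect_equal(nrow(m2$reactions), 18L)
  expect_equal(nrow(m2$species), 12L)
  m3 <- generate_model(map, "shea_ackers_rna")
  expect_equal(nrow(m3$reactions), 12L)
  expect_equal(nrow(m3$species), 6L)
  # promoter states only exist under the explicit-binding strategies
  expect_false(any(m3$species$role == "promoter_state"))
})

test_that("protein-level reaction counts match the oracle on 100 random repressor circuits", {
  for (seed in 1:100) {
    reg <- new_registry()
    circ <- random_repressor_circuit(seed, reg)
    map <- build_regulation_map(linearize(circ, reg))
    m <- generate_model(map, "mass_action_protein")
    expect_equal(nrow(m$reactions), oracle_protein_counts(map)$reactions,
                 info = paste("seed", seed))
  }
})

test_that("stoichiometry columns are products minus reactants", {
  map <- rep_map()
  m <- generate_model(map, "mass_action_protein")
  S <- stoichiometry(m)
  expect_equal(dim(S), c(9L, 12L))
  bind <- S[, "bind_P1_TF3"]
  expect_equal(bind[["P1_free"]], -1L)
  expect_equal(bind[["TF3"]], -1L)
  expect_equal(bind[["P1_TF3"]], 1L)
  expect_equal(sum(bind != 0), 3L)
  expr_col <- S[, "expr_P1_free_TF1"]
  expect_equal(expr_col[["TF1"]], 1L)
  expect_equal(sum(expr_col != 0), 1L)  # catalyst cancels
})

test_that("mass-action parameters are one-per-reaction and collision-free", {
  map <- rep_map()
  for (strategy in c("mass_action_protein", "mass_action_rna")) {
    m <- generate_model(map, strategy)
    expect_equal(anyDuplicated(m$reactions$parameter), 0L)
    expect_equal(length(m$parameters), nrow(m$reactions))
  }
})

test_that("Shea-Ackers transcription law has the occupancy-ratio limits", {
  reg <- new_registry()
  declare_molecule_type(reg, "Act", "Protein")
  declare_molecule_type(reg, "Rep", "Protein")
  declare_molecule_type(reg, "Out", "Protein")
  circ <- circuit("Mixed") |>
    declare_molecule("Act") |> declare_molecule("Rep") |> declare_molecule("Out") |>
    add_part(part(reg, "Promoter", "pM", regulated_by = c("Act", "Rep"),
                  signs = c("positive", "negative"))) |>
    add_part(part(reg, "CodingRegion", "cOut", codes_for = "Out"))
  m <- generate_model(build_regulation_map(linearize(circ, reg)), "shea_ackers_rna")
  law <- m$reactions$rate_law[[which(m$reactions$name == "tx_pM_Out")]]
  rate <- function(Act, Rep) {
    eval(parse(text = law), envir = c(as.list(m$parameters),
                                      list(Act = Act, Rep = Rep)))
  }
  p <- m$parameters
  # activator -> 0 limit: basal over repressor occupancy
  expect_equal(rate(0, 3),
               p[["k_tx_pM_Out"]] * p[["a0_pM"]] / (1 + p[["K_pM_Rep"]] * 9),
               tolerance = 1e-12)
  # monotone decreasing in the repressor
  reps <- seq(0, 5, by = 0.5)
  vals <- vapply(reps, function(r) rate(2, r), numeric(1))
  expect_true(all(diff(vals) < 0))
  # bounded by the maximal activated rate
  expect_true(all(vapply(seq(0, 100, by = 5), function(a) rate(a, 0), numeric(1)) <=
                    p[["k_tx_pM_Out"]] * max(p[["a_pM_Act"]], p[["a0_pM"]])))
  # unregulated promoter transcribes at a constant basal rate
  m0 <- generate_model(rep_map()[0, ] |> (\(x) {
    reg2 <- new_registry()
    declare_molecule_type(reg2, "Solo", "Protein")
    solo <- circuit("Solo") |> declare_molecule("Solo") |>
      add_part(part(reg2, "ConstitutivePromoter", "pS")) |>
      add_part(part(reg2, "CodingRegion", "cS", codes_for = "Solo"))
    build_regulation_map(linearize(solo, reg2))
  })(), "shea_ackers_rna")
  law0 <- m0$reactions$rate_law[[which(m0$reactions$name == "tx_pS_Solo")]]
  expect_equal(eval(parse(text = law0), envir = as.list(m0$parameters)),
               m0$parameters[["k_tx_pS_Solo"]] * m0$parameters[["a0_pS"]],
               tolerance = 1e-12)
})

test_that("promoter totals are conserved structurally and along ODE trajectories", {
  map <- rep_map()
  m <- generate_model(map, "mass_action_protein")
  S <- stoichiometry(m)
  prev <- c("TF3", "TF1", "TF2")
  for (i in 1:3) {
    states <- c(paste0("P", i, "_free"), paste0("P", i, "_", prev[[i]]))
    v <- as.numeric(m$species$name %in% states)
    expect_equal(max(abs(t(v) %*% S)), 0)  # left-null vector of S
  }
  sc <- scenario(50, init = c(TF1 = 2, TF2 = 1, TF3 = 0.5))
  tr <- simulate_ode(m, sc)
  for (i in 1:3) {
    tot <- tr[[paste0("P", i, "_free")]] + tr[[paste0("P", i, "_", prev[[i]])]]
    expect_lt(max(abs(tot - tot[[1]])) / tot[[1]], 1e-6)
  }
})

test_that("reaction listing prints one line per reaction with rate and parameter", {
  m <- generate_model(rep_map(), "mass_action_protein")
  lines <- print_reactions(m)
  expect_length(lines, 12L)
  expect_match(lines[[1]], "P1_free \\+ TF3 -> P1_TF3")
  expect_match(lines[[1]], "k_bind_P1_TF3 = 1")
})
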
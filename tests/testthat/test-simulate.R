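test_that("scenarios validate their time grid and events", {
  expect_error(scenario(-1), "t_end > 0|is not TRUE")
  expect_error(scenario(10, events = data.frame(time = 20, species = "x",
                                                value = 1)),
               "within")
  sc <- scenario(10, events = data.frame(time = c(5, 2), species = "x",
                                         value = 1:2))
  expect_equal(sc$events$time, c(2, 5))  # sorted
})

test_that("a hand-built logistic model matches the closed form to 1e-6", {
  m <- circuitweaver:::empty_model("manual")
  m <- circuitweaver:::add_species(m, "N", "population", 0.01)
  m <- circuitweaver:::add_reaction(m, "growth",
                                    stats::setNames(numeric(), character()),
                                    c(N = 1), "mu", 0.05, "growth",
                                    rate_law = "mu * N * (1 - N / K_cap)")
  m$parameters[["K_cap"]] <- 2
  tr <- simulate_ode(m, scenario(300, times = seq(0, 300, by = 1)))
  closed <- 2 / (1 + ((2 - 0.01) / 0.01) * exp(-0.05 * tr$time))
  expect_lt(max(abs(tr$N - closed) / closed), 1e-6)
})

test_that("zero rates give constant trajectories", {
  m <- birth_death_model(k_b = 0, k_d = 0)
  tr <- simulate_ode(m, scenario(50, init = c(Npart = 7)))
  expect_true(all(tr$Npart == 7))
})

test_that("events set species values exactly at their times", {
  m <- birth_death_model(k_b = 0, k_d = 0)
  sc <- scenario(10, times = seq(0, 10, by = 0.25),
                 events = data.frame(time = 5, species = "Npart", value = 3))
  tr <- simulate_ode(m, sc)
  expect_equal(tr$Npart[tr$time < 5], rep(0, sum(tr$time < 5)))
  expect_equal(tr$Npart[tr$time > 5], rep(3, sum(tr$time > 5)))
  # add events accumulate
  sc2 <- scenario(10, times = seq(0, 10, by = 0.25),
                  events = data.frame(time = c(2, 4), species = "Npart",
                                      value = 2, method = "add"))
  tr2 <- simulate_ode(m, sc2)
  expect_equal(tr2$Npart[[nrow(tr2)]], 4)
})

test_that("SSA is reproducible under a seed and validates inputs", {
  m <- birth_death_model()
  sc <- scenario(50, times = seq(0, 50, by = 1))
  t1 <- simulate_ssa(m, sc, seed = 11)
  t2 <- simulate_ssa(m, sc, seed = 11)
  expect_identical(t1$Npart, t2$Npart)
  t3 <- simulate_ssa(m, sc, seed = 12)
  expect_false(identical(t1$Npart, t3$Npart))
  expect_error(simulate_ssa(m, scenario(10, init = c(Npart = -1)), seed = 1),
               "non-negative")
  expect_error(simulate_ssa(m, scenario(10, init = c(Npart = 0.5)), seed = 1),
               "integer")
})

test_that("SSA events are applied and the caller's RNG state is untouched", {
  m <- birth_death_model(k_b = 0, k_d = 0)
  sc <- scenario(10, times = seq(0, 10, by = 0.5),
                 events = data.frame(time = 5, species = "Npart", value = 9))
  tr <- simulate_ssa(m, sc, seed = 2)
  expect_equal(tr$Npart[tr$time > 5], rep(9, sum(tr$time > 5)))
  set.seed(123); before <- .Random.seed
  invisible(simulate_ssa(m, sc, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("birth-death SSA matches the analytic stationary mean within 3 SE", {
  m <- birth_death_model(k_b = 1, k_d = 0.1)  # mean k_b / k_d = 10
  finals <- vapply(1:100, function(s) {
    tr <- simulate_ssa(m, scenario(80, times = seq(0, 80, by = 20)), seed = s)
    tr$Npart[[nrow(tr)]]
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 10), 3 * se)
})

test_that("SSA means approach the ODE solution when counts are scaled up", {
  reg <- new_registry()
  declare_molecule_type(reg, "Px", "Protein")
  solo <- circuit("Solo") |> declare_molecule("Px") |>
    add_part(part(reg, "ConstitutivePromoter", "pS")) |>
    add_part(part(reg, "CodingRegion", "cS", codes_for = "Px"))
  rm <- generate_rules(weave(solo, list(), reg),
                       params = c(k_tx_pS_Px = 0.5, k_tl_Px = 0.5,
                                  k_degm_Px = 0.5, k_deg_Px = 0.1),
                       copies = 100L)
  grounded <- rule_model_to_reactions(rm)
  sc <- scenario(120, times = seq(0, 120, by = 2))
  ode <- simulate_ode(grounded, sc)
  ssa_runs <- lapply(1:5, function(s) simulate_ssa(rm, sc, seed = s))
  ssa_mean <- Reduce(`+`, lapply(ssa_runs, function(tr) tr$Px)) / 5
  tail_idx <- which(sc$times >= 60)
  rel <- abs(mean(ssa_mean[tail_idx]) - mean(ode$Px[tail_idx])) /
    mean(ode$Px[tail_idx])
  expect_lt(rel, 0.05)
})

test_that("the oscillation detector classifies known signals", {
  t <- seq(0, 60, by = 0.05)
  sine <- structure(tibble::tibble(time = t, s = sin(t)),
                    class = c("cw_trajectory", class(tibble::tibble())))
  d <- detect_oscillation(sine, "s")
  expect_true(d$oscillating)
  expect_equal(d$period, 2 * pi, tolerance = 0.02)

  decay <- structure(tibble::tibble(time = t, s = exp(-t / 10)),
                     class = c("cw_trajectory", class(tibble::tibble())))
  expect_false(detect_oscillation(decay, "s")$oscillating)

  # damped oscillation with only a few surviving peaks fails the >= 5 rule
  damped <- structure(tibble::tibble(time = t, s = exp(-t / 6) * sin(t)),
                      class = c("cw_trajectory", class(tibble::tibble())))
  dd <- detect_oscillation(damped, "s")
  expect_false(dd$oscillating)
  expect_lt(dd$n_peaks, 5L)

  short <- structure(tibble::tibble(time = 1:50, s = sin(1:50)),
                     class = c("cw_trajectory", class(tibble::tibble())))
  expect_error(detect_oscillation(short, "s"), "at least 100")
})

test_that("conserved quantities stay constant along mass-action ODE trajectories", {
  reg <- new_registry()
  map <- build_regulation_map(
    linearize(fixture_circuit("AbstractRepressilator", reg), reg))
  m <- generate_model(map, "mass_action_rna")
  S <- stoichiometry(m)
  # left null space of S via SVD: vectors v with t(v) %*% S = 0
  sv <- svd(S, nu = nrow(S))
  rank <- sum(sv$d > 1e-10)
  null_left <- sv$u[, setdiff(seq_len(nrow(S)), seq_len(rank)), drop = FALSE]
  tr <- simulate_ode(m, scenario(40, init = c(TF1 = 1, TF3 = 2)))
  X <- as.matrix(tr[, m$species$name])
  if (ncol(null_left) > 0) {
    cons <- X %*% null_left
    for (j in seq_len(ncol(cons))) {
      spread <- max(abs(cons[, j] - cons[1, j]))
      scale <- max(abs(cons[, j]), 1e-8)
      expect_lt(spread / scale, 1e-6)
    }
  }
})

test_that("the switchable-scenario runner demands an inducer event", {
  cm <- coupled_switchable_model("AraC")
  expect_error(run_switchable_scenario(cm, scenario(100)), "inducer event")
})
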
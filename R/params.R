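#' Shipped parameter sets
#'
#' Named parameter sets under which the shipped example systems display
#' their reference behaviour. They were found by coarse grid search over the
#' generated models and are frozen here so that every example simulates out
#' of the box; they are package defaults, not measured quantities.
#'
#' * `"repressilator_ode"` — Shea-Ackers RNA+protein repressilator
#'   (concentration units, min): sustained oscillation.
#' * `"repressilator_rules"` — rule-based repressilator (count units, min):
#'   stochastic oscillation with rotating dominance.
#' * `"switch"` / `"oscillator"` — Shea-Ackers models of the bistable toggle
#'   switch and the positive/negative-feedback oscillator.
#' * `"coupling"` — shared-protease coupling (`V`, `Km`, `delta`, `gamma`,
#'   with `delta >> gamma`: the protease must degrade the tagged oscillator
#'   species much more strongly than the switch protein).
#'
#' @param set Parameter-set name.
#' @return Named numeric vector.
#' @export
shipped_parameters <- function(set = c("repressilator_ode",
                                       "repressilator_rules",
                                       "switch", "oscillator", "coupling")) {
  set <- match.arg(set)
  switch(set,
    repressilator_ode = c(
      k_tx = 30, K = 0.2, k_tl = 5, k_degm = 0.3466, k_deg = 0.15,
      n_hill = 2
    ),
    repressilator_rules = c(
      k_bind = 0.05, k_unbind = 0.1, k_tx = 5, k_tl = 1.2,
      k_degm = 0.3466, k_deg = 0.0693
    ),
    switch = c(
      k_tx = 6, k_tl = 2, k_degm = 0.35, k_deg = 0.1,
      K_B = 2, K_A = 2, K_I = 1e4, n_hill = 2
    ),
    oscillator = c(
      k_tx = 109.375, k_tl = 21.875, k_degm = 3.0625, k_deg_AraC = 2.625,
      k_deg_LacI = 0.4375, k_deg_GFP = 2.625, K_a = 0.04, K_r = 0.25,
      a_act = 20, a0 = 0.1, n_hill = 2
    ),
    coupling = c(V = 800, Km = 20, delta = 20, gamma = 0.015)
  )
}

#' Build the repressilator reaction model
#'
#' Constructs the abstract three-gene repressilator fixture, builds its
#' regulation map and generates a reaction model with the shipped parameter
#' set (overridable).
#'
#' @param strategy Kinetic strategy, see [generate_model()].
#' @param params Named overrides of the shipped set (compact names: `k_tx`,
#'   `K`, `k_tl`, `k_degm`, `k_deg`, `n_hill`).
#' @param reg Optional registry to reuse.
#' @return A `cw_reaction_model`.
#' @export
repressilator_model <- function(strategy = "shea_ackers_rna",
                                params = shipped_parameters("repressilator_ode"),
                                reg = new_registry()) {
  circ <- fixture_circuit("AbstractRepressilator", reg)
  map <- build_regulation_map(linearize(circ, reg))
  prev <- c("TF3", "TF1", "TF2")
  full <- c()
  for (i in 1:3) {
    full[paste0("k_tx_P", i, "_TF", i)] <- params[["k_tx"]]
    full[paste0("K_P", i, "_", prev[[i]])] <- params[["K"]]
    full[paste0("k_tl_TF", i)] <- params[["k_tl"]]
    full[paste0("k_degm_TF", i)] <- params[["k_degm"]]
    full[paste0("k_deg_TF", i)] <- params[["k_deg"]]
    full[paste0("k_expr_P", i, "_free_TF", i)] <- params[["k_tx"]]
    full[paste0("k_bind_P", i, "_", prev[[i]])] <- params[["K"]]
    full[paste0("k_unbind_P", i, "_", prev[[i]])] <- 1
  }
  full["n_hill"] <- if ("n_hill" %in% names(params)) params[["n_hill"]] else 2
  generate_model(map, strategy, params = full)
}

#' Build the repressilator rule-based model
#'
#' @param params Compact overrides (`k_bind`, `k_unbind`, `k_tx`, `k_tl`,
#'   `k_degm`, `k_deg`), count units.
#' @param reg Optional registry to reuse.
#' @return A `cw_rule_model`.
#' @export
repressilator_rule_model <- function(params = shipped_parameters("repressilator_rules"),
                                     reg = new_registry()) {
  circ <- fixture_circuit("AbstractRepressilator", reg)
  woven <- weave(circ, list(), reg)
  prev <- c("TF3", "TF1", "TF2")
  full <- c()
  for (i in 1:3) {
    full[paste0("k_bind_P", i, "_", prev[[i]])] <- params[["k_bind"]]
    full[paste0("k_unbind_P", i, "_", prev[[i]])] <- params[["k_unbind"]]
    full[paste0("k_tx_P", i, "_TF", i)] <- params[["k_tx"]]
    full[paste0("k_tl_TF", i)] <- params[["k_tl"]]
    full[paste0("k_degm_TF", i)] <- params[["k_degm"]]
    full[paste0("k_deg_TF", i)] <- params[["k_deg"]]
  }
  generate_rules(woven, params = full)
}

#' Build the toggle-switch and feedback-oscillator Shea-Ackers models
#'
#' Both core concerns are generated with the Shea-Ackers RNA strategy from
#' their fixture circuits, under the shipped parameter sets.
#'
#' @param params Named overrides of the corresponding shipped set.
#' @param reg Optional registry to reuse.
#' @return A `cw_reaction_model`.
#' @export
switch_model <- function(params = shipped_parameters("switch"),
                         reg = new_registry()) {
  circ <- fixture_circuit("ToggleSwitch", reg)
  map <- build_regulation_map(linearize(circ, reg))
  full <- c(
    k_tx_pA_A = params[["k_tx"]], k_tx_pB_B = params[["k_tx"]],
    k_tl_A = params[["k_tl"]], k_tl_B = params[["k_tl"]],
    k_degm_A = params[["k_degm"]], k_degm_B = params[["k_degm"]],
    k_deg_A = params[["k_deg"]], k_deg_B = params[["k_deg"]],
    K_pA_B = params[["K_B"]], K_pB_A = params[["K_A"]],
    K_pB_Inducer = params[["K_I"]], n_hill = params[["n_hill"]]
  )
  generate_model(map, "shea_ackers_rna", params = full)
}

#' @rdname switch_model
#' @export
oscillator_model <- function(params = shipped_parameters("oscillator"),
                             reg = new_registry()) {
  circ <- fixture_circuit("FeedbackOscillator", reg)
  map <- build_regulation_map(linearize(circ, reg))
  full <- c(n_hill = params[["n_hill"]])
  genes <- c("AraC", "LacI", "GFP")
  for (i in 1:3) {
    g <- genes[[i]]
    full[paste0("k_tx_pHyb", i, "_", g)] <- params[["k_tx"]]
    full[paste0("K_pHyb", i, "_AraC")] <- params[["K_a"]]
    full[paste0("K_pHyb", i, "_LacI")] <- params[["K_r"]]
    full[paste0("a_pHyb", i, "_AraC")] <- params[["a_act"]]
    full[paste0("a0_pHyb", i)] <- params[["a0"]]
    full[paste0("k_tl_", g)] <- params[["k_tl"]]
    full[paste0("k_degm_", g)] <- params[["k_degm"]]
    full[paste0("k_deg_", g)] <- params[[paste0("k_deg_", g)]]
  }
  generate_model(map, "shea_ackers_rna", params = full)
}

#' Build the protease-coupled switchable-oscillator model
#'
#' Couples the shipped switch and oscillator models through the shared
#' protease, tagging switch protein `A` and one oscillator species.
#'
#' @param tag Oscillator species sharing the protease: `"AraC"` (the
#'   configuration producing switchable oscillation) or `"GFP"`.
#' @param coupling_params Named overrides of the shipped coupling set.
#' @param switch_params,oscillator_params Overrides for the two core models.
#' @return A coupled `cw_reaction_model`.
#' @export
coupled_switchable_model <- function(tag = c("AraC", "GFP"),
                                     coupling_params = shipped_parameters("coupling"),
                                     switch_params = shipped_parameters("switch"),
                                     oscillator_params = shipped_parameters("oscillator")) {
  tag <- match.arg(tag)
  cp <- protease_coupling(
    tag_switch = "A", tag_oscillator = tag,
    V = coupling_params[["V"]], Km = coupling_params[["Km"]],
    delta = coupling_params[["delta"]], gamma = coupling_params[["gamma"]])
  apply_protease_coupling(switch_model(switch_params),
                          oscillator_model(oscillator_params), cp)
}

#' Standard switchable-oscillator scenario
#'
#' The reference scenario for the coupled switch/oscillator system: the
#' switch starts in the low-`A` state (`B` high), the oscillator starts on
#' its limit cycle, and the inducer is added (set to 1) at `t_event`.
#'
#' @param t_end End time (min).
#' @param t_event Inducer-addition time (min); default 90.
#' @param by Output grid spacing (min).
#' @return A [scenario()].
#' @export
switchable_scenario <- function(t_end = 420, t_event = 90, by = 0.5) {
  scenario(
    t_end, times = seq(0, t_end, by = by),
    init = c(sw_B = 5, osc_AraC = 0.1, osc_LacI = 10),
    events = data.frame(time = t_event, species = "sw_Inducer", value = 1)
  )
}
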
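test_that("weaving with no aspects is the identity on the declared flow", {
  reg <- new_registry()
  circ <- fixture_circuit("InducedGFP", reg)
  woven <- weave(circ, list(), reg)
  declared <- linearize(circ, reg)
  expect_equal(flow_parts(woven$flow)$name, flow_parts(declared)$name)
  expect_true(all(woven$flow$provenance == "design"))
})

test_that("design-rules weaving brackets every coding region", {
  reg <- new_registry()
  gfp <- fixture_circuit("CodingGFP", reg)
  woven <- weave(gfp, list(design_rules_aspect()), reg)
  expect_equal(flow_parts(woven$flow)$part_type,
               c("ConstitutivePromoter", "RBS", "CodingRegion", "Terminator"))
  # two coding regions: 4 declared parts become 8
  two <- two_gene_circuit(reg)
  w2 <- weave(two, list(design_rules_aspect()), reg)
  tp <- flow_parts(w2$flow)$part_type
  expect_equal(length(tp), 8L)
  cds <- which(tp == "CodingRegion")
  expect_true(all(tp[cds - 1L] == "RBS"))
  expect_true(all(tp[cds + 1L] == "Terminator"))
})

test_that("advice resolution ranks by priority, aspect order, then declaration order", {
  reg <- new_registry()
  circ <- circuit("C") |> add_part(part(reg, "RBS", "seed"))

  mk_replace <- function(label, priority) {
    aspect(label, advice_list = list(
      advice(point_cut("seed", "replace", priority = priority),
             function(ctx) part(ctx$registry, "RBS", paste0("by_", label)))))
  }
  w <- weave(circ, list(mk_replace("low", 1), mk_replace("high", 2)), reg)
  expect_equal(flow_parts(w$flow)$name, "by_high")

  mk_before <- function(label) {
    aspect(label, advice_list = list(
      advice(point_cut("seed", "before"),
             function(ctx) part(ctx$registry, "RBS", paste0("ins_", label)))))
  }
  w2 <- weave(circ, list(mk_before("A"), mk_before("B")), reg)
  expect_equal(flow_parts(w2$flow)$name, c("ins_A", "ins_B", "seed"))

  bracketing <- aspect("Bracket", advice_list = list(
    advice(point_cut("seed", "before"),
           function(ctx) part(ctx$registry, "RBS", "pre")),
    advice(point_cut("seed", "after"),
           function(ctx) part(ctx$registry, "RBS", "post"))))
  w3 <- weave(circ, list(bracketing), reg)
  expect_equal(flow_parts(w3$flow)$name, c("pre", "seed", "post"))
})

test_that("replace advice sees the replaced part and exactly one replacement is applied", {
  reg <- new_registry()
  declare_molecule_type(reg, "Ara")
  declare_molecule_type(reg, "TF", "Protein")
  circ <- circuit("C") |> declare_molecule("Ara") |>
    add_part(part(reg, "PositivePromoter", "pIn", regulated_by = "Ara"))
  swap <- aspect("Swap", advice_list = list(
    advice(point_cut("pIn", "replace"), function(ctx) {
      old_regs <- vapply(ctx$part$regulation, `[[`, character(1), "molecule")
      part(ctx$registry, "PositivePromoter", "pNew", regulated_by = old_regs)
    })))
  w <- weave(circ, list(swap), reg)
  parts <- flow_parts(w$flow)
  expect_equal(parts$name, "pNew")
  expect_equal(parts$regulation[[1]][[1]]$molecule, "Ara")
  # round trip: removing insertions and undoing replacements recovers the design
  restored <- declared_flow(w)
  expect_equal(flow_parts(restored)$name, "pIn")
})

test_that("weaving is deterministic and never reorders design parts", {
  reg <- new_registry()
  circ <- two_gene_circuit(reg)
  w1 <- weave(circ, list(design_rules_aspect()), reg)
  w2 <- weave(circ, list(design_rules_aspect()), reg)
  expect_equal(flow_parts(w1$flow)$name, flow_parts(w2$flow)$name)
  design_names <- flow_parts(linearize(circ, reg))$name
  woven_design <- flow_parts(w1$flow)
  expect_equal(woven_design$name[woven_design$provenance == "design"],
               design_names)
})

test_that("advice-inserted parts are join points for other aspects but not their inserter", {
  reg <- new_registry()
  circ <- circuit("C") |> add_part(part(reg, "RBS", "seed"))
  # an advice inserting a part that matches its own point cut must not
  # re-trigger itself: exactly one insertion per design part
  selfish <- aspect("Selfish", advice_list = list(
    advice(point_cut("RBS+", "after"),
           function(ctx) part(ctx$registry, "RBS", paste0("s_", ctx$part$name)))))
  w0 <- weave(circ, list(selfish), reg)
  expect_equal(flow_parts(w0$flow)$name, c("seed", "s_seed"))

  # but a different aspect evaluated at that position does see the insertion
  inserter <- aspect("Inserter", advice_list = list(
    advice(point_cut("RBS+", "after"),
           function(ctx) part(ctx$registry, "Terminator", paste0("t_", ctx$part$name)))))
  reactor <- aspect("Reactor", advice_list = list(
    advice(point_cut("Terminator+", "after"),
           function(ctx) part(ctx$registry, "Promoter", paste0("p_", ctx$part$name)))))
  w <- weave(circ, list(inserter, reactor), reg)
  nm <- flow_parts(w$flow)$name
  expect_true("t_seed" %in% nm)    # inserted by Inserter at the design part
  expect_true("p_t_seed" %in% nm)  # Reactor reacted to the inserted part
})

test_that("runaway mutual advice triggering raises a cyclic-advice error naming aspects", {
  reg <- new_registry()
  circ <- circuit("C") |> add_part(part(reg, "RBS", "Xseed"))
  a <- aspect("PingAspect", advice_list = list(
    advice(point_cut("X*", "after"), function(ctx) part(ctx$registry, "RBS", "Ypart"))))
  b <- aspect("PongAspect", advice_list = list(
    advice(point_cut("Y*", "after"), function(ctx) part(ctx$registry, "RBS", "Xpart"))))
  expect_error(weave(circ, list(a, b), reg), "cyclic advice.*PingAspect|PongAspect")
})

test_that("type advice annotates matched parts after weaving, with conflict detection", {
  reg <- new_registry()
  rep3 <- fixture_circuit("AbstractRepressilator", reg)
  annotate <- aspect("Annotate", type_advice_list = list(
    type_advice("Promoter+", "reaction_set",
                function(ctx) paste0("rx_", ctx$part$name))))
  w <- weave(rep3, list(annotate), reg)
  props <- w$properties
  expect_equal(sort(props$part), c("P1", "P2", "P3"))
  expect_equal(props$value[[which(props$part == "P2")]], "rx_P2")

  # advice on a type absent from the system is a no-op
  noop <- aspect("Noop", type_advice_list = list(
    type_advice("RBS+", "unused", function(ctx) 1)))
  w2 <- weave(rep3, list(noop), reg)
  expect_equal(nrow(w2$properties), 0L)

  # two aspects attaching distinct property names coexist
  other <- aspect("Other", type_advice_list = list(
    type_advice("Promoter+", "colour", function(ctx) "green")))
  w3 <- weave(rep3, list(annotate, other), reg)
  expect_equal(nrow(w3$properties), 6L)

  # same property name from two aspects conflicts
  clash <- aspect("Clash", type_advice_list = list(
    type_advice("Promoter+", "reaction_set", function(ctx) "dup")))
  expect_error(weave(rep3, list(annotate, clash), reg), "already set")
})

test_that("aspect outputs are registered on the woven system", {
  reg <- new_registry()
  gfp <- fixture_circuit("CodingGFP", reg)
  out_aspect <- aspect("Diagram", outputs = list(
    pigeon = function(woven) emit_pigeon(woven)))
  w <- weave(gfp, list(design_rules_aspect(), out_aspect), reg)
  expect_true("pigeon" %in% names(w$outputs))
  expect_equal(length(w$outputs$pigeon), 4L)
})
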
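# Reference circuits for the eight captioned signature cases: a simple
# induced-reporter compartment with a BioBrick RBS, a TetR-repressed promoter
# and a TetR coding region, plus a constitutive compartment without
# regulation.
sig_fixture <- function() {
  reg <- new_registry()
  declare_molecule_type(reg, "TetR", "Protein")
  declare_molecule_type(reg, "GFP", "Protein")
  declare_molecule_type(reg, "Ara")
  declare_part_type(reg, "BBa_B0030", "RBS")
  simple <- circuit("SimpleCircuit") |>
    declare_molecule("TetR") |>
    declare_molecule("Ara") |>
    add_part(part(reg, "NegativePromoter", "pTet", regulated_by = "TetR")) |>
    add_part(part(reg, "BBa_B0030", "BBa_B0030")) |>
    add_part(part(reg, "CodingRegion", "cTetR", codes_for = "TetR")) |>
    add_part(part(reg, "Terminator", "term1"))
  list(reg = reg, circ = simple, flow = linearize(simple, reg))
}

test_that("part-signature parsing covers the grammar and reports malformed input", {
  s <- parse_part_signature("SimpleCircuit.BBa_B0030")
  expect_equal(s$compartments, "SimpleCircuit")
  expect_equal(s$name_pattern, "BBa_B0030")
  expect_false(s$include_subtypes)

  s <- parse_part_signature("Simple*.Promoter+")
  expect_equal(s$compartments, "Simple*")
  expect_true(s$include_subtypes)

  s <- parse_part_signature("!*.Terminator")
  expect_true(s$negated)

  s <- parse_part_signature("Promoter+()")
  expect_true(s$molecule_sig$require_none)

  s <- parse_part_signature("Part+(Protein+)")
  expect_true(s$molecule_sig$include_subtypes)
  expect_equal(s$molecule_sig$name_pattern, "Protein")

  expect_error(parse_part_signature("Promoter+(TetR"), "parenthes")
  expect_error(parse_part_signature(""), "empty")
  expect_error(parse_part_signature("A..B"), "malformed|invalid")
  expect_error(parse_part_signature("(TetR)"), "invalid|malformed|parenthes")
})

test_that("molecule signatures match on the type tree with wildcards", {
  reg <- new_registry()
  declare_molecule_type(reg, "GFP", "Protein")
  declare_molecule_type(reg, "TetR", "Protein")
  expect_true(match_molecule("Protein+", "GFP", reg))
  expect_false(match_molecule("Protein", "GFP", reg))
  expect_true(match_molecule("Ara", "Ara", new_registry() |>
                               (\(r) { declare_molecule_type(r, "Ara"); r })()))
  expect_true(match_molecule("T*", "TetR", reg))
  expect_false(match_molecule("T*", "GFP", reg))
})

test_that("the eight captioned signature cases select exactly the described parts", {
  fx <- sig_fixture()
  flow <- fx$flow
  sel <- function(sig) sort(match_expression(sig, flow)$name)

  # A: exact part within its compartment
  expect_equal(sel("SimpleCircuit.BBa_B0030"), "BBa_B0030")
  # B: all promoters and subtypes within Simple* compartments
  expect_equal(sel("Simple*.Promoter+"), "pTet")
  # C: promoters associated with a TetR molecule
  expect_equal(sel("Simple*.Promoter+(TetR)"), "pTet")
  # D: any part associated with TetR (regulation or coded product)
  expect_equal(sel("Simple*.Part+(TetR)"), sort(c("pTet", "cTetR")))
  # E: parts associated with any Protein-derived molecule
  expect_equal(sel("Part+(Protein+)"), sort(c("pTet", "cTetR")))
  # F: promoters with no associated molecule, on a constitutive circuit
  reg <- fx$reg
  const <- circuit("ConstCircuit") |>
    add_part(part(reg, "ConstitutivePromoter", "pConst")) |>
    add_part(part(reg, "RBS", "rbs1")) |>
    add_part(part(reg, "Terminator", "termC"))
  cflow <- linearize(const, reg)
  expect_equal(sort(match_expression("Promoter+()", cflow)$name), "pConst")
  # G: negation — everything that is not an unregulated terminator
  expect_equal(sort(match_expression("!*.Terminator()", cflow)$name),
               sort(c("pConst", "rbs1")))
  # H: %-chain returns the coding region connected to the RBS as context
  expect_equal(sel("BBa_B0030 % CodingRegion+"), "cTetR")
})

test_that("single-signature chains reduce to match_part and long chains return nothing", {
  fx <- sig_fixture()
  parts <- flow_parts(fx$flow)
  hits <- match_expression("Promoter+", fx$flow)$context_index
  direct <- which(vapply(seq_len(nrow(parts)), function(i) {
    match_part("Promoter+", fx$flow, i)
  }, logical(1)))
  expect_equal(hits, direct)
  long_chain <- paste(rep("Part+", nrow(parts) + 1L), collapse = " % ")
  expect_equal(nrow(match_expression(long_chain, fx$flow)), 0L)
})

test_that("matcher agrees with the brute-force oracle on 200 random circuits", {
  n_mismatch <- 0L
  for (seed in 1:200) {
    reg <- new_registry()
    cfg <- circuit_generator_config(seed)
    circ <- random_circuit(cfg, reg)
    flow <- linearize(circ, reg)
    parts <- flow_parts(flow)
    for (k in 1:3) {
      sig <- random_signature(cfg, circ, reg)
      for (i in seq_len(nrow(parts))) {
        got <- match_part(sig, flow, i, reg)
        want <- oracle_match_part(sig, parts, i, reg)
        if (!identical(got, want)) {
          n_mismatch <- n_mismatch + 1L
          cat("mismatch seed", seed, "sig", sig, "part", parts$name[[i]], "\n")
        }
      }
    }
  }
  expect_equal(n_mismatch, 0L)
})

test_that("negation complements the match set over the same flow", {
  for (seed in 1:25) {
    reg <- new_registry()
    cfg <- circuit_generator_config(seed + 1000)
    circ <- random_circuit(cfg, reg)
    flow <- linearize(circ, reg)
    parts <- flow_parts(flow)
    sig <- random_signature(cfg, circ, reg)
    sig <- sub("^!", "", sig)
    pos <- vapply(seq_len(nrow(parts)), function(i) match_part(sig, flow, i, reg),
                  logical(1))
    negd <- vapply(seq_len(nrow(parts)), function(i) {
      match_part(paste0("!", sig), flow, i, reg)
    }, logical(1))
    expect_identical(negd, !pos)
  }
})

test_that("wildcard star matches everything and its negation nothing", {
  fx <- sig_fixture()
  parts <- flow_parts(fx$flow)
  expect_equal(nrow(match_expression("*", fx$flow)), nrow(parts))
  expect_equal(nrow(match_expression("!*", fx$flow)), 0L)
})
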
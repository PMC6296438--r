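ensure_part_type <- function(reg, name, parent) {
  if (!name %in% names(reg$part)) declare_part_type(reg, name, parent)
  invisible(reg)
}

ensure_molecule_type <- function(reg, name, parent = "Molecule") {
  if (!name %in% names(reg$molecule)) declare_molecule_type(reg, name, parent)
  invisible(reg)
}

#' Built-in fixture circuits
#'
#' Constructs the worked-example circuits used throughout the package:
#'
#' * `"CodingGFP"` — a constitutive promoter followed by a GFP coding region
#'   (no RBS or terminator; those are supplied by [design_rules_aspect()]).
#' * `"InducedGFP"` — GFP expression gated by an arabinose-induced positive
#'   promoter (`PBad`, regulated by `Ara`).
#' * `"AbstractRepressilator"` — three genes in a ring, each negative promoter
#'   repressed by the previous gene's product (`TF1`..`TF3`).
#' * `"AndGate"` — an abstract two-input AND: two positive promoters drive two
#'   activator halves whose joint product activates a hybrid promoter.
#' * `"ToggleSwitch"` — two mutually repressing transcription factors `A` and
#'   `B`; an external `Inducer` additionally represses the `B` gene (the way
#'   IPTG inactivates a repressor), so adding it flips the switch to the
#'   high-`A` state.
#' * `"FeedbackOscillator"` — a positive/negative feedback oscillator: one
#'   hybrid promoter, activated by AraC and repressed by LacI, drives AraC,
#'   LacI and GFP.
#'
#' Any molecule and part types a fixture needs are declared in `reg` if not
#' already present.
#'
#' @param name Fixture name (see above).
#' @param reg A registry from [new_registry()].
#' @return A [circuit()].
#' @export
fixture_circuit <- function(name, reg) {
  switch(
    name,
    CodingGFP = {
      ensure_molecule_type(reg, "GFP", "Protein")
      circuit("CodingGFP") |>
        declare_molecule("GFP") |>
        add_part(part(reg, "ConstitutivePromoter", "pConst")) |>
        add_part(part(reg, "CodingRegion", "cGFP", codes_for = "GFP"))
    },
    InducedGFP = {
      ensure_molecule_type(reg, "GFP", "Protein")
      ensure_molecule_type(reg, "Ara")
      ensure_part_type(reg, "PBad", "PositivePromoter")
      circuit("InducedGFP") |>
        declare_molecule("Ara") |>
        declare_molecule("GFP") |>
        add_part(part(reg, "PBad", "PBad", regulated_by = "Ara")) |>
        add_part(part(reg, "CodingRegion", "cGFP", codes_for = "GFP"))
    },
    AbstractRepressilator = {
      for (m in c("TF1", "TF2", "TF3")) ensure_molecule_type(reg, m, "Protein")
      prev <- c("TF3", "TF1", "TF2")
      circ <- circuit("AbstractRepressilator")
      for (m in c("TF1", "TF2", "TF3")) circ <- declare_molecule(circ, m)
      for (i in 1:3) {
        circ <- circ |>
          add_part(part(reg, "NegativePromoter", paste0("P", i),
                        regulated_by = prev[[i]])) |>
          add_part(part(reg, "CodingRegion", paste0("cTF", i),
                        codes_for = paste0("TF", i)))
      }
      circ
    },
    AndGate = {
      for (m in c("SigA", "SigB")) ensure_molecule_type(reg, m)
      for (m in c("ActA", "ActB", "GFP")) ensure_molecule_type(reg, m, "Protein")
      circuit("AndGate") |>
        declare_molecule("SigA") |>
        declare_molecule("SigB") |>
        declare_molecule("ActA") |>
        declare_molecule("ActB") |>
        declare_molecule("GFP") |>
        add_part(part(reg, "PositivePromoter", "pInA", regulated_by = "SigA")) |>
        add_part(part(reg, "CodingRegion", "cActA", codes_for = "ActA")) |>
        add_part(part(reg, "Terminator", "tA")) |>
        add_part(part(reg, "PositivePromoter", "pInB", regulated_by = "SigB")) |>
        add_part(part(reg, "CodingRegion", "cActB", codes_for = "ActB")) |>
        add_part(part(reg, "Terminator", "tB")) |>
        add_part(part(reg, "Promoter", "pAnd", regulated_by = c("ActA", "ActB"),
                      signs = c("positive", "positive"))) |>
        add_part(part(reg, "CodingRegion", "cOut", codes_for = "GFP")) |>
        add_part(part(reg, "Terminator", "tOut"))
    },
    ToggleSwitch = {
      for (m in c("A", "B")) ensure_molecule_type(reg, m, "Protein")
      ensure_molecule_type(reg, "Inducer")
      circuit("ToggleSwitch") |>
        declare_molecule("A") |>
        declare_molecule("B") |>
        declare_molecule("Inducer") |>
        add_part(part(reg, "NegativePromoter", "pA", regulated_by = "B")) |>
        add_part(part(reg, "CodingRegion", "cA", codes_for = "A")) |>
        add_part(part(reg, "Terminator", "tA")) |>
        add_part(part(reg, "NegativePromoter", "pB",
                      regulated_by = c("A", "Inducer"))) |>
        add_part(part(reg, "CodingRegion", "cB", codes_for = "B")) |>
        add_part(part(reg, "Terminator", "tB"))
    },
    FeedbackOscillator = {
      for (m in c("AraC", "LacI", "GFP")) ensure_molecule_type(reg, m, "Protein")
      circ <- circuit("FeedbackOscillator")
      for (m in c("AraC", "LacI", "GFP")) circ <- declare_molecule(circ, m)
      genes <- c(AraC = "cAraC", LacI = "cLacI", GFP = "cGFP")
      for (i in seq_along(genes)) {
        circ <- circ |>
          add_part(part(reg, "Promoter", paste0("pHyb", i),
                        regulated_by = c("AraC", "LacI"),
                        signs = c("positive", "negative"))) |>
          add_part(part(reg, "CodingRegion", genes[[i]],
                        codes_for = names(genes)[[i]])) |>
          add_part(part(reg, "Terminator", paste0("t", i)))
      }
      circ
    },
    stop("unknown fixture circuit: '", name, "'", call. = FALSE)
  )
}

#' List the built-in fixture circuits
#' @return Character vector of fixture names accepted by [fixture_circuit()].
#' @export
fixture_names <- function() {
  c("CodingGFP", "InducedGFP", "AbstractRepressilator", "AndGate",
    "ToggleSwitch", "FeedbackOscillator")
}

#' The design-rules aspect
#'
#' Encodes the composition constraint that every coding region needs an
#' upstream ribosome binding site and a downstream terminator: a point cut
#' before every `CodingRegion+` inserts a generic RBS, one after inserts a
#' generic terminator. The aspect is deliberately not robust to designs that
#' already contain an RBS or terminator around the coding region — it will
#' duplicate them (a documented limitation of the simple rule).
#'
#' @return A [aspect()] named `"DesignRules"`.
#' @export
design_rules_aspect <- function() {
  aspect(
    "DesignRules",
    advice_list = list(
      advice(point_cut("CodingRegion+", "before"),
             function(ctx) part(ctx$registry, "RBS")),
      advice(point_cut("CodingRegion+", "after"),
             function(ctx) part(ctx$registry, "Terminator"))
    )
  )
}

#' The repressilation composition aspect
#'
#' Weaves an oscillation concern into a GFP reporter circuit, making the GFP
#' promoter depend on one of the oscillator's transcription factors:
#'
#' * if the promoter upstream of the (single) GFP coding region is
#'   constitutive, it is simply replaced by a positive promoter regulated by
#'   the oscillator factor;
#' * if it is an already-regulated positive promoter, replacing it would lose
#'   the inducer input, so an abstract AND gate is inserted instead: the
#'   original inducer and the oscillator factor each drive one activator
#'   half, and the joint halves activate a hybrid promoter that takes the
#'   original promoter's place.
#'
#' In both cases the oscillator's parts and molecules are appended to the
#' woven system after the reporter.
#'
#' @param output_circuit The reporter [circuit()]; must contain exactly one
#'   GFP coding region.
#' @param oscillator The oscillator circuit whose parts are appended (for
#'   example `fixture_circuit("AbstractRepressilator", reg)`).
#' @param reg The registry.
#' @param tf Oscillator transcription factor wired to the reporter; defaults
#'   to the first protein the oscillator codes for.
#' @return A [aspect()] named `"Repressilation"`.
#' @export
repressilation_aspect <- function(output_circuit, oscillator, reg, tf = NULL) {
  rep_flow <- flow_parts(linearize(output_circuit, reg))
  gfp_idx <- which(!is.na(rep_flow$codes_for) & rep_flow$codes_for == "GFP")
  if (length(gfp_idx) != 1L) {
    stop("repressilation target not found: reporter must contain exactly one ",
         "GFP coding region", call. = FALSE)
  }
  is_prom <- vapply(rep_flow$part_type, function(tp) {
    is_subtype(reg, tp, "Promoter", "part")
  }, logical(1))
  prom_idx <- max(which(is_prom & seq_len(nrow(rep_flow)) < gfp_idx), -Inf)
  if (!is.finite(prom_idx)) {
    stop("repressilation target not found: no promoter upstream of the GFP ",
         "coding region", call. = FALSE)
  }
  prom <- rep_flow[prom_idx, , drop = FALSE]
  constitutive <- is_subtype(reg, prom$part_type[[1]], "ConstitutivePromoter", "part") ||
    length(prom$regulation[[1]]) == 0
  positive <- is_subtype(reg, prom$part_type[[1]], "PositivePromoter", "part")
  if (!constitutive && !positive) {
    stop("repressilation target not found: promoter upstream of GFP is ",
         "neither constitutive nor a positive promoter (unsupported case)",
         call. = FALSE)
  }

  osc_flow <- flow_parts(linearize(oscillator, reg))
  osc_products <- osc_flow$codes_for[!is.na(osc_flow$codes_for)]
  if (is.null(tf)) tf <- osc_products[[1]]
  osc_molecules <- unique(unlist(lapply(seq_len(nrow(osc_flow)), function(i) {
    part_molecules(osc_flow$part[[i]])
  })))

  append_oscillator <- advice(
    point_cut(paste0(rep_flow$name[[gfp_idx]]), "after", priority = -1L),
    function(ctx) {
      c(lapply(osc_molecules, molecule_declaration), osc_flow$part)
    }
  )

  if (constitutive) {
    adv <- list(
      advice(point_cut(prom$name[[1]], "replace"), function(ctx) {
        list(molecule_declaration(tf),
             part(ctx$registry, "PositivePromoter", "pOsc", regulated_by = tf))
      }),
      append_oscillator
    )
  } else {
    ensure_molecule_type(reg, "AndActA", "Protein")
    ensure_molecule_type(reg, "AndActB", "Protein")
    adv <- list(
      # drive the two AND-gate activator halves from the original inducer(s)
      # and from the oscillator factor, upstream of the reporter promoter
      advice(point_cut(prom$name[[1]], "before"), function(ctx) {
        orig_reg <- ctx$part$regulation
        c(list(molecule_declaration(tf),
               molecule_declaration("AndActA"),
               molecule_declaration("AndActB"),
               part(ctx$registry, "PositivePromoter", "pAndIn",
                    regulated_by = vapply(orig_reg, `[[`, character(1), "molecule")),
               part(ctx$registry, "CodingRegion", "cAndActA", codes_for = "AndActA"),
               part(ctx$registry, "Terminator", "tAndA"),
               part(ctx$registry, "PositivePromoter", "pAndOsc", regulated_by = tf),
               part(ctx$registry, "CodingRegion", "cAndActB", codes_for = "AndActB"),
               part(ctx$registry, "Terminator", "tAndB")))
      }),
      advice(point_cut(prom$name[[1]], "replace"), function(ctx) {
        part(ctx$registry, "Promoter", "pAnd",
             regulated_by = c("AndActA", "AndActB"),
             signs = c("positive", "positive"))
      }),
      append_oscillator
    )
  }
  aspect("Repressilation", advice_list = adv)
}
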
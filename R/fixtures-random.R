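#' Configuration for the random-circuit generator
#'
#' The generator draws randomized but always-valid circuits used by the
#' oracle-equivalence and property tests: every draw contains at least one
#' promoter and one coding region, transcription units are well formed, all
#' referenced molecules are declared in scope, and regulation signs respect
#' the promoter type hierarchy.
#'
#' @param seed Integer seed; the same seed reproduces the same circuit.
#' @param max_parts Maximum number of parts (default 12).
#' @param n_molecules Number of molecule types to draw from (max 3).
#' @param n_part_types Number of extra custom part types (max 4).
#' @param p_regulated Probability that a promoter is regulated.
#' @param p_nested Probability of adding a nested sub-compartment.
#' @return A `cw_generator_config`.
#' @export
circuit_generator_config <- function(seed, max_parts = 12L, n_molecules = 3L,
                                     n_part_types = 4L, p_regulated = 0.5,
                                     p_nested = 0.3) {
  stopifnot(max_parts >= 2, n_molecules >= 1, n_molecules <= 3,
            n_part_types <= 4, p_regulated >= 0, p_regulated <= 1)
  structure(list(seed = as.integer(seed), max_parts = as.integer(max_parts),
                 n_molecules = as.integer(n_molecules),
                 n_part_types = as.integer(n_part_types),
                 p_regulated = p_regulated, p_nested = p_nested),
            class = "cw_generator_config")
}

#' Draw a random circuit
#'
#' @param cfg A [circuit_generator_config()].
#' @param reg A registry; custom types are declared into it.
#' @return A [circuit()] satisfying all structural invariants by
#'   construction.
#' @export
random_circuit <- function(cfg, reg = new_registry()) {
  stopifnot(inherits(cfg, "cw_generator_config"))
  set.seed(cfg$seed)
  mols <- paste0("Mol", seq_len(cfg$n_molecules))
  for (m in mols) ensure_molecule_type(reg, m, "Protein")
  base_types <- c("PositivePromoter", "NegativePromoter", "ConstitutivePromoter",
                  "RBS", "CodingRegion", "Terminator")
  custom <- character()
  if (cfg$n_part_types > 0) {
    for (i in seq_len(cfg$n_part_types)) {
      parent <- sample(base_types, 1)
      nm <- paste0("Cust", i, "_", parent)
      ensure_part_type(reg, nm, parent)
      custom <- c(custom, nm)
    }
  }
  n_parts <- sample(2:cfg$max_parts, 1)
  build_body <- function(circ, n, prefix) {
    i <- 0L
    repeat {
      if (i >= n) break
      # one transcription unit: promoter, coding region(s), maybe terminator
      ptype <- sample(c("PositivePromoter", "NegativePromoter",
                        "ConstitutivePromoter",
                        custom[grepl("Promoter", custom)]), 1)
      regd <- cfg$p_regulated > 0 && stats::runif(1) < cfg$p_regulated &&
        !is_subtype(reg, ptype, "ConstitutivePromoter", "part")
      regulators <- if (regd) sample(mols, sample(1:2, 1)) else NULL
      i <- i + 1L
      circ <- add_part(circ, part(reg, ptype, paste0(prefix, "p", i),
                                  regulated_by = regulators))
      n_cds <- min(sample(1:2, 1), n - i)
      for (k in seq_len(max(n_cds, 0))) {
        ctype <- sample(c("CodingRegion", custom[grepl("CodingRegion", custom)]), 1)
        i <- i + 1L
        circ <- add_part(circ, part(reg, ctype, paste0(prefix, "c", i),
                                    codes_for = sample(mols, 1)))
      }
      if (i < n && stats::runif(1) < 0.7) {
        ttype <- sample(c("Terminator", custom[grepl("Terminator", custom)]), 1)
        i <- i + 1L
        circ <- add_part(circ, part(reg, ttype, paste0(prefix, "t", i)))
      }
    }
    circ
  }
  root <- circuit("RandCircuit")
  for (m in mols) root <- declare_molecule(root, m)
  root <- build_body(root, n_parts, "r")
  if (stats::runif(1) < cfg$p_nested) {
    sub <- circuit("SubCompartment", permeable = TRUE)
    sub <- build_body(sub, sample(2:4, 1), "s")
    root <- add_subcircuit(root, sub)
  }
  # guarantee at least one promoter and one coding region
  parts <- flow_parts(linearize(root, reg))
  has_cds <- any(vapply(parts$part_type, function(tp) {
    is_subtype(reg, tp, "CodingRegion", "part")
  }, logical(1)))
  if (!has_cds) {
    root <- add_part(root, part(reg, "CodingRegion", "rc_extra",
                                codes_for = mols[[1]]))
  }
  root
}

#' Draw a random part signature
#'
#' Signatures are drawn from the full grammar — wildcards, subtype `+`,
#' negation `!`, empty `()`, molecule signatures and compartment prefixes —
#' biased towards names and types actually present in the circuit so that
#' matches are common.
#'
#' @param cfg A [circuit_generator_config()] (its seed stream is assumed
#'   already active; call after [random_circuit()] or set a seed).
#' @param circ The circuit the signature will be evaluated against.
#' @param reg The registry.
#' @return A signature string.
#' @export
random_signature <- function(cfg, circ, reg) {
  parts <- flow_parts(linearize(circ, reg))
  pool_names <- unique(c(parts$name, parts$part_type, names(reg$part)))
  nm <- sample(pool_names, 1)
  if (stats::runif(1) < 0.3 && nchar(nm) > 2) {
    cut <- sample(seq_len(nchar(nm) - 1), 1)
    nm <- paste0(substr(nm, 1, cut), "*")
  }
  if (stats::runif(1) < 0.4 && nm %in% names(reg$part)) nm <- paste0(nm, "+")
  if (stats::runif(1) < 0.3) {
    msig <- if (stats::runif(1) < 0.3) "" else {
      mol <- sample(names(reg$molecule), 1)
      if (stats::runif(1) < 0.5) paste0(mol, "+") else mol
    }
    nm <- paste0(nm, "(", msig, ")")
  }
  if (stats::runif(1) < 0.3) {
    comp <- sample(unique(vapply(parts$path, function(p) p[[length(p)]],
                                 character(1))), 1)
    if (stats::runif(1) < 0.3 && nchar(comp) > 2) {
      comp <- paste0(substr(comp, 1, 3), "*")
    }
    nm <- paste0(comp, ".", nm)
  }
  if (stats::runif(1) < 0.2) nm <- paste0("!", nm)
  nm
}
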
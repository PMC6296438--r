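# Independent brute-force oracles used by the property tests. These
# deliberately re-derive everything from first principles (string chopping,
# parent-pointer walks, explicit condition enumeration) rather than calling
# the package's parser/matcher internals.

# ancestor path by explicit parent-pointer walk
oracle_ancestry <- function(reg, name, kind) {
  tree <- reg[[kind]]
  out <- character()
  cur <- name
  repeat {
    out <- c(out, cur)
    nxt <- tree[[cur]]
    if (is.na(nxt)) break
    cur <- nxt
  }
  out
}

oracle_glob <- function(pattern, x) {
  rx <- paste0("^", gsub("\\*", ".*", gsub("([.\\\\+?^$(){}\\[\\]|])", "\\\\\\1",
                                           pattern)), "$")
  grepl(rx, x)
}

# explicit enumeration of the three signature conditions over one flow part
oracle_match_part <- function(sig_text, parts, i, reg) {
  s <- sig_text
  neg <- substr(s, 1, 1) == "!"
  if (neg) s <- substr(s, 2, nchar(s))
  molsig <- NULL
  if (grepl("\\(", s)) {
    molsig <- sub("^.*\\(([^()]*)\\)$", "\\1", s)
    s <- sub("\\([^()]*\\)$", "", s)
  }
  segs <- strsplit(s, ".", fixed = TRUE)[[1]]
  name <- segs[length(segs)]
  comps <- segs[-length(segs)]
  plus <- grepl("\\+$", name)
  if (plus) name <- sub("\\+$", "", name)

  path <- parts$path[[i]]
  cond_comp <- TRUE
  if (length(comps) > 0) {
    if (length(comps) > length(path)) {
      cond_comp <- FALSE
    } else {
      suffix <- path[(length(path) - length(comps) + 1):length(path)]
      cond_comp <- all(mapply(oracle_glob, comps, suffix))
    }
  }
  type_names <- if (plus) {
    oracle_ancestry(reg, parts$part_type[[i]], "part")
  } else {
    parts$part_type[[i]]
  }
  cond_name <- any(oracle_glob(name, c(parts$name[[i]], type_names)))
  cond_mol <- TRUE
  if (!is.null(molsig)) {
    assoc <- unique(c(
      vapply(parts$regulation[[i]], `[[`, character(1), "molecule"),
      if (!is.na(parts$codes_for[[i]])) parts$codes_for[[i]]
    ))
    if (molsig == "") {
      cond_mol <- length(assoc) == 0
    } else {
      mplus <- grepl("\\+$", molsig)
      mname <- sub("\\+$", "", molsig)
      cond_mol <- length(assoc) > 0 && any(vapply(assoc, function(m) {
        cand <- if (mplus) oracle_ancestry(reg, m, "molecule") else m
        any(oracle_glob(mname, cand))
      }, logical(1)))
    }
  }
  res <- cond_comp && cond_name && cond_mol
  if (neg) !res else res
}

# expected reaction counts for the protein-level mass-action strategy on a
# circuit whose regulated promoters carry exactly one regulator each
oracle_protein_counts <- function(map) {
  p <- sum(vapply(map$regulators, length, integer(1)) > 0)
  pairs <- sum(vapply(seq_len(nrow(map)), function(i) {
    length(map$products[[i]])
  }, integer(1)))
  prots <- unique(unlist(map$products))
  list(reactions = 2L * p + pairs + length(prots))
}

# tiny fixture: two coding regions driven by one constitutive promoter each
two_gene_circuit <- function(reg) {
  ensure <- function(m) if (!m %in% names(reg$molecule)) {
    declare_molecule_type(reg, m, "Protein")
  }
  ensure("ProtX"); ensure("ProtY")
  circuit("TwoGene") |>
    declare_molecule("ProtX") |>
    declare_molecule("ProtY") |>
    add_part(part(reg, "ConstitutivePromoter", "px")) |>
    add_part(part(reg, "CodingRegion", "cx", codes_for = "ProtX")) |>
    add_part(part(reg, "ConstitutivePromoter", "py")) |>
    add_part(part(reg, "CodingRegion", "cy", codes_for = "ProtY"))
}

# random repressor-only circuit for rule-model property tests: each gene is a
# (promoter, coding region, terminator) unit, promoters constitutive or
# repressed by one molecule
random_repressor_circuit <- function(seed, reg) {
  set.seed(seed)
  n_genes <- sample(1:3, 1)
  mols <- paste0("RMol", seq_len(3))
  for (m in mols) if (!m %in% names(reg$molecule)) {
    declare_molecule_type(reg, m, "Protein")
  }
  circ <- circuit(paste0("RepCirc", seed))
  for (m in mols) circ <- declare_molecule(circ, m)
  products <- sample(mols, n_genes)  # distinct product per gene
  for (g in seq_len(n_genes)) {
    regulated <- stats::runif(1) < 0.5
    prom <- if (regulated) {
      part(reg, "NegativePromoter", paste0("rp", g),
           regulated_by = sample(mols, 1))
    } else {
      part(reg, "ConstitutivePromoter", paste0("rp", g))
    }
    circ <- circ |>
      add_part(prom) |>
      add_part(part(reg, "CodingRegion", paste0("rc", g),
                    codes_for = products[[g]])) |>
      add_part(part(reg, "Terminator", paste0("rt", g)))
  }
  circ
}

# one-species birth-death model built by hand (k_b, k_d in 1/min)
birth_death_model <- function(k_b = 1, k_d = 0.1) {
  m <- circuitweaver:::empty_model("manual")
  m <- circuitweaver:::add_species(m, "Npart", "protein", 0)
  m <- circuitweaver:::add_reaction(m, "birth", stats::setNames(numeric(), character()),
                                    c(Npart = 1), "k_b", k_b, "expression")
  m <- circuitweaver:::add_reaction(m, "death", c(Npart = 1),
                                    stats::setNames(numeric(), character()),
                                    "k_d", k_d, "degradation_protein")
  m
}
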
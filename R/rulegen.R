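#' Generate a rule-based model from a woven circuit
#'
#' Builds an agent/site rule model of the transcriptional circuit: each
#' promoter is an agent with an operator site `op`, each repressor protein an
#' agent with a DNA-binding site `dna`, each mRNA and non-binding protein a
#' plain agent. Per gene, rules are instantiated in up to six categories —
#' repressor binding/unbinding at the operator, transcription from the free
#' promoter, translation, mRNA degradation and degradation of the free
#' protein (a promoter-bound repressor must unbind before it can degrade).
#' Activator-regulated promoters are not supported by this rule schema.
#'
#' The instantiated-rule count is `4 * genes + 2 * regulated promoters`.
#'
#' @param woven A `cw_woven` (or `cw_flow`) containing at least one
#'   transcription unit.
#' @param params Named numeric overrides for rule rate constants (same naming
#'   scheme as the mass-action reaction parameters, count units).
#' @param copies Promoter copy number per cell (initial count).
#' @return A `cw_rule_model` with fields `agents`, `rules`, `init`,
#'   `observables`.
#' @export
generate_rules <- function(woven, params = numeric(), copies = 1L) {
  map <- build_regulation_map(woven)
  if (nrow(map) == 0) {
    stop("rule generation requires at least one transcription unit", call. = FALSE)
  }
  for (regs in map$regulators) {
    signs <- vapply(regs, `[[`, character(1), "sign")
    if (any(signs == "positive")) {
      stop("unsupported feature: activator-regulated promoters are not ",
           "supported by the rule-based modelling aspect", call. = FALSE)
    }
  }
  agents <- tibble::tibble(name = character(), sites = list())
  rules <- tibble::tibble(label = character(), lhs = character(),
                          rhs = character(), rate_name = character(),
                          rate = numeric(), category = character())
  init <- numeric()
  binders <- unique(unlist(lapply(map$regulators, function(rs) {
    vapply(rs, `[[`, character(1), "molecule")
  }))) %||% character()
  add_agent <- function(name, sites) {
    if (!name %in% agents$name) {
      agents <<- dplyr::bind_rows(agents,
        tibble::tibble(name = name, sites = list(sites)))
    }
  }
  add_rule <- function(label, lhs, rhs, rate_name, default, category) {
    rate <- param_or(params, rate_name, default)
    rules <<- dplyr::bind_rows(rules, tibble::tibble(
      label = label, lhs = lhs, rhs = rhs, rate_name = rate_name,
      rate = rate, category = category))
  }
  for (i in seq_len(nrow(map))) {
    prom <- sanitize_id(map$promoter[[i]])
    pa <- paste0("p", prom)
    regs <- vapply(map$regulators[[i]], `[[`, character(1), "molecule")
    add_agent(pa, if (length(regs) > 0) "op" else character())
    init[[paste0(pa, if (length(regs) > 0) "(op[.])" else "()")]] <- copies
    for (m in sanitize_id(regs)) {
      add_agent(m, "dna")
      kb <- paste0("k_bind_", prom, "_", m)
      ku <- paste0("k_unbind_", prom, "_", m)
      add_rule(paste0(prom, ".bind.", m),
               paste0(pa, "(op[.]), ", m, "(dna[.])"),
               paste0(pa, "(op[1]), ", m, "(dna[1])"),
               kb, default_rate("binding"), "BIND")
      add_rule(paste0(prom, ".unbind.", m),
               paste0(pa, "(op[1]), ", m, "(dna[1])"),
               paste0(pa, "(op[.]), ", m, "(dna[.])"),
               ku, default_rate("unbinding"), "UNBIND")
    }
    psite <- if (length(regs) > 0) "(op[.])" else "()"
    for (pr in sanitize_id(map$products[[i]])) {
      mr <- paste0("mRNA_", pr)
      add_agent(mr, character())
      if (!pr %in% agents$name) {
        add_agent(pr, if (pr %in% sanitize_id(binders)) "dna" else character())
      }
      kt <- paste0("k_tx_", prom, "_", pr)
      add_rule(paste0(prom, ".transcribe.", pr),
               paste0(pa, psite),
               paste0(pa, psite, ", ", mr, "()"),
               kt, default_rate("transcription"), "TRANSCRIBE")
      kl <- paste0("k_tl_", pr)
      add_rule(paste0(pr, ".translate"),
               paste0(mr, "()"),
               paste0(mr, "(), ", pr,
                      if (pr %in% sanitize_id(binders)) "(dna[.])" else "()"),
               kl, default_rate("translation"), "TRANSLATE")
      kdm <- paste0("k_degm_", pr)
      add_rule(paste0(pr, ".degrade_mrna"), paste0(mr, "()"), ".",
               kdm, default_rate("degradation_rna"), "DEGRADE_RNA")
      kd <- paste0("k_deg_", pr)
      free <- if (pr %in% sanitize_id(binders)) "(dna[.])" else "()"
      add_rule(paste0(pr, ".degrade"), paste0(pr, free), ".",
               kd, default_rate("degradation_protein"), "DEGRADE_PROTEIN")
    }
  }
  dup <- duplicated(rules$label)
  rules <- rules[!dup, , drop = FALSE]
  obs <- unique(sanitize_id(unlist(map$products))) %||% character()
  structure(list(agents = agents, rules = rules, init = init,
                 observables = obs),
            class = "cw_rule_model")
}

#' @export
print.cw_rule_model <- function(x, ...) {
  cat("<cw_rule_model> ", nrow(x$agents), " agents, ", nrow(x$rules),
      " rules (", paste(sort(unique(x$rules$category)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Export a rule model to Kappa text
#'
#' Writes the model in a Kappa dialect: `%agent:` signatures, labelled rules
#' with rates, `%init:` counts and `%obs:` observables, in deterministic
#' order so identical models export byte-identically.
#'
#' @param model A `cw_rule_model`.
#' @param file Optional path.
#' @return Character vector of lines; invisibly when `file` is given.
#' @export
export_kappa <- function(model, file = NULL) {
  stopifnot(inherits(model, "cw_rule_model"))
  lines <- "// rule-based model (Kappa dialect), generated by circuitweaver"
  for (i in seq_len(nrow(model$agents))) {
    sites <- model$agents$sites[[i]]
    lines <- c(lines, sprintf("%%agent: %s(%s)", model$agents$name[[i]],
                              paste(sites, collapse = ",")))
  }
  for (i in seq_len(nrow(model$rules))) {
    r <- model$rules[i, ]
    lines <- c(lines, sprintf("'%s' %s -> %s @ %g",
                              r$label, r$lhs, r$rhs, r$rate))
  }
  for (nm in names(model$init)) {
    lines <- c(lines, sprintf("%%init: %g %s", model$init[[nm]], nm))
  }
  for (ob in model$observables) {
    lines <- c(lines, sprintf("%%obs: '%s' |%s()|", ob, ob))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse Kappa-dialect text
#'
#' A parser for the dialect emitted by [export_kappa()]: checks agent
#' signatures, rule syntax (label, pattern arrow, rate), bond/site notation,
#' that every agent used in a rule, init or observable is declared, and that
#' bond labels pair up within each pattern. Returns the parsed structure so
#' exported files can be round-tripped and simulated.
#'
#' @param lines Character vector of Kappa lines (or a file path of length 1
#'   pointing to an existing file).
#' @return A list with `agents`, `rules`, `init`, `observables`.
#' @export
parse_kappa <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  agents <- list()
  rules <- list()
  init <- numeric()
  obs <- character()
  agent_rx <- "^%agent:\\s*([A-Za-z0-9_]+)\\(([A-Za-z0-9_,]*)\\)\\s*$"
  rule_rx <- "^'([^']+)'\\s+(.*?)\\s*->\\s*(.*?)\\s*@\\s*([-0-9.eE+]+)\\s*$"
  init_rx <- "^%init:\\s*([0-9.eE+-]+)\\s+(.*)$"
  obs_rx <- "^%obs:\\s*'([^']+)'\\s*\\|(.*)\\|\\s*$"
  pat_agent_rx <- "^([A-Za-z0-9_]+)\\((([A-Za-z0-9_]+\\[(\\.|[0-9]+)\\])?(,[A-Za-z0-9_]+\\[(\\.|[0-9]+)\\])*)\\)$"
  check_pattern <- function(pat, where) {
    if (identical(trimws(pat), ".")) return(invisible())
    toks <- strsplit(pat, "\\),\\s*")[[1]]
    toks <- ifelse(endsWith(toks, ")"), toks, paste0(toks, ")"))
    bonds <- integer()
    for (tk in toks) {
      m <- regmatches(tk, regexec(pat_agent_rx, tk))[[1]]
      if (length(m) == 0) {
        stop("Kappa parse error in ", where, ": bad agent pattern '", tk, "'",
             call. = FALSE)
      }
      if (!m[[2]] %in% names(agents)) {
        stop("Kappa parse error in ", where, ": undeclared agent '", m[[2]],
             "'", call. = FALSE)
      }
      ids <- regmatches(tk, gregexpr("\\[[0-9]+\\]", tk))[[1]]
      bonds <- c(bonds, as.integer(gsub("[^0-9]", "", ids)))
    }
    if (length(bonds) > 0 && any(table(bonds) != 2)) {
      stop("Kappa parse error in ", where, ": unpaired bond label", call. = FALSE)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "//")) next
    if (grepl(agent_rx, ln)) {
      m <- regmatches(ln, regexec(agent_rx, ln))[[1]]
      sites <- strsplit(m[[3]], ",", fixed = TRUE)[[1]]
      agents[[m[[2]]]] <- sites[nzchar(sites)]
    } else if (grepl(rule_rx, ln)) {
      m <- regmatches(ln, regexec(rule_rx, ln))[[1]]
      check_pattern(m[[3]], paste0("rule '", m[[2]], "' (lhs)"))
      check_pattern(m[[4]], paste0("rule '", m[[2]], "' (rhs)"))
      rules[[length(rules) + 1L]] <- list(label = m[[2]], lhs = m[[3]],
                                          rhs = m[[4]],
                                          rate = as.numeric(m[[5]]))
    } else if (grepl(init_rx, ln)) {
      m <- regmatches(ln, regexec(init_rx, ln))[[1]]
      check_pattern(m[[3]], "%init")
      init[[m[[3]]]] <- as.numeric(m[[2]])
    } else if (grepl(obs_rx, ln)) {
      m <- regmatches(ln, regexec(obs_rx, ln))[[1]]
      check_pattern(m[[3]], "%obs")
      obs <- c(obs, m[[2]])
    } else {
      stop("Kappa parse error: unrecognized line '", ln, "'", call. = FALSE)
    }
  }
  list(agents = agents, rules = rules, init = init, observables = obs)
}

#' Ground a rule model into a reaction network
#'
#' The emitted rule schema has no polymerisation, so every rule grounds to a
#' single mass-action reaction over a finite species set: a free and a bound
#' state per regulated promoter, one species per mRNA, and free-protein
#' counts. Used to simulate rule models with the stochastic engine.
#'
#' @param model A `cw_rule_model`.
#' @return A `cw_reaction_model` in count units.
#' @export
rule_model_to_reactions <- function(model) {
  stopifnot(inherits(model, "cw_rule_model"))
  out <- empty_model("rule_ground")
  promoter_of <- function(lhs) sub("\\(.*$", "", strsplit(lhs, ",")[[1]][[1]])
  for (i in seq_len(nrow(model$rules))) {
    r <- model$rules[i, ]
    ags <- function(pat) {
      if (identical(trimws(pat), ".")) return(character())
      vapply(strsplit(pat, "\\),\\s*")[[1]], function(tk) sub("\\(.*$", "", tk),
             character(1), USE.NAMES = FALSE)
    }
    lhs_ag <- ags(r$lhs); rhs_ag <- ags(r$rhs)
    bound_name <- function(p, m) paste0(p, "_", m, "_bound")
    species_for <- switch(r$category,
      BIND = {
        p <- lhs_ag[[1]]; m <- lhs_ag[[2]]
        list(re = stats::setNames(c(1, 1), c(paste0(p, "_free"), m)),
             pr = stats::setNames(1, bound_name(p, m)))
      },
      UNBIND = {
        p <- lhs_ag[[1]]; m <- lhs_ag[[2]]
        list(re = stats::setNames(1, bound_name(p, m)),
             pr = stats::setNames(c(1, 1), c(paste0(p, "_free"), m)))
      },
      TRANSCRIBE = {
        p <- lhs_ag[[1]]; mr <- setdiff(rhs_ag, lhs_ag)
        list(re = stats::setNames(1, paste0(p, "_free")),
             pr = stats::setNames(c(1, 1), c(paste0(p, "_free"), mr)))
      },
      TRANSLATE = {
        mr <- lhs_ag[[1]]; pr <- setdiff(rhs_ag, lhs_ag)
        list(re = stats::setNames(1, mr),
             pr = stats::setNames(c(1, 1), c(mr, pr)))
      },
      DEGRADE_RNA = ,
      DEGRADE_PROTEIN = {
        list(re = stats::setNames(1, lhs_ag[[1]]),
             pr = stats::setNames(numeric(), character()))
      },
      stop("unknown rule category: ", r$category, call. = FALSE))
    for (s in names(species_for$re)) {
      role <- if (grepl("_free$|_bound$", s)) "promoter_state"
        else if (startsWith(s, "mRNA_")) "mRNA" else "protein"
      out <- add_species(out, s, role, 0)
    }
    for (s in names(species_for$pr)) {
      role <- if (grepl("_free$|_bound$", s)) "promoter_state"
        else if (startsWith(s, "mRNA_")) "mRNA" else "protein"
      out <- add_species(out, s, role, 0)
    }
    out <- add_reaction(out, r$label, species_for$re, species_for$pr,
                        r$rate_name, r$rate, r$category)
  }
  # initial promoter copies
  for (nm in names(model$init)) {
    ag <- sub("\\(.*$", "", nm)
    target <- paste0(ag, "_free")
    if (!target %in% out$species$name) target <- ag
    out$species$initial[out$species$name == target] <- model$init[[nm]]
  }
  out
}
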
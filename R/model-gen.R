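sanitize_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Build the promoter/coding-region regulation map
#'
#' Walks the woven execution flow and maps every coding region to its driving
#' promoter: the nearest preceding promoter in the same compartment with no
#' intervening terminator (so a promoter drives all coding regions up to the
#' next terminator — operons are supported). Regulatory links of each
#' promoter are carried along. A coding region with no upstream promoter is a
#' structural error.
#'
#' @param woven A `cw_woven` from [weave()], or a `cw_flow`.
#' @return A tibble of class `cw_regulation_map`, one row per promoter:
#'   `promoter`, `promoter_type`, `regulators` (list of
#'   `list(molecule, sign)`), `products` (character vector of coded
#'   molecules, flow order). The set of inducer molecules (regulators never
#'   coded by the system) is attached as attribute `inducers`.
#' @export
build_regulation_map <- function(woven) {
  flow <- if (inherits(woven, "cw_woven")) woven$flow else woven
  reg <- if (inherits(woven, "cw_woven")) woven$registry else attr(flow, "registry")
  parts <- flow_parts(flow)
  rows <- list()
  current <- 0L
  current_path <- NULL
  for (i in seq_len(nrow(parts))) {
    tp <- parts$part_type[[i]]
    if (!is.null(current_path) && !identical(parts$path[[i]], current_path)) {
      current <- 0L
    }
    current_path <- parts$path[[i]]
    if (is_subtype(reg, tp, "Promoter", "part")) {
      rows[[length(rows) + 1L]] <- list(
        promoter = parts$name[[i]], promoter_type = tp,
        regulators = parts$regulation[[i]], products = character()
      )
      current <- length(rows)
    } else if (is_subtype(reg, tp, "Terminator", "part")) {
      current <- 0L
    } else if (is_subtype(reg, tp, "CodingRegion", "part")) {
      if (current == 0L) {
        stop("orphan coding region '", parts$name[[i]],
             "': no upstream promoter in its transcription unit", call. = FALSE)
      }
      rows[[current]]$products <- c(rows[[current]]$products,
                                    parts$codes_for[[i]])
    }
  }
  map <- tibble::tibble(
    promoter = vapply(rows, `[[`, character(1), "promoter"),
    promoter_type = vapply(rows, `[[`, character(1), "promoter_type"),
    regulators = lapply(rows, `[[`, "regulators"),
    products = lapply(rows, `[[`, "products")
  )
  products <- unique(unlist(map$products)) %||% character()
  regulators <- unique(unlist(lapply(map$regulators, function(rs) {
    vapply(rs, `[[`, character(1), "molecule")
  }))) %||% character()
  attr(map, "inducers") <- setdiff(regulators, products)
  class(map) <- c("cw_regulation_map", class(map))
  map
}

default_rate <- function(category) {
  switch(category,
    binding = 1, unbinding = 1,
    expression = 2, transcription = 2, translation = 4,
    degradation_protein = 0.05, degradation_rna = 0.3,
    1
  )
}

empty_model <- function(strategy) {
  structure(
    list(
      species = tibble::tibble(name = character(), role = character(),
                               initial = numeric()),
      reactions = tibble::tibble(name = character(), reactants = list(),
                                 products = list(), rate_law = character(),
                                 parameter = character(), category = character(),
                                 mass_action = logical()),
      parameters = numeric(), observables = list(), strategy = strategy
    ),
    class = "cw_reaction_model"
  )
}

add_species <- function(model, name, role, initial = 0) {
  if (!name %in% model$species$name) {
    model$species <- dplyr::bind_rows(
      model$species, tibble::tibble(name = name, role = role, initial = initial))
  }
  model
}

add_reaction <- function(model, name, reactants, products, parameter,
                         value, category, rate_law = NULL) {
  mass_action <- is.null(rate_law)
  if (mass_action) {
    terms <- c(parameter, rep(names(reactants), unlist(reactants)))
    rate_law <- paste(terms, collapse = " * ")
  }
  if (name %in% model$reactions$name) {
    stop("duplicate reaction name: '", name, "'", call. = FALSE)
  }
  if (parameter %in% names(model$parameters) &&
      model$parameters[[parameter]] != value) {
    stop("parameter '", parameter, "' redefined with a different value",
         call. = FALSE)
  }
  model$parameters[[parameter]] <- value
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    tibble::tibble(name = name, reactants = list(reactants),
                   products = list(products), rate_law = rate_law,
                   parameter = parameter, category = category,
                   mass_action = mass_action))
  model
}

param_or <- function(params, name, default) {
  if (name %in% names(params)) params[[name]] else default
}

#' Generate a reaction-network model from a regulation map
#'
#' Three kinetic strategies are available:
#'
#' * `"mass_action_protein"` — protein-level mass action. Each regulated
#'   promoter gets a reversible regulator-binding pair (written as two
#'   irreversible reactions); expression produces protein directly from the
#'   active promoter state (the free state for repressed promoters, each
#'   bound state for activated ones); every coded protein degrades.
#' * `"mass_action_rna"` — as above, with expression split into transcription
#'   (mRNA synthesis from the active promoter state) and translation, plus
#'   mRNA degradation.
#' * `"shea_ackers_rna"` — no explicit promoter-state species; each
#'   promoter's transcription rate is the statistical-thermodynamic occupancy
#'   ratio `k_tx (a0 + sum_i a_i K_i [A_i]^n) / (1 + sum_i K_i [A_i]^n +
#'   sum_j K_j [R_j]^n)` over activators `A` and repressors `R`, with
#'   cooperativity `n` (default 2); translation and both degradations as in
#'   the RNA mass-action strategy.
#'
#' One rate parameter is defined per mass-action reaction and rates follow
#' the law of mass action; Shea-Ackers transcription additionally introduces
#' the association constants `K_*`, activated rates `a_*`, basal weights
#' `a0_*` (1 for repressor-only promoters, 0 otherwise, unless overridden)
#' and the shared Hill exponent `n_hill`. Default parameter values come from
#' a shipped set so that every generated model simulates out of the box;
#' override any of them via `params`.
#'
#' @param map A [build_regulation_map()] result.
#' @param strategy One of the three strategy names above.
#' @param params Named numeric overrides for auto-named parameters.
#' @param options List: `hill_n` (default 2), `alpha0` (named per-promoter
#'   basal weights), `promoter_copies` (initial promoter count, default 1).
#' @return An object of class `cw_reaction_model` with fields `species`,
#'   `reactions`, `parameters`, `observables`, `strategy`.
#' @export
generate_model <- function(map, strategy = c("mass_action_protein",
                                             "mass_action_rna",
                                             "shea_ackers_rna"),
                           params = numeric(), options = list()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(map, "cw_regulation_map"))
  model <- empty_model(strategy)
  hill_n <- options$hill_n %||% 2
  copies <- options$promoter_copies %||% 1

  inducers <- attr(map, "inducers")
  products <- unique(unlist(map$products)) %||% character()
  explicit_promoters <- strategy != "shea_ackers_rna"

  for (i in seq_len(nrow(map))) {
    prom <- sanitize_id(map$promoter[[i]])
    regs <- map$regulators[[i]]
    prods <- map$products[[i]]
    reg_mols <- vapply(regs, `[[`, character(1), "molecule")
    reg_signs <- vapply(regs, `[[`, character(1), "sign")

    if (explicit_promoters) {
      free_sp <- paste0(prom, "_free")
      model <- add_species(model, free_sp, "promoter_state", copies)
      bound_sps <- character()
      for (j in seq_along(regs)) {
        m <- sanitize_id(reg_mols[[j]])
        bound <- paste0(prom, "_", m)
        bound_sps <- c(bound_sps, bound)
        model <- add_species(model, bound, "promoter_state", 0)
        role <- if (reg_mols[[j]] %in% inducers) "inducer" else "protein"
        model <- add_species(model, m, role, 0)
        kb <- paste0("k_bind_", prom, "_", m)
        ku <- paste0("k_unbind_", prom, "_", m)
        model <- add_reaction(model, paste0("bind_", prom, "_", m),
                              stats::setNames(c(1, 1), c(free_sp, m)),
                              stats::setNames(1, bound),
                              kb, param_or(params, kb, default_rate("binding")),
                              "binding")
        model <- add_reaction(model, paste0("unbind_", prom, "_", m),
                              stats::setNames(1, bound),
                              stats::setNames(c(1, 1), c(free_sp, m)),
                              ku, param_or(params, ku, default_rate("unbinding")),
                              "unbinding")
      }
      # active states: free for repressor-regulated (and constitutive)
      # promoters, each activator-bound state for activated promoters
      active <- if (length(regs) == 0 || all(reg_signs == "negative")) {
        free_sp
      } else {
        bound_sps[reg_signs == "positive"]
      }
      for (pr in prods) {
        prs <- sanitize_id(pr)
        model <- add_species(model, prs, "protein", 0)
        for (act in active) {
          if (strategy == "mass_action_protein") {
            kp <- paste0("k_expr_", act, "_", prs)
            model <- add_reaction(model, paste0("expr_", act, "_", prs),
                                  stats::setNames(1, act),
                                  stats::setNames(c(1, 1), c(act, prs)),
                                  kp, param_or(params, kp, default_rate("expression")),
                                  "expression")
          } else {
            mr <- paste0("mRNA_", prs)
            model <- add_species(model, mr, "mRNA", 0)
            kt <- paste0("k_tx_", act, "_", prs)
            model <- add_reaction(model, paste0("tx_", act, "_", prs),
                                  stats::setNames(1, act),
                                  stats::setNames(c(1, 1), c(act, mr)),
                                  kt, param_or(params, kt, default_rate("transcription")),
                                  "transcription")
          }
        }
      }
    } else {
      # Shea-Ackers: occupancy-ratio transcription, no binding species
      for (j in seq_along(regs)) {
        m <- sanitize_id(reg_mols[[j]])
        role <- if (reg_mols[[j]] %in% inducers) "inducer" else "protein"
        model <- add_species(model, m, role, 0)
      }
      act_idx <- which(reg_signs == "positive")
      rep_idx <- which(reg_signs == "negative")
      a0_default <- if (length(act_idx) == 0) 1 else 0
      a0_name <- paste0("a0_", prom)
      alpha0 <- (options$alpha0 %||% numeric())[prom] %||% NA
      a0_val <- if (!is.na(alpha0)) alpha0 else
        param_or(params, a0_name, a0_default)
      model$parameters[[a0_name]] <- a0_val
      model$parameters[["n_hill"]] <- param_or(params, "n_hill", hill_n)
      num <- a0_name
      den <- "1"
      for (j in act_idx) {
        m <- sanitize_id(reg_mols[[j]])
        Kn <- paste0("K_", prom, "_", m)
        an <- paste0("a_", prom, "_", m)
        model$parameters[[Kn]] <- param_or(params, Kn, 1)
        model$parameters[[an]] <- param_or(params, an, 10)
        term <- paste0(Kn, " * ", m, "^n_hill")
        num <- paste0(num, " + ", an, " * ", term)
        den <- paste0(den, " + ", term)
      }
      for (j in rep_idx) {
        m <- sanitize_id(reg_mols[[j]])
        Kn <- paste0("K_", prom, "_", m)
        model$parameters[[Kn]] <- param_or(params, Kn, 1)
        den <- paste0(den, " + ", Kn, " * ", m, "^n_hill")
      }
      for (pr in prods) {
        prs <- sanitize_id(pr)
        mr <- paste0("mRNA_", prs)
        model <- add_species(model, prs, "protein", 0)
        model <- add_species(model, mr, "mRNA", 0)
        kt <- paste0("k_tx_", prom, "_", prs)
        law <- paste0(kt, " * (", num, ") / (", den, ")")
        model <- add_reaction(model, paste0("tx_", prom, "_", prs),
                              stats::setNames(numeric(), character()),
                              stats::setNames(1, mr),
                              kt, param_or(params, kt, default_rate("transcription")),
                              "transcription", rate_law = law)
      }
    }
  }

  if (strategy != "mass_action_protein") {
    for (pr in unique(sanitize_id(products))) {
      mr <- paste0("mRNA_", pr)
      if (!mr %in% model$species$name) next
      kl <- paste0("k_tl_", pr)
      model <- add_reaction(model, paste0("tl_", pr),
                            stats::setNames(1, mr),
                            stats::setNames(c(1, 1), c(mr, pr)),
                            kl, param_or(params, kl, default_rate("translation")),
                            "translation")
      kdm <- paste0("k_degm_", pr)
      model <- add_reaction(model, paste0("degm_", pr),
                            stats::setNames(1, mr),
                            stats::setNames(numeric(), character()),
                            kdm, param_or(params, kdm, default_rate("degradation_rna")),
                            "degradation_rna")
    }
  }
  for (pr in unique(sanitize_id(products))) {
    kd <- paste0("k_deg_", pr)
    model <- add_reaction(model, paste0("deg_", pr),
                          stats::setNames(1, pr),
                          stats::setNames(numeric(), character()),
                          kd, param_or(params, kd, default_rate("degradation_protein")),
                          "degradation_protein")
  }
  model
}

#' Stoichiometry matrix of a reaction model
#'
#' @param model A `cw_reaction_model`.
#' @return Integer matrix, species in rows and reactions in columns; each
#'   column is products minus reactants of that reaction.
#' @export
stoichiometry <- function(model) {
  sp <- model$species$name
  S <- matrix(0L, nrow = length(sp), ncol = nrow(model$reactions),
              dimnames = list(sp, model$reactions$name))
  for (j in seq_len(nrow(model$reactions))) {
    re <- model$reactions$reactants[[j]]
    pr <- model$reactions$products[[j]]
    for (s in names(re)) S[s, j] <- S[s, j] - re[[s]]
    for (s in names(pr)) S[s, j] <- S[s, j] + pr[[s]]
  }
  S
}

format_side <- function(x) {
  if (length(x) == 0) return("0")
  paste(ifelse(unlist(x) == 1, names(x),
               paste0(unlist(x), " ", names(x))), collapse = " + ")
}

#' Plain-text reaction listing
#'
#' One reaction per line with its rate law and parameter value.
#'
#' @param model A `cw_reaction_model`.
#' @param file Optional path; when given the text is also written there.
#' @return The listing as a character vector of lines, invisibly when `file`
#'   is given.
#' @export
print_reactions <- function(model, file = NULL) {
  lines <- vapply(seq_len(nrow(model$reactions)), function(j) {
    r <- model$reactions[j, ]
    sprintf("%s: %s -> %s  @ %s  [%s = %g]",
            r$name, format_side(r$reactants[[1]]), format_side(r$products[[1]]),
            r$rate_law, r$parameter, model$parameters[[r$parameter]])
  }, character(1))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @export
print.cw_reaction_model <- function(x, ...) {
  cat("<cw_reaction_model> strategy=", x$strategy, ": ",
      nrow(x$species), " species, ", nrow(x$reactions), " reactions, ",
      length(x$parameters), " parameters\n", sep = "")
  invisible(x)
}
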
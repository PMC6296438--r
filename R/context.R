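#' Host-growth context
#'
#' Describes the cross-cutting concern of a reproducing bacterial population
#' into which a core circuit model is placed. Three kinds are supported:
#' exponential growth, logistic growth, and "lag-logistic" growth — a viable
#' logistic population plus a dying, non-viable subpopulation that decays
#' exponentially, producing the initial dip seen in optical-density curves.
#'
#' @param kind `"exponential"`, `"logistic"` or `"lag_logistic"`.
#' @param mu Maximum specific growth rate (1/min); > 0.
#' @param K Carrying capacity (population units); > 0 (ignored for
#'   exponential growth).
#' @param d Death rate of the non-viable subpopulation (1/min);
#'   lag-logistic only.
#' @param N0 Initial viable population.
#' @param N0_dead Initial non-viable population (lag-logistic only).
#' @return A `cw_growth_context`.
#' @export
growth_context <- function(kind = c("exponential", "logistic", "lag_logistic"),
                           mu, K = 1, d = 0, N0 = 0.01, N0_dead = 0) {
  kind <- match.arg(kind)
  stopifnot(mu >= 0, K > 0, d >= 0, N0 >= 0, N0_dead >= 0)
  if (kind == "lag_logistic" && d <= 0) {
    stop("lag-logistic growth requires a positive death rate `d`", call. = FALSE)
  }
  structure(list(kind = kind, mu = mu, K = K, d = d, N0 = N0,
                 N0_dead = N0_dead),
            class = "cw_growth_context")
}

#' Place a core model into a growth context
#'
#' Adds a population species `N` (and `N_dead` for lag-logistic growth) with
#' dynamics `dN/dt = mu N` (exponential), `mu N (1 - N/K)` (logistic, and the
#' viable subpopulation of lag-logistic growth, with `dN_dead/dt = -d
#' N_dead`), plus dilution of every intracellular species at the
#' instantaneous per-capita growth rate. Promoter-state species are not
#' diluted by default (DNA copy number per cell is assumed constant).
#' Observables `total_fluorescence = [GFP] * N` and `OD = N (+ N_dead)` are
#' registered. Every core reaction is retained unchanged: the design stays
#' invariant, only its abstraction changes.
#'
#' @param model A `cw_reaction_model` with at least one protein species.
#' @param ctx A [growth_context()].
#' @param fluorescence Name of the per-cell fluorescent species for the
#'   `total_fluorescence` observable; `NULL` to skip it. An error is raised
#'   if the named species is absent.
#' @param dilute_promoters Also dilute promoter-state species? Default FALSE.
#' @return The transformed `cw_reaction_model`.
#' @export
apply_growth_context <- function(model, ctx, fluorescence = "GFP",
                                 dilute_promoters = FALSE) {
  stopifnot(inherits(model, "cw_reaction_model"),
            inherits(ctx, "cw_growth_context"))
  if (!any(model$species$role %in% c("protein", "imported"))) {
    stop("growth context requires a model with at least one protein species",
         call. = FALSE)
  }
  if (!is.null(fluorescence) && !fluorescence %in% model$species$name) {
    stop("fluorescence observable requested but species '", fluorescence,
         "' is absent from the model", call. = FALSE)
  }
  model <- add_species(model, "N", "population", ctx$N0)
  model$parameters[["mu"]] <- ctx$mu
  percap <- switch(ctx$kind,
    exponential = "mu",
    logistic = ,
    lag_logistic = {
      model$parameters[["K_cap"]] <- ctx$K
      "mu * (1 - N / K_cap)"
    })
  model <- add_reaction(model, "growth_N",
                        stats::setNames(numeric(), character()),
                        stats::setNames(1, "N"),
                        "mu", ctx$mu, "growth",
                        rate_law = paste0("(", percap, ") * N"))
  if (ctx$kind == "lag_logistic") {
    model <- add_species(model, "N_dead", "population", ctx$N0_dead)
    model$parameters[["d_dead"]] <- ctx$d
    model <- add_reaction(model, "death_N_dead",
                          stats::setNames(1, "N_dead"),
                          stats::setNames(numeric(), character()),
                          "d_dead", ctx$d, "death")
  }
  roles <- c("protein", "mRNA", "inducer", if (dilute_promoters) "promoter_state")
  intracellular <- model$species$name[model$species$role %in%
                                        setdiff(roles, "inducer")]
  for (s in intracellular) {
    model <- add_reaction(model, paste0("dilute_", s),
                          stats::setNames(1, s),
                          stats::setNames(numeric(), character()),
                          "mu", ctx$mu, "dilution",
                          rate_law = paste0("(", percap, ") * ", s))
  }
  od <- if (ctx$kind == "lag_logistic") "N + N_dead" else "N"
  model$observables[["OD"]] <- od
  if (!is.null(fluorescence)) {
    model$observables[["total_fluorescence"]] <-
      paste0(fluorescence, " * N")
  }
  model
}

#' Shared-protease coupling configuration
#'
#' Post-translational coupling of two circuits through a common protease:
#' one tagged species per sub-circuit competes for the same degradation
#' machinery, so each tagged species' degradation is saturable and decreases
#' as the other accumulates.
#'
#' @param tag_switch Tagged species name in the switch model (protein `A`).
#' @param tag_oscillator Tagged species name in the oscillator model
#'   (`"GFP"` or `"AraC"`).
#' @param V Maximum protease flux; > 0.
#' @param Km Half-saturation constant; > 0.
#' @param delta Protease strength on the oscillator species; > 0.
#' @param gamma Protease strength on the switch species; > 0.
#' @return A `cw_protease_coupling`.
#' @export
protease_coupling <- function(tag_switch = "A", tag_oscillator = c("AraC", "GFP"),
                              V, Km, delta, gamma) {
  tag_oscillator <- match.arg(tag_oscillator)
  stopifnot(V > 0, Km > 0, delta > 0, gamma > 0)
  structure(list(tag_switch = tag_switch, tag_oscillator = tag_oscillator,
                 V = V, Km = Km, delta = delta, gamma = gamma),
            class = "cw_protease_coupling")
}

prefix_model <- function(model, prefix) {
  old <- model$species$name
  new <- paste0(prefix, old)
  map <- stats::setNames(new, old)
  model$species$name <- new
  rename_side <- function(side) stats::setNames(unlist(side) %||% numeric(),
                                                unname(map[names(side)]))
  sub_ids <- function(text, map) {
    e <- parse(text = text)[[1]]
    walk <- function(x) {
      if (is.name(x)) {
        nm <- as.character(x)
        if (nm %in% names(map)) return(as.name(map[[nm]]))
        return(x)
      }
      if (is.call(x)) {
        for (i in seq_along(x)[-1]) x[[i]] <- walk(x[[i]])
      }
      x
    }
    paste(deparse(walk(e), width.cutoff = 500), collapse = " ")
  }
  model$reactions$reactants <- lapply(model$reactions$reactants, rename_side)
  model$reactions$products <- lapply(model$reactions$products, rename_side)
  model$reactions$rate_law <- vapply(model$reactions$rate_law, sub_ids,
                                     character(1), map = map, USE.NAMES = FALSE)
  model$reactions$name <- paste0(prefix, model$reactions$name)
  model$observables <- lapply(model$observables, sub_ids, map = map)
  model
}

#' Couple two models through a shared protease
#'
#' Merges the switch and oscillator models into one (species and reaction
#' namespaces kept disjoint with `sw_`/`osc_` prefixes) and replaces the two
#' tagged species' first-order degradation reactions with competitive
#' saturable terms:
#' `deg(A) = gamma V [A] / (Km + [A] + [X])` and
#' `deg(X) = delta V [X] / (Km + [A] + [X])`,
#' where `A` is the tagged switch species and `X` the tagged oscillator
#' species. All other reactions are untouched, so increasing either
#' competitor's concentration strictly decreases the other's degradation
#' rate (protease queueing).
#'
#' @param switch_model,osc_model `cw_reaction_model`s containing the tagged
#'   species and their first-order degradation reactions.
#' @param coupling A [protease_coupling()].
#' @return The merged, coupled `cw_reaction_model`. The prefixed tagged
#'   species names are attached as attributes `tag_switch`/`tag_oscillator`.
#' @export
apply_protease_coupling <- function(switch_model, osc_model, coupling) {
  stopifnot(inherits(coupling, "cw_protease_coupling"))
  for (chk in list(list(switch_model, coupling$tag_switch, "switch"),
                   list(osc_model, coupling$tag_oscillator, "oscillator"))) {
    if (!chk[[2]] %in% chk[[1]]$species$name) {
      stop("coupling error: tagged species '", chk[[2]],
           "' is missing from the ", chk[[3]], " model", call. = FALSE)
    }
  }
  sw <- prefix_model(switch_model, "sw_")
  os <- prefix_model(osc_model, "osc_")
  merged <- empty_model("coupled")
  merged$species <- dplyr::bind_rows(sw$species, os$species)
  merged$reactions <- dplyr::bind_rows(sw$reactions, os$reactions)
  merged$parameters <- c(sw$parameters,
                         os$parameters[setdiff(names(os$parameters),
                                               names(sw$parameters))])
  merged$observables <- c(sw$observables, os$observables)
  A <- paste0("sw_", coupling$tag_switch)
  X <- paste0("osc_", coupling$tag_oscillator)
  merged$parameters[["prot_V"]] <- coupling$V
  merged$parameters[["prot_Km"]] <- coupling$Km
  merged$parameters[["prot_delta"]] <- coupling$delta
  merged$parameters[["prot_gamma"]] <- coupling$gamma
  pool <- paste0("(prot_Km + ", A, " + ", X, ")")
  retag <- function(merged, species, strength) {
    idx <- which(merged$reactions$category == "degradation_protein" &
                   vapply(merged$reactions$reactants, function(re) {
                     length(re) == 1 && names(re) == species
                   }, logical(1)))
    if (length(idx) == 0) {
      stop("coupling error: no first-order degradation reaction found for '",
           species, "'", call. = FALSE)
    }
    merged$reactions$rate_law[idx] <-
      paste0(strength, " * prot_V * ", species, " / ", pool)
    merged$reactions$category[idx] <- "coupled_degradation"
    merged$reactions$mass_action[idx] <- FALSE
    merged
  }
  merged <- retag(merged, A, "prot_gamma")
  merged <- retag(merged, X, "prot_delta")
  attr(merged, "tag_switch") <- A
  attr(merged, "tag_oscillator") <- X
  merged
}

#' Canonical reaction fingerprints
#'
#' Used for core-invariance checks: a reaction's fingerprint is its sorted
#' reactant and product multisets plus its rate law, independent of table
#' order.
#'
#' @param model A `cw_reaction_model`.
#' @return Character vector of fingerprints, one per reaction.
#' @export
reaction_fingerprints <- function(model) {
  vapply(seq_len(nrow(model$reactions)), function(j) {
    r <- model$reactions[j, ]
    side <- function(s) paste(sort(paste0(names(s), ":", unlist(s))), collapse = ",")
    paste(side(r$reactants[[1]]), "->", side(r$products[[1]]), "@", r$rate_law)
  }, character(1))
}
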
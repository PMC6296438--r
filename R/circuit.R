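#' Create a genetic part
#'
#' A part is a typed genetic element: a promoter, RBS, coding region,
#' terminator, or any user-declared subtype of these. Promoters may carry
#' regulation links to molecules; coding regions code for a molecule.
#' Regulation signs are inferred from the promoter type (`PositivePromoter`
#' descent is positive, `NegativePromoter` descent negative); hybrid promoters
#' that descend from neither must state `signs` explicitly — this is how
#' multi-input (AND-gate style) promoters are built.
#'
#' @param reg A registry from [new_registry()].
#' @param type Registered part type name.
#' @param name Instance name; defaults to the type name.
#' @param regulated_by Character vector of regulating molecule type names
#'   (promoters only). Order is kept.
#' @param codes_for Molecule type name coded for (coding regions only).
#' @param signs Optional character vector (`"positive"`/`"negative"`), one per
#'   regulator, for promoters descending from neither `PositivePromoter` nor
#'   `NegativePromoter`.
#' @return An object of class `cw_part`.
#' @examples
#' reg <- new_registry()
#' declare_molecule_type(reg, "GFP", "Protein")
#' part(reg, "CodingRegion", "cGFP", codes_for = "GFP")
#' @export
part <- function(reg, type, name = type, regulated_by = NULL, codes_for = NULL,
                 signs = NULL) {
  stopifnot(inherits(reg, "cw_registry"))
  if (!type %in% names(reg$part)) {
    stop("unknown part type: '", type, "'", call. = FALSE)
  }
  is_coding <- is_subtype(reg, type, "CodingRegion", "part")
  is_promoter <- is_subtype(reg, type, "Promoter", "part")
  if (!is.null(codes_for) && !is_coding) {
    stop("only CodingRegion parts may code for a molecule ('", name, "')",
         call. = FALSE)
  }
  if (is_coding && is.null(codes_for)) {
    stop("coding region '", name, "' must code for a molecule", call. = FALSE)
  }
  if (length(regulated_by) > 0 && !is_promoter) {
    stop("only Promoter parts may be regulated ('", name, "')", call. = FALSE)
  }
  regulation <- list()
  if (length(regulated_by) > 0) {
    if (is_subtype(reg, type, "ConstitutivePromoter", "part")) {
      stop("constitutive promoter '", name, "' cannot take regulators",
           call. = FALSE)
    }
    if (is.null(signs)) {
      signs <- if (is_subtype(reg, type, "PositivePromoter", "part")) {
        rep("positive", length(regulated_by))
      } else if (is_subtype(reg, type, "NegativePromoter", "part")) {
        rep("negative", length(regulated_by))
      } else {
        stop("promoter '", name, "' descends from neither PositivePromoter ",
             "nor NegativePromoter; supply `signs` explicitly", call. = FALSE)
      }
    }
    stopifnot(length(signs) == length(regulated_by),
              all(signs %in% c("positive", "negative")))
    regulation <- Map(function(m, s) list(molecule = m, sign = s),
                      regulated_by, signs)
    names(regulation) <- NULL
  }
  structure(
    list(type = type, name = name, regulation = regulation,
         codes_for = codes_for),
    class = "cw_part"
  )
}

#' @export
print.cw_part <- function(x, ...) {
  reg_txt <- if (length(x$regulation)) {
    paste0(" <- ", paste(vapply(x$regulation, function(r) {
      paste0(r$molecule, " (", r$sign, ")")
    }, character(1)), collapse = ", "))
  } else ""
  cf <- if (!is.null(x$codes_for)) paste0(" codes for ", x$codes_for) else ""
  cat("<cw_part> ", x$name, " [", x$type, "]", reg_txt, cf, "\n", sep = "")
  invisible(x)
}

part_molecules <- function(p) {
  c(vapply(p$regulation, `[[`, character(1), "molecule"),
    p$codes_for %||% character())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Create a circuit (compartment)
#'
#' Circuits hold molecules, parts and subcircuits in declaration order, and
#' act as compartments: a closed circuit resolves molecule references only in
#' its own scope; a permeable one also searches enclosing scopes, nearest
#' first. Circuits are value objects — [add_part()], [declare_molecule()] and
#' [add_subcircuit()] return a modified copy.
#'
#' @param name Circuit name.
#' @param permeable Logical; can the compartment see enclosing scopes?
#' @return An object of class `cw_circuit`.
#' @export
circuit <- function(name, permeable = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(name = name, permeable = isTRUE(permeable), events = list()),
    class = "cw_circuit"
  )
}

circuit_molecules <- function(circ) {
  ev <- circ$events
  unlist(lapply(ev, function(e) if (e$kind == "molecule") e$name else NULL)) %||%
    character()
}

#' Declare a molecule in a circuit's scope
#'
#' Molecule declaration is a join point in the compiled execution flow.
#' Re-declaring the same molecule in the same circuit is idempotent.
#'
#' @param circ A [circuit()].
#' @param name Registered molecule type name.
#' @return The modified circuit.
#' @export
declare_molecule <- function(circ, name) {
  stopifnot(inherits(circ, "cw_circuit"))
  if (name %in% circuit_molecules(circ)) return(circ)
  circ$events <- c(circ$events, list(list(kind = "molecule", name = name)))
  circ
}

#' Add a part to a circuit
#'
#' Part addition is the primary join point the weaver dispatches on. For a
#' closed circuit every molecule the part references must already be declared
#' locally; permeable circuits defer resolution to compile time, when the
#' enclosing scopes are known.
#'
#' @param circ A [circuit()].
#' @param p A [part()].
#' @return The modified circuit.
#' @export
add_part <- function(circ, p) {
  stopifnot(inherits(circ, "cw_circuit"), inherits(p, "cw_part"))
  if (!circ$permeable) {
    missing <- setdiff(part_molecules(p), circuit_molecules(circ))
    if (length(missing) > 0) {
      stop("molecule '", missing[[1]], "' referenced by part '", p$name,
           "' is not in scope of closed circuit '", circ$name, "'",
           call. = FALSE)
    }
  }
  circ$events <- c(circ$events, list(list(kind = "part", part = p)))
  circ
}

#' Nest a subcircuit
#'
#' @param circ Parent circuit.
#' @param sub Child circuit (a compartment of its own).
#' @return The modified parent circuit.
#' @export
add_subcircuit <- function(circ, sub) {
  stopifnot(inherits(circ, "cw_circuit"), inherits(sub, "cw_circuit"))
  circ$events <- c(circ$events, list(list(kind = "circuit", circuit = sub)))
  circ
}

#' @export
print.cw_circuit <- function(x, ...) {
  kinds <- vapply(x$events, `[[`, character(1), "kind")
  cat("<cw_circuit> '", x$name, "' (", if (x$permeable) "permeable" else "closed",
      "): ", sum(kinds == "part"), " parts, ", sum(kinds == "molecule"),
      " molecules, ", sum(kinds == "circuit"), " subcircuits\n", sep = "")
  invisible(x)
}

# Resolve molecule `m` from a scope stack (list of character vectors, outermost
# first) given the permeability of each level. Returns depth index or 0.
resolve_molecule <- function(m, scopes, permeable) {
  n <- length(scopes)
  for (i in rev(seq_len(n))) {
    if (m %in% scopes[[i]]) return(i)
    # can only look further out if the current level is permeable
    if (!permeable[[i]]) return(0L)
  }
  0L
}

#' Linearize a circuit tree into an execution flow
#'
#' Compiles the circuit into its execution flow: a depth-first,
#' declaration-order sequence of steps, each a part addition or a molecule
#' declaration, with the compartment path recorded. Molecule scoping is
#' checked here for the whole tree (closed compartments resolve locally,
#' permeable ones search enclosing scopes nearest first).
#'
#' @param circ A [circuit()].
#' @param reg The registry the circuit's parts were built against.
#' @return A tibble of class `cw_flow` with one row per step: `step`, `path`
#'   (list of compartment names, outermost first), `kind`, `part_type`,
#'   `name`, `codes_for`, `regulation` (list), `flow_index` (0-based position
#'   among parts, `NA` for molecule steps), `provenance`, and a `part`
#'   list-column holding the part objects.
#' @export
linearize <- function(circ, reg) {
  stopifnot(inherits(circ, "cw_circuit"))
  rows <- list()
  walk <- function(c0, path, scopes, permeable) {
    path <- c(path, c0$name)
    scopes <- c(scopes, list(character()))
    permeable <- c(permeable, c0$permeable)
    depth <- length(scopes)
    for (e in c0$events) {
      if (e$kind == "molecule") {
        scopes[[depth]] <- union(scopes[[depth]], e$name)
        rows[[length(rows) + 1L]] <<- list(
          path = path, kind = "molecule", part_type = NA_character_,
          name = e$name, codes_for = NA_character_, regulation = list(),
          part = NULL
        )
      } else if (e$kind == "part") {
        for (m in part_molecules(e$part)) {
          if (resolve_molecule(m, scopes, permeable) == 0L) {
            stop("molecule '", m, "' referenced by part '", e$part$name,
                 "' cannot be resolved in compartment '", c0$name, "'",
                 call. = FALSE)
          }
        }
        rows[[length(rows) + 1L]] <<- list(
          path = path, kind = "part", part_type = e$part$type,
          name = e$part$name, codes_for = e$part$codes_for %||% NA_character_,
          regulation = e$part$regulation, part = e$part
        )
      } else {
        walk(e$circuit, path, scopes, permeable)
      }
    }
  }
  walk(circ, character(), list(), logical())
  flow <- tibble::tibble(
    step = seq_along(rows),
    path = lapply(rows, `[[`, "path"),
    kind = vapply(rows, `[[`, character(1), "kind"),
    part_type = vapply(rows, `[[`, character(1), "part_type"),
    name = vapply(rows, `[[`, character(1), "name"),
    codes_for = vapply(rows, `[[`, character(1), "codes_for"),
    regulation = lapply(rows, `[[`, "regulation"),
    part = lapply(rows, `[[`, "part"),
    provenance = rep("design", length(rows))
  )
  flow$flow_index <- NA_integer_
  is_part <- flow$kind == "part"
  flow$flow_index[is_part] <- seq_len(sum(is_part)) - 1L
  attr(flow, "registry") <- reg
  class(flow) <- c("cw_flow", class(flow))
  flow
}

#' Parts of an execution flow
#'
#' @param flow A `cw_flow` tibble from [linearize()] or a woven system's flow.
#' @return The part rows only, in flow order.
#' @export
flow_parts <- function(flow) {
  flow[flow$kind == "part", , drop = FALSE]
}
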
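yaml_schema_id <- "circuitweaver-circuit/1"

circuit_to_list <- function(circ) {
  kinds <- vapply(circ$events, `[[`, character(1), "kind")
  parts <- lapply(circ$events[kinds == "part"], function(e) {
    p <- e$part
    out <- list(type = p$type, name = p$name)
    if (length(p$regulation) > 0) {
      out$regulated_by <- lapply(p$regulation, `[[`, "molecule")
      out$signs <- lapply(p$regulation, `[[`, "sign")
    }
    if (!is.null(p$codes_for)) out$codes_for <- p$codes_for
    out
  })
  subs <- lapply(circ$events[kinds == "circuit"],
                 function(e) circuit_to_list(e$circuit))
  list(name = circ$name, permeable = circ$permeable,
       molecules = as.list(circuit_molecules(circ)),
       parts = parts, subcircuits = subs)
}

#' Write / read a circuit in the declarative YAML format
#'
#' The schema (versioned `circuitweaver-circuit/1`) has top-level keys
#' `schema`, `types` (`parts`/`molecules`, each a list of `name`/`parent`
#' pairs for non-built-in types) and `circuit` (`name`, `permeable`,
#' `molecules`, `parts` with `type`/`name`/`regulated_by`/`signs`/
#' `codes_for`, and nested `subcircuits`). Declaration order within a
#' circuit is molecules, then parts, then subcircuits; circuits built that
#' way round-trip losslessly.
#'
#' @param circ A [circuit()].
#' @param reg The registry the circuit was built against.
#' @param file Output path.
#' @return `write_circuit_yaml()` returns `file` invisibly;
#'   `read_circuit_yaml()` returns `list(circuit, registry)`.
#' @export
write_circuit_yaml <- function(circ, reg, file) {
  circ_list <- circuit_to_list(circ)  # force before reading the registry
  builtin <- new_registry()
  custom_types <- function(kind) {
    extra <- setdiff(names(reg[[kind]]), names(builtin[[kind]]))
    lapply(extra, function(nm) list(name = nm, parent = unname(reg[[kind]][[nm]])))
  }
  doc <- list(schema = yaml_schema_id,
              types = list(parts = custom_types("part"),
                           molecules = custom_types("molecule")),
              circuit = circ_list)
  yaml::write_yaml(doc, file)
  invisible(file)
}

list_to_circuit <- function(lst, reg) {
  circ <- circuit(lst$name, permeable = isTRUE(lst$permeable))
  for (m in lst$molecules) circ <- declare_molecule(circ, m)
  for (p in lst$parts) {
    circ <- add_part(circ, part(
      reg, p$type, p$name %||% p$type,
      regulated_by = unlist(p$regulated_by),
      codes_for = p$codes_for,
      signs = unlist(p$signs)))
  }
  for (s in lst$subcircuits) circ <- add_subcircuit(circ, list_to_circuit(s, reg))
  circ
}

#' @rdname write_circuit_yaml
#' @export
read_circuit_yaml <- function(file, reg = new_registry()) {
  doc <- yaml::read_yaml(file)
  if (!identical(doc$schema, yaml_schema_id)) {
    stop("unsupported circuit schema: ", doc$schema %||% "<missing>",
         call. = FALSE)
  }
  declare_in_order <- function(entries, kind) {
    pending <- entries
    while (length(pending) > 0) {
      progressed <- FALSE
      rest <- list()
      for (e in pending) {
        if (e$parent %in% names(reg[[kind]])) {
          if (!e$name %in% names(reg[[kind]])) {
            declare_type(reg, kind, e$name, e$parent)
          }
          progressed <- TRUE
        } else {
          rest[[length(rest) + 1L]] <- e
        }
      }
      if (!progressed) {
        stop("unresolvable type parents in YAML types block", call. = FALSE)
      }
      pending <- rest
    }
  }
  declare_in_order(doc$types$parts %||% list(), "part")
  declare_in_order(doc$types$molecules %||% list(), "molecule")
  list(circuit = list_to_circuit(doc$circuit, reg), registry = reg)
}
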
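#' Point cuts, advice and aspects
#'
#' A point cut pairs a point-cut expression with an operator saying where the
#' advice acts relative to the matched join point — `"before"`, `"after"` or
#' `"replace"` — and a priority used to rank competing advice. An advice
#' attaches a body to a point cut; the body receives a match context and
#' returns the parts (and molecule declarations) to inject. Type advice
#' attaches named properties to every part matching a signature once the
#' structure is final. Aspects bundle advice, type advice and output
#' generators into one reusable concern.
#'
#' @param expression A point-cut expression string (see [signatures]) or a
#'   parsed expression.
#' @param operator One of `"before"`, `"after"`, `"replace"`.
#' @param priority Integer priority, larger wins; default 0.
#' @return `point_cut()` returns a `cw_pointcut`.
#' @export
point_cut <- function(expression, operator = c("before", "after", "replace"),
                      priority = 0L) {
  operator <- match.arg(operator)
  if (is.character(expression)) expression <- parse_pointcut_expression(expression)
  structure(list(expression = expression, operator = operator,
                 priority = as.integer(priority)),
            class = "cw_pointcut")
}

#' @rdname point_cut
#' @param pointcut A [point_cut()].
#' @param body For `advice()`: `function(ctx)` returning a list of [part()]
#'   objects and/or [molecule_declaration()]s (`"before"`/`"after"`), or a
#'   single part (`"replace"`). `ctx` has fields `part` (the matched part
#'   object; for replace advice this is the part being replaced, so its
#'   regulation links can be copied), `row` (its flow row), `flow` and
#'   `registry`.
#' @return `advice()` returns a `cw_advice`.
#' @export
advice <- function(pointcut, body) {
  stopifnot(inherits(pointcut, "cw_pointcut"), is.function(body))
  structure(list(pointcut = pointcut, body = body), class = "cw_advice")
}

#' @rdname point_cut
#' @param target A part-signature string selecting the parts to annotate.
#' @param property Property name (unique per part across all aspects).
#' @param provider `function(ctx)` computing the property value for one
#'   matched part; it may read, but not mutate, the woven flow.
#' @return `type_advice()` returns a `cw_type_advice`.
#' @export
type_advice <- function(target, property, provider) {
  stopifnot(is.character(target), is.character(property), is.function(provider))
  structure(list(target = target, property = property, provider = provider),
            class = "cw_type_advice")
}

#' @rdname point_cut
#' @param name Aspect name (used in provenance).
#' @param advice_list List of [advice()] objects, in declaration order.
#' @param type_advice_list List of [type_advice()] objects.
#' @param outputs Named list of `function(woven)` artifact generators,
#'   registered on the woven system after weaving.
#' @return `aspect()` returns a `cw_aspect`.
#' @export
aspect <- function(name, advice_list = list(), type_advice_list = list(),
                   outputs = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, advice_list = advice_list,
                 type_advice_list = type_advice_list, outputs = outputs),
            class = "cw_aspect")
}

#' Declare a molecule from advice
#'
#' Advice bodies return these alongside parts to bring new molecules into the
#' join point's compartment scope.
#'
#' @param name Registered molecule type name.
#' @return A `cw_molecule_decl`.
#' @export
molecule_declaration <- function(name) {
  structure(list(name = name), class = "cw_molecule_decl")
}

#' Rank competing advice at one join point
#'
#' Matches are ordered by priority (descending), then by aspect position in
#' the weave call, then by declaration order within the aspect. At most one
#' replace advice may apply per join point — the highest ranked; two replace
#' matches of identical rank are an ambiguity error.
#'
#' @param matches A data frame with columns `priority`, `aspect_idx`,
#'   `decl_idx`, `operator`.
#' @return The data frame sorted by rank, with replace matches reduced to the
#'   winner.
#' @export
resolve_advice <- function(matches) {
  ord <- order(-matches$priority, matches$aspect_idx, matches$decl_idx)
  matches <- matches[ord, , drop = FALSE]
  repl <- which(matches$operator == "replace")
  if (length(repl) > 1) {
    a <- matches[repl[1], ]; b <- matches[repl[2], ]
    if (a$priority == b$priority && a$aspect_idx == b$aspect_idx &&
        a$decl_idx == b$decl_idx) {
      stop("ambiguous replace advice: two replace matches of equal rank at one join point",
           call. = FALSE)
    }
    matches <- matches[-repl[-1], , drop = FALSE]
  }
  matches
}

new_flow_row <- function(template_row, p, provenance, inserted_by, id) {
  tibble::tibble(
    step = NA_integer_, path = template_row$path, kind = "part",
    part_type = p$type, name = p$name,
    codes_for = p$codes_for %||% NA_character_,
    regulation = list(p$regulation), part = list(p),
    provenance = provenance, flow_index = NA_integer_,
    id = id, inserted_by = inserted_by, replaced = list(NULL)
  )
}

new_molecule_row <- function(template_row, name, provenance, inserted_by, id) {
  tibble::tibble(
    step = NA_integer_, path = template_row$path, kind = "molecule",
    part_type = NA_character_, name = name, codes_for = NA_character_,
    regulation = list(list()), part = list(NULL),
    provenance = provenance, flow_index = NA_integer_,
    id = id, inserted_by = inserted_by, replaced = list(NULL)
  )
}

#' Weave aspects into a circuit design
#'
#' Compiles the design into its execution flow and replays it under the given
#' aspects: at every part-addition join point all matching advice is applied
#' in rank order (see [resolve_advice()]); parts inserted by advice are
#' themselves join points for advice evaluated later at that position, but
#' never re-trigger the advice that inserted them. A weaving-depth cap
#' converts runaway mutual triggering into an error naming the aspects
#' involved. After structural weaving, type advice runs over the final flow
#' in aspect order and aspect outputs are registered.
#'
#' @param design A [circuit()].
#' @param aspects List of [aspect()]s (possibly empty), applied in order.
#' @param reg The registry.
#' @param max_depth Maximum number of insertion rounds before a cyclic-advice
#'   error is raised.
#' @return An object of class `cw_woven` with fields `flow` (the woven
#'   execution flow, with `provenance` per part), `registry`, `design`,
#'   `properties` (a tibble of type-advice annotations), `outputs` and
#'   `aspects`.
#' @examples
#' reg <- new_registry()
#' gfp <- fixture_circuit("CodingGFP", reg)
#' woven <- weave(gfp, list(design_rules_aspect()), reg)
#' flow_parts(woven$flow)$part_type
#' @export
weave <- function(design, aspects = list(), reg, max_depth = 10L) {
  if (inherits(aspects, "cw_aspect")) aspects <- list(aspects)
  flow <- linearize(design, reg)
  flow$id <- paste0("d", seq_len(nrow(flow)))
  flow$inserted_by <- NA_character_
  flow$replaced <- replicate(nrow(flow), NULL, simplify = FALSE)

  adv <- list()
  for (ai in seq_along(aspects)) {
    asp <- aspects[[ai]]
    for (di in seq_along(asp$advice_list)) {
      a <- asp$advice_list[[di]]
      adv[[length(adv) + 1L]] <- list(
        uid = paste0("a", ai, ".", di), aspect = asp$name, aspect_idx = ai,
        decl_idx = di, advice = a
      )
    }
  }

  evaluated <- new.env(parent = emptyenv())
  depth <- 0L
  repeat {
    # find fresh matches: advice x part pairs not yet evaluated
    matches <- list()
    for (a in adv) {
      ctx <- match_expression(a$advice$pointcut$expression, flow, reg)
      if (nrow(ctx) == 0) next
      parts <- flow_parts(flow)
      for (i in seq_len(nrow(ctx))) {
        pid <- parts$id[[ctx$context_index[[i]]]]
        seen <- evaluated[[pid]] %||% character()
        inserter <- parts$inserted_by[[ctx$context_index[[i]]]]
        if (a$uid %in% seen) next
        if (!is.na(inserter) && identical(inserter, a$uid)) next
        matches[[length(matches) + 1L]] <- list(
          part_id = pid, uid = a$uid, aspect = a$aspect,
          aspect_idx = a$aspect_idx, decl_idx = a$decl_idx,
          operator = a$advice$pointcut$operator,
          priority = a$advice$pointcut$priority,
          body = a$advice$body
        )
      }
    }
    # mark every current part as evaluated against every advice
    for (pid in flow$id[flow$kind == "part"]) {
      evaluated[[pid]] <- union(evaluated[[pid]] %||% character(),
                                vapply(adv, `[[`, character(1), "uid"))
    }
    if (length(matches) == 0) break
    depth <- depth + 1L
    if (depth > max_depth) {
      stop("cyclic advice: weaving did not terminate within ", max_depth,
           " rounds (aspects involved: ",
           paste(unique(vapply(matches, `[[`, character(1), "aspect")),
                 collapse = ", "), ")", call. = FALSE)
    }
    by_part <- split(matches, vapply(matches, `[[`, character(1), "part_id"))
    counter <- 0L
    next_id <- function() paste0("w", depth, ".", (counter <<- counter + 1L))
    pieces <- list()
    for (r in seq_len(nrow(flow))) {
      row <- flow[r, , drop = FALSE]
      ms <- if (row$kind == "part") by_part[[row$id]] else NULL
      if (is.null(ms)) {
        pieces[[length(pieces) + 1L]] <- row
        next
      }
      df <- data.frame(
        priority = vapply(ms, `[[`, numeric(1), "priority"),
        aspect_idx = vapply(ms, `[[`, numeric(1), "aspect_idx"),
        decl_idx = vapply(ms, `[[`, numeric(1), "decl_idx"),
        operator = vapply(ms, `[[`, character(1), "operator"),
        idx = seq_along(ms)
      )
      df <- resolve_advice(df)
      ctx <- list(part = row$part[[1]], row = row, flow = flow, registry = reg)
      emit <- function(ret, aspect, uid) {
        if (is.null(ret)) return()
        if (inherits(ret, "cw_part") || inherits(ret, "cw_molecule_decl")) {
          ret <- list(ret)
        }
        for (item in ret) {
          if (inherits(item, "cw_part")) {
            pieces[[length(pieces) + 1L]] <<-
              new_flow_row(row, item, aspect, uid, next_id())
          } else if (inherits(item, "cw_molecule_decl")) {
            pieces[[length(pieces) + 1L]] <<-
              new_molecule_row(row, item$name, aspect, uid, next_id())
          } else {
            stop("advice body must return parts or molecule declarations",
                 call. = FALSE)
          }
        }
      }
      for (i in df$idx[df$operator == "before"]) {
        m <- ms[[i]]
        emit(m$body(ctx), m$aspect, m$uid)
      }
      irepl <- df$idx[df$operator == "replace"]
      if (length(irepl) == 1) {
        m <- ms[[irepl]]
        ret <- m$body(ctx)
        mols <- Filter(function(x) inherits(x, "cw_molecule_decl"),
                       if (inherits(ret, "cw_part")) list() else ret)
        ps <- if (inherits(ret, "cw_part")) list(ret) else
          Filter(function(x) inherits(x, "cw_part"), ret)
        if (length(ps) != 1) {
          stop("replace advice must return exactly one part", call. = FALSE)
        }
        emit(mols, m$aspect, m$uid)
        repl_row <- new_flow_row(row, ps[[1]], m$aspect, m$uid, next_id())
        repl_row$replaced <- list(row$part[[1]])
        pieces[[length(pieces) + 1L]] <- repl_row
      } else {
        pieces[[length(pieces) + 1L]] <- row
      }
      for (i in df$idx[df$operator == "after"]) {
        m <- ms[[i]]
        emit(m$body(ctx), m$aspect, m$uid)
      }
    }
    flow <- dplyr::bind_rows(pieces)
    attr(flow, "registry") <- reg
    class(flow) <- unique(c("cw_flow", class(flow)))
  }

  flow$step <- seq_len(nrow(flow))
  flow$flow_index <- NA_integer_
  is_part <- flow$kind == "part"
  flow$flow_index[is_part] <- seq_len(sum(is_part)) - 1L
  attr(flow, "registry") <- reg
  class(flow) <- unique(c("cw_flow", class(flow)))
  validate_flow_scope(flow)

  woven <- structure(
    list(flow = flow, registry = reg, design = design,
         properties = tibble::tibble(part_id = character(), part = character(),
                                     property = character(), value = list()),
         outputs = list(),
         aspects = vapply(aspects, `[[`, character(1), "name")),
    class = "cw_woven"
  )
  for (asp in aspects) {
    for (ta in asp$type_advice_list) {
      woven <- apply_type_advice(woven, ta, aspect_name = asp$name)
    }
  }
  for (asp in aspects) {
    for (nm in names(asp$outputs)) {
      if (nm %in% names(woven$outputs)) {
        stop("duplicate aspect output name: '", nm, "'", call. = FALSE)
      }
      woven$outputs[[nm]] <- asp$outputs[[nm]](woven)
    }
  }
  woven
}

# every regulation/coding molecule must be declared at an ancestor-or-same
# compartment earlier in the flow (design parts were already scope-checked
# with full permeability rules at linearize time)
validate_flow_scope <- function(flow) {
  declared <- list()
  for (r in seq_len(nrow(flow))) {
    if (flow$kind[[r]] == "molecule") {
      declared[[length(declared) + 1L]] <- flow$path[[r]]
      names(declared)[length(declared)] <- flow$name[[r]]
    } else {
      p <- flow$part[[r]]
      for (m in part_molecules(p)) {
        paths <- declared[names(declared) == m]
        ok <- any(vapply(paths, function(dp) {
          length(dp) <= length(flow$path[[r]]) &&
            identical(dp, flow$path[[r]][seq_along(dp)])
        }, logical(1)))
        if (!ok) {
          stop("after weaving, molecule '", m, "' referenced by part '",
               p$name, "' does not resolve in its compartment", call. = FALSE)
        }
      }
    }
  }
  invisible(flow)
}

#' Attach a type-advice property to a woven system
#'
#' Runs one type advice over the final flow: every part matching the target
#' signature gets `property` set to the provider's value. A part may carry
#' many distinct properties, but setting the same property name twice on the
#' same part is a conflict error.
#'
#' @param woven A `cw_woven` from [weave()].
#' @param ta A [type_advice()].
#' @param aspect_name Provenance label recorded with the property.
#' @return The woven system with the property table extended.
#' @export
apply_type_advice <- function(woven, ta, aspect_name = "adhoc") {
  stopifnot(inherits(woven, "cw_woven"), inherits(ta, "cw_type_advice"))
  ctx_rows <- match_expression(ta$target, woven$flow, woven$registry)
  parts <- flow_parts(woven$flow)
  for (i in seq_len(nrow(ctx_rows))) {
    row <- ctx_rows[i, , drop = FALSE]
    pid <- row$id[[1]]
    dup <- woven$properties$part_id == pid & woven$properties$property == ta$property
    if (any(dup)) {
      stop("property '", ta$property, "' already set on part '", row$name,
           "' (aspect conflict)", call. = FALSE)
    }
    value <- ta$provider(list(part = row$part[[1]], row = row,
                              flow = woven$flow, registry = woven$registry))
    woven$properties <- dplyr::bind_rows(
      woven$properties,
      tibble::tibble(part_id = pid, part = row$name, property = ta$property,
                     value = list(value), aspect = aspect_name)
    )
  }
  woven
}

#' Recover the declared flow from a woven system
#'
#' Drops every advice-inserted step and undoes replacements, reconstructing
#' the design's own execution flow (the round-trip guarantee: weaving never
#' reorders design parts).
#'
#' @param woven A `cw_woven`.
#' @return A `cw_flow` tibble equivalent to `linearize(design, reg)`.
#' @export
declared_flow <- function(woven) {
  flow <- woven$flow
  keep <- list()
  for (r in seq_len(nrow(flow))) {
    if (flow$provenance[[r]] == "design") {
      keep[[length(keep) + 1L]] <- flow[r, , drop = FALSE]
    } else if (!is.null(flow$replaced[[r]])) {
      orig <- flow$replaced[[r]]
      row <- new_flow_row(flow[r, , drop = FALSE], orig, "design",
                          NA_character_, flow$id[[r]])
      keep[[length(keep) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(keep)
  out$step <- seq_len(nrow(out))
  out$flow_index <- NA_integer_
  is_part <- out$kind == "part"
  out$flow_index[is_part] <- seq_len(sum(is_part)) - 1L
  attr(out, "registry") <- woven$registry
  class(out) <- unique(c("cw_flow", class(out)))
  out
}

#' @export
print.cw_woven <- function(x, ...) {
  parts <- flow_parts(x$flow)
  cat("<cw_woven> ", nrow(parts), " parts (",
      sum(parts$provenance != "design"), " from aspects: ",
      paste(x$aspects, collapse = ", "), ")\n", sep = "")
  cat(paste0("  ", parts$name, " [", parts$part_type, "] <", parts$provenance,
             ">", collapse = "\n"), "\n")
  invisible(x)
}
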
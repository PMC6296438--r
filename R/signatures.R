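#' Part-signature and point-cut matching language
#'
#' Point cuts select join points with a small pattern language over the
#' compiled execution flow. A part signature has the shape
#'
#' ```
#' ['!'] [compartment '.' ...] name ['+'] [ '(' molecule-signature ')' | '()' ]
#' ```
#'
#' where `*` in any name matches an arbitrary (possibly empty) substring,
#' `+` extends a type name to all of its subtypes, a leading `!` negates the
#' whole signature, an empty `()` requires the part to have no associated
#' molecule, and a molecule signature in parentheses requires at least one
#' associated molecule (a regulator or the coded product) to match. Several
#' part signatures joined with `%` form a point-cut expression matching runs
#' of consecutive parts; the match context is the part matched by the final
#' signature in the chain.
#'
#' @name signatures
NULL

glob_match <- function(pattern, x) {
  grepl(utils::glob2rx(pattern), x)
}

sig_name_rx <- "[A-Za-z0-9_*]+"

#' Parse a molecule signature
#'
#' @param text Signature text, e.g. `"Protein+"`, `"T*"`, or `""` (the empty
#'   signature used for `()`).
#' @return A list of class `cw_molecule_signature` with fields
#'   `name_pattern`, `include_subtypes`, `require_none`.
#' @export
parse_molecule_signature <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) {
    out <- list(name_pattern = NA_character_, include_subtypes = FALSE,
                require_none = TRUE)
  } else {
    m <- regmatches(text, regexec(paste0("^(", sig_name_rx, ")(\\+)?$"), text))[[1]]
    if (length(m) == 0) {
      stop("invalid molecule signature: '", text, "'", call. = FALSE)
    }
    out <- list(name_pattern = m[[2]], include_subtypes = m[[3]] == "+",
                require_none = FALSE)
  }
  structure(out, class = "cw_molecule_signature")
}

#' Parse a part signature
#'
#' @param text Signature text (see [signatures] for the grammar).
#' @return A list of class `cw_part_signature` with fields `negated`,
#'   `compartments` (character vector of name patterns), `name_pattern`,
#'   `include_subtypes`, `molecule_sig` (`NULL` if absent).
#' @examples
#' parse_part_signature("Simple*.Promoter+")
#' parse_part_signature("!*.Terminator")
#' @export
parse_part_signature <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  orig <- text
  if (!nzchar(text)) stop("empty part signature", call. = FALSE)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in part signature '", orig, "' (position ",
         nchar(text), ")", call. = FALSE)
  }
  negated <- startsWith(text, "!")
  if (negated) text <- substring(text, 2L)
  molecule_sig <- NULL
  paren <- regexpr("\\(([^()]*)\\)$", text)
  if (paren > 0) {
    inner <- sub("^.*\\(([^()]*)\\)$", "\\1", text)
    molecule_sig <- parse_molecule_signature(inner)
    text <- substring(text, 1L, paren - 1L)
  } else if (grepl("[()]", text)) {
    stop("misplaced parentheses in part signature '", orig, "'", call. = FALSE)
  }
  segs <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (length(segs) == 0 || any(!nzchar(segs)) || grepl("\\.$", text)) {
    stop("malformed name/compartment chain in part signature '", orig,
         "' (position ", nchar(orig), ")", call. = FALSE)
  }
  name <- segs[[length(segs)]]
  comps <- segs[-length(segs)]
  include_subtypes <- endsWith(name, "+")
  if (include_subtypes) name <- substring(name, 1L, nchar(name) - 1L)
  ok <- function(s) grepl(paste0("^", sig_name_rx, "$"), s)
  if (!nzchar(name) || !ok(name) || (length(comps) > 0 && !all(vapply(comps, ok, logical(1))))) {
    stop("invalid identifier in part signature '", orig, "'", call. = FALSE)
  }
  structure(
    list(negated = negated, compartments = comps, name_pattern = name,
         include_subtypes = include_subtypes, molecule_sig = molecule_sig),
    class = "cw_part_signature"
  )
}

#' Parse a point-cut expression
#'
#' @param text One or more part signatures joined with `%`.
#' @return A list of class `cw_pointcut_expression` whose `chain` field is a
#'   list of parsed part signatures.
#' @export
parse_pointcut_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pieces <- trimws(strsplit(text, "%", fixed = TRUE)[[1]])
  if (length(pieces) == 0 || any(!nzchar(pieces))) {
    stop("invalid point-cut expression: '", text, "'", call. = FALSE)
  }
  structure(list(chain = lapply(pieces, parse_part_signature), text = text),
            class = "cw_pointcut_expression")
}

#' Match a molecule signature against a molecule type
#'
#' Matches on the type name; with `+` the pattern may match any ancestor type,
#' so `"Protein+"` matches every protein subtype.
#'
#' @param sig A [parse_molecule_signature()] result (or its text).
#' @param molecule Registered molecule type name.
#' @param reg The registry.
#' @return Logical scalar.
#' @export
match_molecule <- function(sig, molecule, reg) {
  if (is.character(sig)) sig <- parse_molecule_signature(sig)
  if (sig$require_none) stop("empty molecule signature matches absence, not a molecule",
                             call. = FALSE)
  candidates <- if (sig$include_subtypes) {
    type_ancestry(reg, molecule, "molecule")
  } else {
    molecule
  }
  any(glob_match(sig$name_pattern, candidates))
}

part_row_associated <- function(row) {
  mols <- vapply(row$regulation[[1]], `[[`, character(1), "molecule")
  if (!is.na(row$codes_for)) mols <- c(mols, row$codes_for)
  unique(mols)
}

match_part_row <- function(sig, row, reg) {
  res <- TRUE
  # compartment chain matches as a suffix of the part's full path
  if (length(sig$compartments) > 0) {
    path <- row$path[[1]]
    k <- length(sig$compartments)
    if (k > length(path)) {
      res <- FALSE
    } else {
      tail_path <- path[(length(path) - k + 1L):length(path)]
      res <- all(mapply(glob_match, sig$compartments, tail_path))
    }
  }
  if (res) {
    # instance name first, then type name; '+' extends to ancestor type names
    candidates <- if (sig$include_subtypes) {
      type_ancestry(reg, row$part_type, "part")
    } else {
      row$part_type
    }
    res <- any(glob_match(sig$name_pattern, c(row$name, candidates)))
  }
  if (res && !is.null(sig$molecule_sig)) {
    assoc <- part_row_associated(row)
    if (sig$molecule_sig$require_none) {
      res <- length(assoc) == 0
    } else {
      res <- length(assoc) > 0 &&
        any(vapply(assoc, function(m) match_molecule(sig$molecule_sig, m, reg),
                   logical(1)))
    }
  }
  if (sig$negated) !res else res
}

#' Match a part signature against one part of a flow
#'
#' @param sig A parsed part signature or its text.
#' @param flow An execution flow from [linearize()].
#' @param index Position of the part within [flow_parts()] (1-based), or a
#'   part's instance name present exactly once in the flow.
#' @param reg The registry; defaults to the flow's.
#' @return Logical scalar.
#' @export
match_part <- function(sig, flow, index, reg = attr(flow, "registry")) {
  if (is.character(sig)) sig <- parse_part_signature(sig)
  parts <- flow_parts(flow)
  if (is.character(index)) {
    index <- which(parts$name == index)
    if (length(index) != 1L) {
      stop("part name does not identify a unique flow part", call. = FALSE)
    }
  }
  stopifnot(index >= 1, index <= nrow(parts))
  match_part_row(sig, parts[index, , drop = FALSE], reg)
}

#' Evaluate a point-cut expression over a flow
#'
#' A match is a run of consecutive parts, all within the same compartment,
#' where the i-th signature of the chain matches the i-th part of the run.
#' The returned context rows are the parts matched by the final signature.
#'
#' @param expr A [parse_pointcut_expression()] result or its text.
#' @param flow An execution flow.
#' @param reg The registry; defaults to the flow's.
#' @return A tibble of context part rows (possibly zero rows), with a
#'   `context_index` column giving the part's position in [flow_parts()].
#' @export
match_expression <- function(expr, flow, reg = attr(flow, "registry")) {
  if (is.character(expr)) expr <- parse_pointcut_expression(expr)
  parts <- flow_parts(flow)
  k <- length(expr$chain)
  hits <- integer()
  n <- nrow(parts)
  if (n >= k && n > 0) {
    for (start in seq_len(n - k + 1L)) {
      run <- start:(start + k - 1L)
      paths <- parts$path[run]
      same_comp <- all(vapply(paths, identical, logical(1), paths[[1]]))
      if (!same_comp) next
      ok <- all(vapply(seq_len(k), function(i) {
        match_part_row(expr$chain[[i]], parts[run[[i]], , drop = FALSE], reg)
      }, logical(1)))
      if (ok) hits <- c(hits, start + k - 1L)
    }
  }
  hits <- unique(hits)
  out <- parts[hits, , drop = FALSE]
  out$context_index <- hits
  out
}
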
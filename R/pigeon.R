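#' Emit a Pigeon circuit-diagram script
#'
#' Writes one Pigeon statement per part of the woven flow, in flow order,
#' using the standard glyph codes (`p` promoter, `r` RBS, `c` coding region,
#' `t` terminator), followed by the regulation arcs in Pigeon's `rep`/`ind`
#' edge syntax. Part types with no glyph mapping get a generic glyph with a
#' warning. Output is deterministic.
#'
#' @param woven A `cw_woven` (or a `cw_flow`).
#' @param file Optional output path.
#' @return Character vector of script lines; invisibly when `file` is given.
#' @export
emit_pigeon <- function(woven, file = NULL) {
  flow <- if (inherits(woven, "cw_woven")) woven$flow else woven
  reg <- if (inherits(woven, "cw_woven")) woven$registry else attr(flow, "registry")
  parts <- flow_parts(flow)
  glyph_of <- function(tp) {
    if (is_subtype(reg, tp, "Promoter", "part")) "p"
    else if (is_subtype(reg, tp, "RBS", "part")) "r"
    else if (is_subtype(reg, tp, "CodingRegion", "part")) "c"
    else if (is_subtype(reg, tp, "Terminator", "part")) "t"
    else {
      warning("no Pigeon glyph for part type '", tp, "'; using generic glyph",
              call. = FALSE)
      "v"
    }
  }
  lines <- character()
  for (i in seq_len(nrow(parts))) {
    colour <- (i - 1L) %% 13L + 1L
    lines <- c(lines, paste(glyph_of(parts$part_type[[i]]), parts$name[[i]],
                            colour))
  }
  arcs <- character()
  for (i in seq_len(nrow(parts))) {
    for (r in parts$regulation[[i]]) {
      edge <- if (r$sign == "negative") "rep" else "ind"
      arcs <- c(arcs, paste(r$molecule, edge, parts$name[[i]]))
    }
  }
  if (length(arcs) > 0) lines <- c(lines, "# Arcs", arcs)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
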
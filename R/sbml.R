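# R expression -> MathML (content markup), covering the operator set used by
# generated rate laws: + - * / ^ and parenthesised subexpressions
expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    return(paste0("<cn>", format(e, digits = 15), "</cn>"))
  }
  if (is.name(e)) {
    return(paste0("<ci>", as.character(e), "</ci>"))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(expr_to_mathml(e[[2]]))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", NULL)
    if (is.null(tag)) {
      stop("cannot convert operator '", op, "' to MathML", call. = FALSE)
    }
    args <- vapply(as.list(e)[-1], expr_to_mathml, character(1))
    return(paste0("<apply><", tag, "/>", paste(args, collapse = ""), "</apply>"))
  }
  stop("cannot convert expression to MathML", call. = FALSE)
}

mathml_to_expr_text <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(trimws(xml2::xml_text(node)))
  if (nm == "cn") return(trimws(xml2::xml_text(node)))
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    return(mathml_to_expr_text(kids[[1]]))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- switch(xml2::xml_name(kids[[1]]),
                 plus = "+", minus = "-", times = "*", divide = "/",
                 power = "^",
                 stop("unsupported MathML operator", call. = FALSE))
    args <- vapply(kids[-1], mathml_to_expr_text, character(1))
    return(paste0("(", paste(args, collapse = paste0(" ", op, " ")), ")"))
  }
  stop("unsupported MathML node: ", nm, call. = FALSE)
}

#' Export a reaction model to SBML
#'
#' Writes an SBML Level 3 Version 1 document: one compartment (`cell`), all
#' species with initial amounts, all parameters, and one reaction per model
#' reaction with its rate law as a MathML `kineticLaw`. The document is
#' checked structurally before it is returned (unique ids, every species and
#' parameter referenced by a rate law defined).
#'
#' @param model A `cw_reaction_model`.
#' @param file Optional path to write the document to.
#' @param model_id SBML model id.
#' @return An `xml_document`, invisibly when `file` is given.
#' @export
export_sbml <- function(model, file = NULL, model_id = "circuit_model") {
  stopifnot(inherits(model, "cw_reaction_model"))
  known <- c(model$species$name, names(model$parameters))
  for (law in model$reactions$rate_law) {
    used <- all.vars(parse(text = law)[[1]])
    bad <- setdiff(used, known)
    if (length(bad) > 0) {
      stop("SBML export error: rate law references undefined symbol(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('<model id="%s" substanceUnits="item" timeUnits="second" extentUnits="item">', model_id),
    '<listOfCompartments>',
    '<compartment id="cell" spatialDimensions="3" size="1" constant="true"/>',
    '</listOfCompartments>'
  )
  if (nrow(model$species) > 0) {
    lines <- c(lines, '<listOfSpecies>',
      sprintf(paste0('<species id="%s" compartment="cell" initialAmount="%s" ',
                     'hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>'),
              model$species$name, format(model$species$initial, digits = 15)),
      '</listOfSpecies>')
  }
  if (length(model$parameters) > 0) {
    lines <- c(lines, '<listOfParameters>',
      sprintf('<parameter id="%s" value="%s" constant="true"/>',
              names(model$parameters),
              format(unname(model$parameters), digits = 15)),
      '</listOfParameters>')
  }
  if (nrow(model$reactions) > 0) {
    rx_lines <- unlist(lapply(seq_len(nrow(model$reactions)), function(j) {
      r <- model$reactions[j, ]
      re <- r$reactants[[1]]; pr <- r$products[[1]]
      out <- sprintf('<reaction id="%s" reversible="false">', r$name)
      if (length(re) > 0) {
        out <- c(out, '<listOfReactants>',
          sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                  names(re), as.integer(unlist(re))),
          '</listOfReactants>')
      }
      if (length(pr) > 0) {
        out <- c(out, '<listOfProducts>',
          sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                  names(pr), as.integer(unlist(pr))),
          '</listOfProducts>')
      }
      math <- expr_to_mathml(parse(text = r$rate_law)[[1]])
      c(out, '<kineticLaw>',
        paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', math, '</math>'),
        '</kineticLaw>', '</reaction>')
    }))
    lines <- c(lines, '<listOfReactions>', rx_lines, '</listOfReactions>')
  }
  lines <- c(lines, '</model>', '</sbml>')
  doc <- xml2::read_xml(paste(esc(lines), collapse = "\n"))
  validate_sbml(doc)
  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Structural validation of an SBML document
#'
#' Checks the constraints the package relies on: SBML L3V1 root, a model
#' element, unique species/parameter/reaction ids, and that every species
#' referenced by a reaction is declared.
#'
#' @param doc An `xml_document`.
#' @return `TRUE` invisibly; otherwise an error describing the defect.
#' @export
validate_sbml <- function(doc) {
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") stop("not an SBML document", call. = FALSE)
  model <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(model, "xml_missing")) stop("SBML document has no model", call. = FALSE)
  ids <- function(xpath) xml2::xml_attr(xml2::xml_find_all(doc, xpath, ns), "id")
  sp <- ids(".//s:listOfSpecies/s:species")
  pa <- ids(".//s:listOfParameters/s:parameter")
  rx <- ids(".//s:listOfReactions/s:reaction")
  for (v in list(sp, pa, rx)) {
    if (anyDuplicated(v)) stop("duplicate ids in SBML document", call. = FALSE)
  }
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:speciesReference", ns), "species")
  bad <- setdiff(refs, sp)
  if (length(bad) > 0) {
    stop("SBML reaction references undeclared species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Import an SBML document back into a reaction model
#'
#' Reads a document written by [export_sbml()] and reconstructs species,
#' reactions (with rate laws recovered from MathML) and parameters; used for
#' round-trip checks.
#'
#' @param x Path to an SBML file or an `xml_document`.
#' @return A `cw_reaction_model`.
#' @export
import_sbml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  validate_sbml(doc)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          m = "http://www.w3.org/1998/Math/MathML")
  model <- empty_model("imported")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  for (n in sp_nodes) {
    model <- add_species(model, xml2::xml_attr(n, "id"), "imported",
                         as.numeric(xml2::xml_attr(n, "initialAmount")))
  }
  pa_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  params <- stats::setNames(
    as.numeric(xml2::xml_attr(pa_nodes, "value")),
    xml2::xml_attr(pa_nodes, "id"))
  model$parameters <- params
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  for (n in rx_nodes) {
    side <- function(xpath) {
      refs <- xml2::xml_find_all(n, xpath, ns)
      stats::setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    math <- xml2::xml_find_first(n, ".//m:math", ns)
    law <- mathml_to_expr_text(math)
    model$reactions <- dplyr::bind_rows(
      model$reactions,
      tibble::tibble(name = xml2::xml_attr(n, "id"),
                     reactants = list(side("./s:listOfReactants/s:speciesReference")),
                     products = list(side("./s:listOfProducts/s:speciesReference")),
                     rate_law = law, parameter = NA_character_,
                     category = "imported", mass_action = NA))
  }
  model
}
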
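#' Create a part/molecule type registry
#'
#' A registry holds the two rooted type trees used by circuit designs: genetic
#' part types (root `Part`) and molecule types (root `Molecule`). The built-in
#' part hierarchy is `Part` with children `Promoter` (itself parent of
#' `PositivePromoter`, `NegativePromoter` and `ConstitutivePromoter`), `RBS`,
#' `CodingRegion` and `Terminator`; the built-in molecule hierarchy is
#' `Molecule` with child `Protein`. Users add concrete subtypes (for example a
#' specific BioBrick RBS, or a transcription factor) with
#' [declare_part_type()] and [declare_molecule_type()].
#'
#' The registry is an environment, so declarations are visible everywhere the
#' registry object is shared. Identifier matching is case-sensitive.
#'
#' @return An object of class `cw_registry`.
#' @examples
#' reg <- new_registry()
#' declare_molecule_type(reg, "TetR", parent = "Protein")
#' is_subtype(reg, "TetR", "Molecule")
#' @export
new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$part <- c(
    Part = NA_character_,
    Promoter = "Part",
    PositivePromoter = "Promoter",
    NegativePromoter = "Promoter",
    ConstitutivePromoter = "Promoter",
    RBS = "Part",
    CodingRegion = "Part",
    Terminator = "Part"
  )
  reg$molecule <- c(Molecule = NA_character_, Protein = "Molecule")
  class(reg) <- "cw_registry"
  reg
}

#' @export
print.cw_registry <- function(x, ...) {
  cat("<cw_registry> ", length(x$part), " part types, ",
      length(x$molecule), " molecule types\n", sep = "")
  invisible(x)
}

registry_kind <- function(reg, name) {
  in_part <- name %in% names(reg$part)
  in_mol <- name %in% names(reg$molecule)
  if (in_part && !in_mol) return("part")
  if (in_mol && !in_part) return("molecule")
  if (in_part && in_mol) return("both")
  NA_character_
}

declare_type <- function(reg, kind, name, parent) {
  stopifnot(inherits(reg, "cw_registry"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("type name must be a single non-empty string", call. = FALSE)
  }
  if (identical(name, parent)) {
    stop("type '", name, "' cannot be its own parent (type tree must be acyclic)",
         call. = FALSE)
  }
  tree <- reg[[kind]]
  if (name %in% names(tree)) {
    stop("duplicate ", kind, " type name: '", name, "'", call. = FALSE)
  }
  if (!parent %in% names(tree)) {
    stop("unknown parent ", kind, " type: '", parent, "'", call. = FALSE)
  }
  tree[[name]] <- parent
  reg[[kind]] <- tree
  invisible(reg)
}

#' Declare a new part or molecule type
#'
#' Registers `name` as a child of `parent` in the registry's type tree. The
#' tree is rooted (at `Part` or `Molecule`), acyclic and has unique names, so
#' redeclaring a name or naming an unknown parent is an error.
#'
#' @param reg A registry from [new_registry()].
#' @param name New type name (case-sensitive identifier).
#' @param parent Name of an existing type; defaults to the tree root.
#' @return The registry, invisibly.
#' @export
declare_part_type <- function(reg, name, parent = "Part") {
  declare_type(reg, "part", name, parent)
}

#' @rdname declare_part_type
#' @export
declare_molecule_type <- function(reg, name, parent = "Molecule") {
  declare_type(reg, "molecule", name, parent)
}

#' Ancestor path of a type
#'
#' @param reg A registry.
#' @param name A registered type name.
#' @param kind `"part"` or `"molecule"`; if `NULL`, inferred from the name.
#' @return Character vector from `name` up to the tree root, inclusive.
#' @export
type_ancestry <- function(reg, name, kind = NULL) {
  if (is.null(kind)) {
    kind <- registry_kind(reg, name)
    if (identical(kind, "both")) {
      stop("'", name, "' names both a part and a molecule type; pass `kind`",
           call. = FALSE)
    }
    if (is.na(kind)) stop("unknown type: '", name, "'", call. = FALSE)
  }
  tree <- reg[[kind]]
  if (!name %in% names(tree)) {
    stop("unknown ", kind, " type: '", name, "'", call. = FALSE)
  }
  path <- character()
  cur <- name
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- tree[[cur]]
  }
  path
}

#' Test the subtype relation
#'
#' `is_subtype(reg, a, b)` is `TRUE` iff `b` lies on `a`'s ancestor path
#' (inclusive, so every type is a subtype of itself). Both names must belong
#' to the same tree; comparing a part type with a molecule type is an error.
#'
#' @inheritParams type_ancestry
#' @param a,b Registered type names of the same kind.
#' @return Logical scalar.
#' @export
is_subtype <- function(reg, a, b, kind = NULL) {
  if (is.null(kind)) {
    ka <- registry_kind(reg, a)
    kb <- registry_kind(reg, b)
    if (is.na(ka)) stop("unknown type: '", a, "'", call. = FALSE)
    if (is.na(kb)) stop("unknown type: '", b, "'", call. = FALSE)
    kind <- if (identical(ka, "both")) kb else ka
    if (identical(kind, "both")) kind <- "part"
    kb2 <- if (identical(kb, "both")) kind else kb
    ka2 <- if (identical(ka, "both")) kind else ka
    if (!identical(ka2, kb2)) {
      stop("cannot compare a ", ka2, " type ('", a, "') with a ", kb2,
           " type ('", b, "')", call. = FALSE)
    }
  }
  b %in% type_ancestry(reg, a, kind)
}
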
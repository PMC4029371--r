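#' Hydrogen-suppressed molecular graph
#'
#' A \code{MolGraph} holds a small molecule as a labeled graph: heavy atoms
#' (periodic element symbol, formal charge, 2D Molfile coordinates, implicit
#' hydrogen count recorded at parse time) and bonds (1-based atom indices,
#' integer order 1/2/3). Explicit hydrogens present in the input are removed
#' on construction and only survive as the per-atom \code{hcount}.
#'
#' @slot id character(1), free-text identifier (Molfile title line).
#' @slot atoms data.frame with columns \code{element}, \code{charge},
#'   \code{x}, \code{y}, \code{hcount}.
#' @slot bonds data.frame with columns \code{a}, \code{b}, \code{order},
#'   \code{stereo} (stereo flags are carried through but never interpreted).
#'
#' @exportClass MolGraph
setClass("MolGraph",
  representation(id = "character", atoms = "data.frame", bonds = "data.frame"))

setValidity("MolGraph", function(object) {
  at <- object@atoms
  bd <- object@bonds
  msgs <- character(0)
  need_at <- c("element", "charge", "x", "y", "hcount")
  need_bd <- c("a", "b", "order", "stereo")
  if (!all(need_at %in% names(at))) {
    return(paste("atoms must have columns", paste(need_at, collapse = ", ")))
  }
  if (!all(need_bd %in% names(bd))) {
    return(paste("bonds must have columns", paste(need_bd, collapse = ", ")))
  }
  n <- nrow(at)
  if (any(at$element == "H")) msgs <- c(msgs, "explicit hydrogens must be suppressed")
  if (nrow(bd)) {
    if (any(bd$a < 1L | bd$a > n | bd$b < 1L | bd$b > n)) {
      msgs <- c(msgs, "bond atom indices out of range")
    }
    if (any(bd$a == bd$b)) msgs <- c(msgs, "self-loop bond")
    key <- paste(pmin(bd$a, bd$b), pmax(bd$a, bd$b))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bond")
    if (!all(bd$order %in% c(1L, 2L, 3L))) {
      msgs <- c(msgs, "bond orders must be 1, 2 or 3 after kekulization")
    }
  }
  if (n && any(!is.finite(at$x) | !is.finite(at$y))) {
    msgs <- c(msgs, "coordinates must be finite")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' KEGG-atom-typed compound with perceived rings and substructures
#'
#' The central container of the package: a \code{MolGraph} plus its perceived
#' ring system, one KEGG atom type (k3 label) per heavy atom, and, once
#' \code{\link{extractSubstructures}} has run, the enumerated substructure
#' instances of the seven attributes.
#'
#' @slot graph a \code{MolGraph}.
#' @slot kind character(1): "Compound" or "Drug" (ENTRY line of KCF output).
#' @slot labels character vector, one k3 KEGG atom type per heavy atom.
#' @slot rings list as returned by \code{\link{perceiveRings}} (after
#'   aromaticity perception).
#' @slot substructures list of substructure instances (possibly empty before
#'   extraction); each instance is a list with elements \code{attribute},
#'   \code{canonical}, \code{atoms} and attribute-specific recipe fields.
#'
#' @exportClass KcfCompound
setClass("KcfCompound",
  representation(graph = "MolGraph", kind = "character", labels = "character",
                 rings = "list", substructures = "list"))

setValidity("KcfCompound", function(object) {
  n <- nrow(object@graph@atoms)
  if (length(object@labels) != n) {
    return("one atom-type label per heavy atom required")
  }
  fam <- substr(object@labels, 1L, 1L)
  el <- object@graph@atoms$element
  expected <- ifelse(el %in% c("F", "Cl", "Br", "I"), "X",
               ifelse(el %in% c("C", "N", "O", "S", "P"), el, "Z"))
  if (n && any(fam != expected)) {
    return("label family character inconsistent with element")
  }
  TRUE
})

#' KCF-S count descriptor
#'
#' Multiset of canonical substructure strings with positive integer counts at
#' a stated resolution level (k1 = element, k2 = atom class, k3 = full atom
#' type). Keys are tagged with their attribute as \code{"ATTR:string"} so the
#' seven attribute namespaces cannot collide.
#'
#' @slot level integer(1), 1, 2 or 3.
#' @slot counts named integer vector, all values >= 1.
#' @slot attrs character vector, the attribute of each key (parallel to
#'   \code{counts}).
#'
#' @exportClass KcfsDescriptor
setClass("KcfsDescriptor",
  representation(level = "integer", counts = "integer", attrs = "character"))

setValidity("KcfsDescriptor", function(object) {
  if (!(object@level %in% 1:3)) return("level must be 1, 2 or 3")
  if (length(object@counts) && (is.null(names(object@counts)) ||
                                any(!nzchar(names(object@counts))))) {
    return("counts must be named")
  }
  if (any(object@counts < 1L)) return("all counts must be >= 1")
  if (anyDuplicated(names(object@counts))) return("duplicate keys")
  if (length(object@attrs) != length(object@counts)) {
    return("attrs must parallel counts")
  }
  TRUE
})

#' Ordered feature space for descriptor projection
#'
#' A frozen, ordered list of descriptor keys derived from a training corpus.
#' Optionally capped to the \code{cap} keys present in the largest number of
#' training molecules (ties broken lexicographically).
#'
#' @slot keys character vector of tagged descriptor keys, unique, ordered.
#' @slot cap integer(1), the requested cap (NA when uncapped).
#'
#' @exportClass FeatureSpace
setClass("FeatureSpace",
  representation(keys = "character", cap = "integer"))

setValidity("FeatureSpace", function(object) {
  if (anyDuplicated(object@keys)) return("keys must be unique")
  TRUE
})

#' Linear SVM model over pair-feature vectors
#'
#' Weight vector and intercept of an L1- (or L2-) regularized squared-hinge
#' linear SVM trained on compound-pair feature vectors.
#'
#' @slot w named numeric weight vector (one entry per feature).
#' @slot bias numeric(1) intercept (unpenalized).
#' @slot cost numeric(1) regularization strength (loss weight).
#' @slot penalty character(1), "l1" or "l2".
#' @slot mode character(1), "diff-common" or "diff-only".
#'
#' @exportClass SvmModel
setClass("SvmModel",
  representation(w = "numeric", bias = "numeric", cost = "numeric",
                 penalty = "character", mode = "character"))

setMethod("show", "MolGraph", function(object) {
  cat(sprintf("MolGraph '%s': %d heavy atoms, %d bonds\n",
              object@id, nrow(object@atoms), nrow(object@bonds)))
  if (nrow(object@atoms)) {
    tab <- table(object@atoms$element)
    cat("  formula (heavy): ",
        paste0(names(tab), ifelse(tab > 1, tab, ""), collapse = " "), "\n")
  }
})

setMethod("show", "KcfCompound", function(object) {
  cat(sprintf("KcfCompound '%s' (%s): %d atoms typed\n",
              object@graph@id, object@kind, length(object@labels)))
  if (length(object@labels)) {
    tab <- sort(table(object@labels), decreasing = TRUE)
    cat("  labels:", paste0(names(tab), "x", tab, collapse = " "), "\n")
  }
  if (length(object@substructures)) {
    at <- vapply(object@substructures, `[[`, character(1), "attribute")
    cat("  substructure instances:",
        paste0(names(table(at)), "=", table(at), collapse = " "), "\n")
  }
})

setMethod("show", "KcfsDescriptor", function(object) {
  cat(sprintf("KcfsDescriptor (k%d): %d distinct keys, total count %d\n",
              object@level, length(object@counts), sum(object@counts)))
})

setMethod("show", "FeatureSpace", function(object) {
  cat(sprintf("FeatureSpace: %d keys%s\n", length(object@keys),
              if (is.na(object@cap)) "" else sprintf(" (capped at %d)", object@cap)))
})

setMethod("show", "SvmModel", function(object) {
  nz <- sum(object@w != 0)
  cat(sprintf("SvmModel (%s, %s): %d features, %d nonzero weights, C=%g\n",
              object@penalty, object@mode, length(object@w), nz, object@cost))
})
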
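# KCF-S descriptors: integer count vectors over canonical substructure
# strings, the weighted Jaccard similarity, and the pair-feature algebra
# (meet / positive difference) used for reaction-likeness prediction.

#' Build a KCF-S descriptor from a typed compound
#'
#' Counts canonical substructure strings at the requested hierarchy level.
#' For k1/k2 the per-atom labels are truncated and every substructure is
#' re-canonicalized through the same extraction code, so truncated strings
#' are re-sorted exactly as the full-level strings were. Keys are tagged
#' \code{"ATTR:string"}.
#'
#' @param cpd a \code{\link{KcfCompound}} (substructures are extracted on
#'   the fly if absent).
#' @param level 1, 2 or 3.
#' @param attrs attributes to include: "all" or a character vector from
#'   ATOM, BOND, TRIPLET, VICINITY, RING, SKELETON, INORGANIC.
#' @return a \code{\link{KcfsDescriptor}}.
#' @examples
#' d <- buildDescriptor(kcfCompound(builtinMolecule("alanine")))
#' descriptorCounts(d)[1:5]
#' @export
buildDescriptor <- function(cpd, level = 3, attrs = "all") {
  stopifnot(is(cpd, "KcfCompound"))
  level <- as.integer(level)
  if (!(level %in% 1:3)) .stopf("level must be 1, 2 or 3")
  if (identical(attrs, "all")) attrs <- .KCF_ATTRS
  if (!all(attrs %in% .KCF_ATTRS)) {
    .stopf("unknown attribute(s): %s", paste(setdiff(attrs, .KCF_ATTRS), collapse = ", "))
  }
  ins <- if (level == 3L) {
    if (length(cpd@substructures)) cpd@substructures
    else extractAll(cpd@graph, cpd@labels, cpd@rings)
  } else {
    extractAll(cpd@graph, truncateLabel(cpd@labels, level), cpd@rings)
  }
  ins <- ins[vapply(ins, `[[`, character(1), "attribute") %in% attrs]
  if (!length(ins)) {
    return(new("KcfsDescriptor", level = level,
               counts = stats::setNames(integer(0), character(0)),
               attrs = character(0)))
  }
  keys <- vapply(ins, function(x) paste0(x$attribute, ":", x$canonical),
                 character(1))
  tab <- table(keys)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts <- counts[order(names(counts), method = "radix")]
  attr_of <- sub(":.*$", "", names(counts))
  new("KcfsDescriptor", level = level, counts = counts, attrs = attr_of)
}

#' Weighted Jaccard similarity of two descriptors
#'
#' Sum of elementwise minima over sum of elementwise maxima across the key
#' union. Two empty descriptors compare as 1.0 (documented convention).
#' Levels must match.
#'
#' @param a,b \code{\link{KcfsDescriptor}} objects at the same level.
#' @return numeric(1) in [0, 1].
#' @examples
#' d <- buildDescriptor(kcfCompound(builtinMolecule("ethanol")))
#' weightedJaccard(d, d)  # 1
#' @export
weightedJaccard <- function(a, b) {
  stopifnot(is(a, "KcfsDescriptor"), is(b, "KcfsDescriptor"))
  if (a@level != b@level) {
    .stopf("descriptor level mismatch (k%d vs k%d)", a@level, b@level)
  }
  keys <- union(names(a@counts), names(b@counts))
  if (!length(keys)) return(1.0)
  va <- numeric(length(keys)); vb <- numeric(length(keys))
  va[match(names(a@counts), keys)] <- a@counts
  vb[match(names(b@counts), keys)] <- b@counts
  sum(pmin(va, vb)) / sum(pmax(va, vb))
}

#' Construct a feature space from training descriptors
#'
#' The key list is the union of keys over the corpus, sorted
#' lexicographically. With a cap \code{n}, the \code{n} keys present in the
#' largest number of training molecules are kept (ties broken
#' lexicographically).
#'
#' @param descriptors list of \code{\link{KcfsDescriptor}} objects.
#' @param cap optional integer: maximum dimension.
#' @return a \code{\link{FeatureSpace}}.
#' @export
featureSpace <- function(descriptors, cap = NULL) {
  all_keys <- lapply(descriptors, function(d) names(descriptorCounts(d)))
  keys <- .byte_sort(unique(unlist(all_keys)))
  if (!is.null(cap) && length(keys) > cap) {
    presence <- table(unlist(lapply(all_keys, unique)))
    presence <- presence[keys]
    ord <- order(-as.integer(presence), keys, method = "radix")
    keys <- .byte_sort(keys[ord[seq_len(cap)]])
  }
  new("FeatureSpace", keys = keys,
      cap = if (is.null(cap)) NA_integer_ else as.integer(cap))
}

#' Project a descriptor onto a feature space
#'
#' @param d a \code{\link{KcfsDescriptor}}.
#' @param space a \code{\link{FeatureSpace}}.
#' @return named numeric vector of length \code{length(space)} (keys absent
#'   from the descriptor are 0; keys outside the space are dropped).
#' @export
projectDescriptor <- function(d, space) {
  stopifnot(is(d, "KcfsDescriptor"), is(space, "FeatureSpace"))
  v <- stats::setNames(numeric(length(space@keys)), space@keys)
  hit <- intersect(names(d@counts), space@keys)
  v[hit] <- d@counts[hit]
  v
}

#' Elementwise minimum of two feature vectors
#'
#' The meet operation captures the substructure counts common to both
#' compounds.
#'
#' @param x,y numeric vectors of equal length.
#' @return numeric vector \code{pmin(x, y)}.
#' @export
featureMeet <- function(x, y) {
  stopifnot(length(x) == length(y))
  pmin(x, y)
}

#' Positive elementwise difference of two feature vectors
#'
#' Captures substructure counts present in \code{x} beyond those in
#' \code{y}: \code{pmax(x - y, 0)}.
#'
#' @param x,y numeric vectors of equal length.
#' @return numeric vector.
#' @export
featureDiff <- function(x, y) {
  stopifnot(length(x) == length(y))
  pmax(x - y, 0)
}

#' Pair feature vector for an ordered compound pair
#'
#' diff-common mode: (meet, x minus y, y minus x), length 3D; diff-only
#' mode: the two difference blocks, length 2D. Block names are prefixed
#' \code{common:}, \code{fwd:}, \code{rev:}.
#'
#' @param a,b \code{\link{KcfsDescriptor}} objects (ordered: a is the
#'   substrate side).
#' @param mode "diff-common" or "diff-only".
#' @param space a \code{\link{FeatureSpace}}.
#' @return named numeric vector of length 3D or 2D.
#' @export
pairFeatures <- function(a, b, mode = c("diff-common", "diff-only"), space) {
  if (!(length(mode) %in% c(1L, 2L)) || !all(mode %in% c("diff-common", "diff-only"))) {
    .stopf("unknown pair-feature mode: %s", paste(mode, collapse = ","))
  }
  mode <- match.arg(mode)
  va <- projectDescriptor(a, space)
  vb <- projectDescriptor(b, space)
  fwd <- stats::setNames(featureDiff(va, vb), paste0("fwd:", names(va)))
  rev_ <- stats::setNames(featureDiff(vb, va), paste0("rev:", names(va)))
  if (mode == "diff-common") {
    com <- stats::setNames(featureMeet(va, vb), paste0("common:", names(va)))
    c(com, fwd, rev_)
  } else {
    c(fwd, rev_)
  }
}
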
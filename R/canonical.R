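# Canonical linear strings for labeled backbones.
#
# A substructure string is a backbone (path or cycle) of atom type labels
# joined by "-", where each backbone atom may carry parenthesized
# substituent groups. The canonical representative is the byte-wise smallest
# rendering over every admissible traversal (all rotations and both
# directions for cycles; both directions for paths). Substituent groups are
# fixed per atom before traversal enumeration:
#   * single-atom substituents form one "(a+b+c)" group, members sorted;
#   * multi-atom branches are rendered recursively and each forms its own
#     "(...)" group; groups are ordered by decreasing rendered length, ties
#     alphabetically.

# one "+"-joined group from single-atom labels (RING, VICINITY, and the
# heteroatom annotations of SKELETON)
.group_plus <- function(singles) {
  if (!length(singles)) return(character(0))
  paste0("(", paste(.byte_sort(singles), collapse = "+"), ")")
}

# every item its own group, longest rendering first, ties alphabetical
# (INORGANIC attachments)
.group_separate <- function(items) {
  if (!length(items)) return(character(0))
  paste0("(", items[order(-nchar(items), items, method = "radix")], ")")
}

# multi-atom branch groups first (longest first, ties alphabetical), then
# the single-atom "+" group (SKELETON)
.group_mixed <- function(multis, singles) {
  c(.group_separate(multis), .group_plus(singles))
}

.render_traversal <- function(labels, attach_str) {
  paste(paste0(labels, attach_str), collapse = "-")
}

#' Canonical string of a labeled backbone
#'
#' Returns the lexicographically smallest rendering of a labeled path or
#' cycle over all admissible traversals (every start atom and both
#' directions for cycles, both directions for paths). Backbone labels are
#' joined by \code{-}; each position's substituent groups (already rendered,
#' including parentheses) are appended to its label unchanged.
#'
#' @param labels character vector of backbone atom type labels, in backbone
#'   order.
#' @param attachments optional list (parallel to \code{labels}) of character
#'   vectors of rendered substituent groups, e.g. \code{c("(C1b)")}.
#' @param cyclic logical(1): treat the backbone as a cycle.
#' @return character(1), the canonical string.
#' @examples
#' canonicalLinearString(rep("C8x", 6), cyclic = TRUE)
#' @export
canonicalLinearString <- function(labels, attachments = NULL, cyclic = FALSE) {
  n <- length(labels)
  if (n == 0L) .stopf("empty backbone")
  if (is.null(attachments)) attachments <- rep(list(character(0)), n)
  att <- vapply(attachments, paste0, character(1), collapse = "")
  best <- NULL
  if (cyclic) {
    idx <- seq_len(n)
    for (s in idx) {
      for (dir in c(1L, -1L)) {
        ord <- if (dir == 1L) ((idx - 1L + s - 1L) %% n) + 1L
               else ((s - idx) %% n) + 1L
        cand <- .render_traversal(labels[ord], att[ord])
        if (is.null(best) || .str_lt(cand, best)) best <- cand
      }
    }
  } else {
    f <- .render_traversal(labels, att)
    r <- .render_traversal(rev(labels), rev(att))
    best <- if (.str_le(f, r)) f else r
  }
  best
}

# Linear rendering with the backbone-selection tie-break used by SKELETON
# and INORGANIC: candidates are first compared on the bare (unsubstituted)
# label sequence of the better direction, then on the full rendering. This
# reproduces strings such as "O1c-P1b(O2b(C1b))(O1c)-O1c", where the two
# plain hydroxy oxygens form the backbone even though the full rendering
# through the ester oxygen would compare smaller.
.chain_candidate <- function(labels, attachments) {
  att <- vapply(attachments, paste0, character(1), collapse = "")
  bare_f <- paste(labels, collapse = "-")
  bare_r <- paste(rev(labels), collapse = "-")
  if (.str_lt(bare_f, bare_r)) {
    list(bare = bare_f, full = .render_traversal(labels, att))
  } else if (.str_lt(bare_r, bare_f)) {
    list(bare = bare_r, full = .render_traversal(rev(labels), rev(att)))
  } else {
    f <- .render_traversal(labels, att)
    r <- .render_traversal(rev(labels), rev(att))
    list(bare = bare_f, full = if (.str_le(f, r)) f else r)
  }
}

.better_candidate <- function(a, b) {
  if (is.null(b)) return(a)
  if (.str_lt(a$bare, b$bare)) return(a)
  if (.str_lt(b$bare, a$bare)) return(b)
  if (.str_le(a$full, b$full)) a else b
}
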
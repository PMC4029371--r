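# Characteristic-substructure ranking: for each canonical string present in
# either molecule set, count the molecules that do or do not contain it and
# rank by the one-sided Fisher's exact test (enriched in set A).

#' Rank substructures characteristic of one molecule set versus another
#'
#' Builds the 2x2 presence table (presence = count >= 1 in the molecule) for
#' every descriptor key in the union of the two sets and computes Fisher's
#' exact test per key. Rows are sorted by ascending p-value, ties by key.
#'
#' @param A,B non-empty lists of \code{\link{KcfsDescriptor}} objects.
#' @param alternative "greater" (default: enriched in A) or "two.sided".
#' @param adjust logical: add a Benjamini-Hochberg adjusted column
#'   \code{p_adj} (off by default; ranks follow the raw p-value).
#' @return data.frame with columns \code{key}, \code{attribute},
#'   \code{canonical}, \code{a}, \code{b}, \code{c}, \code{d}, \code{p}
#'   (and \code{p_adj} when requested): \code{a}/\code{b} molecules in A
#'   containing/lacking the substructure, \code{c}/\code{d} likewise in B.
#' @export
substructureEnrichment <- function(A, B, alternative = c("greater", "two.sided"),
                                   adjust = FALSE) {
  alternative <- match.arg(alternative)
  if (!length(A) || !length(B)) .stopf("both molecule sets must be non-empty")
  keys_a <- lapply(A, function(d) names(descriptorCounts(d)))
  keys_b <- lapply(B, function(d) names(descriptorCounts(d)))
  keys <- .byte_sort(unique(c(unlist(keys_a), unlist(keys_b))))
  nA <- length(A); nB <- length(B)
  cnt_a <- table(factor(unlist(lapply(keys_a, unique)), levels = keys))
  cnt_b <- table(factor(unlist(lapply(keys_b, unique)), levels = keys))
  a <- as.integer(cnt_a)
  c_ <- as.integer(cnt_b)
  b <- nA - a
  d <- nB - c_
  p <- vapply(seq_along(keys), function(i) {
    stats::fisher.test(matrix(c(a[i], c_[i], b[i], d[i]), nrow = 2),
                       alternative = alternative)$p.value
  }, numeric(1))
  out <- data.frame(
    key = keys,
    attribute = sub(":.*$", "", keys),
    canonical = sub("^[A-Z]+:", "", keys),
    a = a, b = b, c = c_, d = d, p = p,
    stringsAsFactors = FALSE)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
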
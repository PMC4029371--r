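# Quasi-clique agglomerative clustering (QCC variant) over weighted-Jaccard
# similarities. Two clusters may merge when at least a fraction r (the
# clique ratio) of their cross pairs exceed the similarity threshold t; at
# r = 1 the procedure reduces to complete-linkage agglomeration cut at t.

#' Pairwise weighted-Jaccard similarity matrix
#'
#' @param descriptors list of \code{\link{KcfsDescriptor}} objects sharing a
#'   level; names become dimnames.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
similarityMatrix <- function(descriptors) {
  n <- length(descriptors)
  S <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        S[i, j] <- S[j, i] <- weightedJaccard(descriptors[[i]], descriptors[[j]])
      }
    }
  }
  dimnames(S) <- list(names(descriptors), names(descriptors))
  S
}

#' Quasi-clique agglomerative clustering
#'
#' Greedy agglomeration over a similarity matrix: a cluster pair is
#' admissible when the fraction of cross pairs with similarity >= \code{t}
#' is at least the clique ratio \code{r}; among admissible pairs the one
#' with the highest minimum cross similarity is merged (ties: higher mean
#' cross similarity, then smaller combined size, then smallest member
#' index), until no pair is admissible. At \code{r = 1} this is exactly
#' complete-linkage clustering cut at threshold \code{t}.
#'
#' @param S square symmetric similarity matrix.
#' @param t similarity threshold in (0, 1].
#' @param r clique ratio in (0, 1].
#' @return list with \code{partition} (integer cluster id per item, named
#'   by rownames of S; ids contiguous, ordered by smallest member),
#'   \code{merges} (data.frame log), \code{t}, \code{r}.
#' @export
qccCluster <- function(S, t, r) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) .stopf("S must be a square matrix")
  if (max(abs(S - t(S))) > 0) .stopf("S must be symmetric")
  if (!(t > 0 && t <= 1) || !(r > 0 && r <= 1)) {
    .stopf("t and r must lie in (0, 1]")
  }
  n <- nrow(S)
  clusters <- as.list(seq_len(n))
  log_rows <- list()
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        cross <- S[clusters[[i]], clusters[[j]], drop = FALSE]
        frac <- mean(cross >= t)
        if (frac < r) next
        cand <- list(i = i, j = j, minS = min(cross), meanS = mean(cross),
                     size = length(clusters[[i]]) + length(clusters[[j]]),
                     member = min(clusters[[i]], clusters[[j]]))
        if (is.null(best) ||
            cand$minS > best$minS ||
            (cand$minS == best$minS && cand$meanS > best$meanS) ||
            (cand$minS == best$minS && cand$meanS == best$meanS &&
             cand$size < best$size) ||
            (cand$minS == best$minS && cand$meanS == best$meanS &&
             cand$size == best$size && cand$member < best$member)) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = length(log_rows) + 1L,
      min_similarity = best$minS, mean_similarity = best$meanS,
      size = best$size)
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- clusters[-c(best$i, best$j)]
    clusters[[length(clusters) + 1L]] <- merged
  }
  # contiguous ids ordered by smallest member
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  partition <- integer(n)
  for (cid in seq_along(clusters)) partition[clusters[[cid]]] <- cid
  names(partition) <- rownames(S)
  merges <- if (length(log_rows)) do.call(rbind, log_rows)
            else data.frame(step = integer(0), min_similarity = numeric(0),
                            mean_similarity = numeric(0), size = integer(0))
  list(partition = partition, merges = merges, t = t, r = r)
}
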
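# Ring perception: a smallest-set-of-smallest-rings (SSSR) basis found by
# collecting the shortest cycle through every edge and keeping a maximal
# linearly independent subset over GF(2), followed by grouping edge-sharing
# rings into fused systems and Hueckel-style aromaticity perception.

#' Perceive the SSSR ring set and fused ring systems
#'
#' Returns the ring information used by atom typing and the RING attribute:
#' an SSSR basis (ring count = bonds - atoms + components), fused systems
#' (maximal groups of SSSR rings sharing at least one bond), and per-atom
#' \code{in_ring} / \code{aromatic} flags (\code{aromatic} is filled in by
#' \code{\link{perceiveAromaticity}}). Rings larger than 12 atoms keep their
#' \code{in_ring} flags but are excluded from substructure enumeration
#' downstream.
#'
#' @param mol a \code{\link{MolGraph}}.
#' @return list with elements \code{rings} (list of integer vectors, each an
#'   ordered cycle), \code{fused} (list of lists with \code{ring_idx} and
#'   \code{atoms}), \code{in_ring} and \code{aromatic} logical vectors.
#' @examples
#' rings <- perceiveRings(builtinMolecule("benzene"))
#' length(rings$rings)  # 1
#' @export
perceiveRings <- function(mol) {
  stopifnot(is(mol, "MolGraph"))
  n <- atomCount(mol)
  bd <- mol@bonds
  adj <- .adjacency(n, bd)
  comps <- if (n) .components(seq_len(n), adj) else list()
  mu <- nrow(bd) - n + length(comps)
  empty <- list(rings = list(), fused = list(),
                in_ring = logical(n), aromatic = logical(n))
  if (mu <= 0L) return(empty)

  # candidate cycles: shortest cycle through each edge
  cand <- list()
  for (j in seq_len(nrow(bd))) {
    p <- .shortest_path(bd$a[j], bd$b[j], adj, skip_edge = c(bd$a[j], bd$b[j]))
    if (!is.null(p)) cand[[length(cand) + 1L]] <- p
  }
  if (!length(cand)) return(empty)
  cand <- cand[order(lengths(cand))]
  # dedupe by atom set
  cand <- cand[!duplicated(lapply(cand, function(p) sort(p)))]

  edge_id <- function(u, v) paste(pmin(u, v), pmax(u, v))
  eids <- edge_id(bd$a, bd$b)
  cycle_vec <- function(p) {
    m <- length(p)
    e <- vapply(seq_len(m), function(i) edge_id(p[i], p[if (i == m) 1L else i + 1L]),
                character(1))
    v <- logical(nrow(bd))
    v[match(e, eids)] <- TRUE
    v
  }
  basis <- matrix(logical(0), nrow = 0, ncol = nrow(bd))
  rings <- list()
  for (p in cand) {
    v <- cycle_vec(p)
    # GF(2) reduction against current basis
    w <- v
    for (r in seq_len(nrow(basis))) {
      pivot <- which(basis[r, ])[1]
      if (w[pivot]) w <- xor(w, basis[r, ])
    }
    if (any(w)) {
      # keep basis rows in pivot order (gaussian elimination)
      basis <- rbind(basis, w)
      # re-sort rows by pivot column for stable elimination
      basis <- basis[order(apply(basis, 1, function(row) which(row)[1])), ,
                     drop = FALSE]
      rings[[length(rings) + 1L]] <- p
      if (length(rings) == mu) break
    }
  }

  in_ring <- logical(n)
  for (p in rings) in_ring[p] <- TRUE

  # fused systems: union-find over rings sharing >= 1 bond
  ring_edges <- lapply(rings, function(p) {
    m <- length(p)
    vapply(seq_len(m), function(i) edge_id(p[i], p[if (i == m) 1L else i + 1L]),
           character(1))
  })
  nr <- length(rings)
  parent <- seq_len(nr)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nr > 1L) {
    for (i in seq_len(nr - 1L)) {
      for (j in seq.int(i + 1L, nr)) {
        if (length(intersect(ring_edges[[i]], ring_edges[[j]]))) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  groups <- split(seq_len(nr), vapply(seq_len(nr), find, integer(1)))
  fused <- list()
  for (g in groups) {
    if (length(g) < 2L) next
    fused[[length(fused) + 1L]] <- list(
      ring_idx = as.integer(g),
      atoms = sort(unique(unlist(rings[g]))))
  }
  list(rings = rings, fused = fused, in_ring = in_ring, aromatic = logical(n))
}

#' Mark aromatic atoms by a Hueckel rule over single SSSR rings
#'
#' A 5-, 6- or 7-membered SSSR ring is aromatic when every ring atom is
#' either an endpoint of a double bond (in-ring or exocyclic) or a
#' heteroatom (N, O, S) able to contribute a lone pair, and the ring's
#' pi-electron count satisfies 4n+2. In-ring double bonds contribute 2,
#' lone-pair heteroatoms contribute 2, and an atom whose double bond points
#' at another atom of the same fused ring system contributes 1 (so the
#' perceived aromaticity of a fused heteroaromatic does not depend on which
#' kekule structure the input happened to be drawn with). Rings of a fused
#' system are judged one by one; an atom is aromatic when any ring
#' containing it is.
#'
#' @param mol a \code{\link{MolGraph}} with kekulized bond orders.
#' @param rings result of \code{\link{perceiveRings}}.
#' @return the ring list with the \code{aromatic} flags filled in.
#' @export
perceiveAromaticity <- function(mol, rings) {
  bd <- mol@bonds
  n <- atomCount(mol)
  el <- mol@atoms$element
  dbl_partner <- vector("list", n)   # atoms double-bonded to each atom
  for (j in seq_len(nrow(bd))) {
    if (bd$order[j] == 2L) {
      dbl_partner[[bd$a[j]]] <- c(dbl_partner[[bd$a[j]]], bd$b[j])
      dbl_partner[[bd$b[j]]] <- c(dbl_partner[[bd$b[j]]], bd$a[j])
    }
  }
  # fused-system membership per atom (0 = not in a fused system)
  sys_id <- integer(n)
  for (s in seq_along(rings$fused)) sys_id[rings$fused[[s]]$atoms] <- s
  aromatic <- logical(n)
  for (p in rings$rings) {
    m <- length(p)
    if (m < 5L || m > 7L) next
    pi_e <- 0L
    ok <- TRUE
    counted_dbl <- character(0)
    for (i in seq_len(m)) {
      v <- p[i]
      dp <- dbl_partner[[v]]
      if (length(dp)) {
        in_ring_dbl <- intersect(dp, p)
        if (length(in_ring_dbl)) {
          for (u in in_ring_dbl) {
            key <- paste(min(u, v), max(u, v))
            if (!(key %in% counted_dbl)) {
              counted_dbl <- c(counted_dbl, key)
              pi_e <- pi_e + 2L
            }
          }
        } else if (sys_id[v] > 0L && any(sys_id[dp] == sys_id[v])) {
          pi_e <- pi_e + 1L  # double bond into the rest of the fused system
        }
        # other exocyclic double bond: sp2, contributes 0
      } else if (el[v] %in% c("N", "O", "S")) {
        pi_e <- pi_e + 2L  # lone pair
      } else {
        ok <- FALSE
        break
      }
    }
    if (ok && pi_e %% 4L == 2L) aromatic[p] <- TRUE
  }
  rings$aromatic <- aromatic
  rings
}
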
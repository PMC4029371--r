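# KEGG atom typing: one three-character label per heavy atom, assigned from
# kekulized bond orders, ring membership and aromaticity. Carbons are typed
# first; O/N/S/P labels then refer to the carbon context (e.g. the ester
# oxygens mirror their C7a carbon). Rule order within an element is
# most-specific-first and is laid out in the same order in this file:
#
#   C: carbonyl (C6a > C7a/C7x > C4a > C5a/C5x) > aromatic (C8x/C8y)
#      > triple (C3a/C3b) > double (C2a..C2y) > saturated (C1a..C1z) > C0
#   O: by neighbor element (P > S > N > C), then bond order / ring
#   N: aromatic (N4/N5) > quaternary (N1d) > triple (N3a) > double (N2) > N1
#   S: oxidized (S4a) > disulfide (S3) > by degree (S1a/S2a/S2x) > S0
#   P: P1b when bonded to oxygen, else P1a
#
# Terminal oxygens on phosphate P and sulfonate S are typed O1c / O1d
# whatever the drawn bond order, so that protonation state and P=O / S=O
# drawing conventions do not change the descriptor.

.catalog_env <- new.env(parent = emptyenv())

#' The KEGG atom type catalog
#'
#' The 68 three-character atom type labels with their structural patterns
#' and names. The same table ships as a plain-text file at
#' \code{system.file("extdata", "kegg_atom_types.tsv", package = "kcfs")}.
#'
#' @return data.frame with columns \code{label}, \code{pattern},
#'   \code{description} (68 rows).
#' @export
keggAtomTypes <- function() {
  if (is.null(.catalog_env$catalog)) {
    path <- system.file("extdata", "kegg_atom_types.tsv", package = "kcfs")
    .catalog_env$catalog <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .catalog_env$catalog
}

#' Truncate an atom type label to a hierarchy level
#'
#' Level k1 is the element family character, k2 the two-character atom
#' class, k3 the full atom type. Labels shorter than \code{k} ("X", "Z") are
#' returned whole.
#'
#' @param label character vector of atom type labels.
#' @param k integer(1) in 1:3.
#' @return character vector of truncated labels.
#' @examples
#' truncateLabel("C1y", 2)  # "C1"
#' truncateLabel("X", 3)    # "X"
#' @export
truncateLabel <- function(label, k) {
  if (length(k) != 1L || !(k %in% 1:3)) {
    .stopf("k must be 1, 2 or 3 (got %s)", paste(k, collapse = ","))
  }
  substr(label, 1L, k)
}

#' Assign KEGG atom types to every heavy atom
#'
#' @param mol a \code{\link{MolGraph}} with kekulized bond orders.
#' @param rings ring information from \code{\link{perceiveRings}} passed
#'   through \code{\link{perceiveAromaticity}}.
#' @return character vector of k3 labels, one per atom.
#' @examples
#' mol <- builtinMolecule("ethanol")
#' rings <- perceiveAromaticity(mol, perceiveRings(mol))
#' assignAtomTypes(mol, rings)  # "C1a" "C1b" "O1a"
#' @export
assignAtomTypes <- function(mol, rings) {
  stopifnot(is(mol, "MolGraph"))
  at <- mol@atoms
  bd <- mol@bonds
  n <- nrow(at)
  if (n == 0L) return(character(0))
  el <- at$element
  in_ring <- rings$in_ring
  aromatic <- rings$aromatic

  nb <- vector("list", n)      # neighbor indices
  nb_ord <- vector("list", n)  # matching bond orders
  for (i in seq_len(n)) { nb[[i]] <- integer(0); nb_ord[[i]] <- integer(0) }
  for (j in seq_len(nrow(bd))) {
    a <- bd$a[j]; b <- bd$b[j]; o <- bd$order[j]
    nb[[a]] <- c(nb[[a]], b); nb_ord[[a]] <- c(nb_ord[[a]], o)
    nb[[b]] <- c(nb[[b]], a); nb_ord[[b]] <- c(nb_ord[[b]], o)
  }
  deg <- lengths(nb)
  bond_in_ring <- function(u, v) {
    for (p in rings$rings) {
      m <- length(p)
      for (i in seq_len(m)) {
        q <- p[if (i == m) 1L else i + 1L]
        if ((p[i] == u && q == v) || (p[i] == v && q == u)) return(TRUE)
      }
    }
    FALSE
  }

  labels <- character(n)

  # --- carbons first -------------------------------------------------------
  for (i in which(el == "C")) {
    o_dbl <- nb[[i]][nb_ord[[i]] == 2L & el[nb[[i]]] == "O"]
    if (length(o_dbl)) {
      o_sgl <- nb[[i]][nb_ord[[i]] == 1L & el[nb[[i]]] == "O"]
      o_sgl_term <- o_sgl[deg[o_sgl] == 1L]
      o_sgl_bridge <- o_sgl[deg[o_sgl] >= 2L]
      if (length(o_sgl_term)) {
        labels[i] <- "C6a"
      } else if (length(o_sgl_bridge)) {
        labels[i] <- if (in_ring[i] && any(in_ring[o_sgl_bridge])) "C7x" else "C7a"
      } else if (deg[i] <= 2L) {
        labels[i] <- "C4a"
      } else {
        labels[i] <- if (in_ring[i]) "C5x" else "C5a"
      }
    } else if (aromatic[i]) {
      labels[i] <- if (deg[i] <= 2L) "C8x" else "C8y"
    } else if (any(nb_ord[[i]] == 3L)) {
      labels[i] <- if (deg[i] <= 1L) "C3a" else "C3b"
    } else if (any(nb_ord[[i]] == 2L)) {
      if (in_ring[i]) {
        labels[i] <- if (deg[i] <= 2L) "C2x" else "C2y"
      } else {
        labels[i] <- switch(min(deg[i], 3L) + 1L, "C2a", "C2a", "C2b", "C2c")
      }
    } else {
      if (in_ring[i]) {
        labels[i] <- switch(min(deg[i], 4L), "C1x", "C1x", "C1y", "C1z")
      } else {
        labels[i] <- switch(min(deg[i], 4L) + 1L, "C1a", "C1a", "C1b", "C1c", "C1d")
      }
    }
    if (deg[i] > 4L) labels[i] <- "C0"
  }

  # --- sulfur (before oxygen: O1d depends on S4a) --------------------------
  for (i in which(el == "S")) {
    o_nb <- nb[[i]][el[nb[[i]]] == "O"]
    o_dbl <- nb[[i]][nb_ord[[i]] == 2L & el[nb[[i]]] == "O"]
    s_nb <- nb[[i]][el[nb[[i]]] == "S"]
    if (length(o_nb) >= 3L || length(o_dbl) >= 2L) {
      labels[i] <- "S4a"
    } else if (length(s_nb)) {
      labels[i] <- if (in_ring[i]) "S3x" else "S3a"
    } else if (deg[i] <= 1L) {
      labels[i] <- "S1a"
    } else if (deg[i] == 2L) {
      labels[i] <- if (in_ring[i]) "S2x" else "S2a"
    } else {
      labels[i] <- "S0"
    }
  }

  # --- phosphorus ----------------------------------------------------------
  for (i in which(el == "P")) {
    labels[i] <- if (any(el[nb[[i]]] == "O")) "P1b" else "P1a"
  }

  # --- oxygen --------------------------------------------------------------
  for (i in which(el == "O")) {
    if (deg[i] == 0L) { labels[i] <- "O0"; next }
    if (deg[i] == 1L) {
      j <- nb[[i]][1]
      o <- nb_ord[[i]][1]
      labels[i] <- switch(el[j],
        "P" = "O1c",
        "S" = if (labels[j] == "S4a") "O1d" else if (o == 2L) "O3c" else "O1d",
        "N" = if (o == 2L) "O3a" else "O1b",
        "C" = if (o == 2L) {
          switch(labels[j], "C4a" = "O4a", "C5a" = "O5a", "C5x" = "O5x",
                 "C6a" = "O6a", "C7a" = "O6a", "C7x" = "O6a", "O0")
        } else {
          if (labels[j] == "C6a") "O6a" else "O1a"
        },
        "O0")
      next
    }
    if (deg[i] == 2L) {
      nbs <- nb[[i]]
      if (sum(el[nbs] == "P") >= 2L) { labels[i] <- "O2c"; next }
      if (any(el[nbs] == "P")) { labels[i] <- "O2b"; next }
      ester_c <- nbs[el[nbs] == "C" & labels[nbs] %in% c("C7a", "C7x")]
      if (length(ester_c)) {
        labels[i] <- if (any(labels[ester_c] == "C7x") && in_ring[i]) "O7x" else "O7a"
        next
      }
      labels[i] <- if (in_ring[i]) "O2x" else "O2a"
      next
    }
    labels[i] <- "O0"
  }

  # --- nitrogen ------------------------------------------------------------
  for (i in which(el == "N")) {
    has_dbl <- any(nb_ord[[i]] == 2L)
    has_tpl <- any(nb_ord[[i]] == 3L)
    if (aromatic[i]) {
      if (has_dbl) {
        labels[i] <- if (deg[i] <= 2L) "N5x" else "N5y"
      } else {
        labels[i] <- if (deg[i] <= 2L) "N4x" else "N4y"
      }
    } else if (deg[i] >= 4L) {
      labels[i] <- if (all(nb_ord[[i]] == 1L)) "N1d" else "N0"
    } else if (has_tpl) {
      labels[i] <- "N3a"
    } else if (has_dbl) {
      if (in_ring[i]) {
        labels[i] <- if (deg[i] <= 2L) "N2x" else "N2y"
      } else {
        labels[i] <- if (deg[i] <= 1L) "N2a" else "N2b"
      }
    } else {
      if (in_ring[i]) {
        labels[i] <- if (deg[i] <= 2L) "N1x" else "N1y"
      } else {
        labels[i] <- switch(min(deg[i], 3L) + 1L, "N1a", "N1a", "N1b", "N1c")
      }
    }
  }

  # --- halogens and everything else ---------------------------------------
  labels[el %in% c("F", "Cl", "Br", "I")] <- "X"
  rest <- !(el %in% c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I"))
  labels[rest] <- "Z"

  labels
}

#' Build a typed compound from a molecular graph
#'
#' Convenience constructor running ring perception, aromaticity perception
#' and atom typing, returning a \code{\link{KcfCompound}} (without
#' substructures; see \code{\link{extractSubstructures}}).
#'
#' @param mol a \code{\link{MolGraph}}.
#' @param kind entry kind for KCF output ("Compound" or "Drug").
#' @return a \code{\link{KcfCompound}}.
#' @examples
#' cpd <- kcfCompound(builtinMolecule("alanine"))
#' atomLabels(cpd)
#' @export
kcfCompound <- function(mol, kind = "Compound") {
  stopifnot(is(mol, "MolGraph"))
  rings <- perceiveAromaticity(mol, perceiveRings(mol))
  labels <- assignAtomTypes(mol, rings)
  new("KcfCompound", graph = mol, kind = kind, labels = labels,
      rings = rings, substructures = list())
}
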
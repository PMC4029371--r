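# Enumeration of the seven substructure attributes (ATOM, BOND, TRIPLET,
# VICINITY, RING, SKELETON, INORGANIC) from a typed molecular graph.
#
# Every extractor returns a list of instances; an instance is
#   list(attribute=, canonical=, atoms= sorted integer vector)
# where `atoms` contains every atom whose label appears in the canonical
# string (backbone plus one-shell branch atoms). Extractors are
# parameterized by the per-atom label vector so that descriptor levels k1/k2
# re-canonicalize truncated labels through exactly the same code path.

.instance <- function(attribute, canonical, atoms, role = NA_integer_) {
  # `role` disambiguates instances sharing one atom set (the center of a
  # TRIPLET inside a triangle); it never appears in rendered output
  list(attribute = attribute, canonical = canonical,
       atoms = sort(unique(as.integer(atoms))), role = role)
}

#' Enumerate ATOM instances
#'
#' One instance per heavy atom, labeled at hierarchy level \code{k}.
#'
#' @param mol a \code{\link{MolGraph}}.
#' @param labels per-atom k3 labels (see \code{\link{assignAtomTypes}}).
#' @param k truncation level (1, 2 or 3).
#' @return list of instances.
#' @export
extractAtoms <- function(mol, labels, k = 3) {
  lab <- truncateLabel(labels, k)
  lapply(seq_along(lab), function(i) .instance("ATOM", lab[i], i))
}

#' Enumerate BOND instances
#'
#' One instance per edge; the two labels are sorted alphabetically and
#' joined with a hyphen.
#'
#' @inheritParams extractAtoms
#' @return list of instances.
#' @export
extractBonds <- function(mol, labels) {
  bd <- mol@bonds
  lapply(seq_len(nrow(bd)), function(j) {
    two <- .byte_sort(c(labels[bd$a[j]], labels[bd$b[j]]))
    .instance("BOND", paste(two, collapse = "-"), c(bd$a[j], bd$b[j]))
  })
}

#' Enumerate TRIPLET instances
#'
#' One instance per unordered pair of edges sharing a central atom; the two
#' flank labels are sorted alphabetically around the center. A center of
#' degree d contributes d(d-1)/2 instances.
#'
#' @inheritParams extractAtoms
#' @return list of instances.
#' @export
extractTriplets <- function(mol, labels) {
  adj <- .adjacency(atomCount(mol), mol@bonds)
  out <- list()
  for (v in seq_along(adj)) {
    nbs <- adj[[v]]
    if (length(nbs) < 2L) next
    pairs <- utils::combn(nbs, 2L)
    for (p in seq_len(ncol(pairs))) {
      fl <- .byte_sort(labels[pairs[, p]])
      out[[length(out) + 1L]] <- .instance(
        "TRIPLET", paste(c(fl[1], labels[v], fl[2]), collapse = "-"),
        c(v, pairs[, p]), role = v)
    }
  }
  out
}

#' Enumerate VICINITY instances
#'
#' One instance per atom with heavy degree >= 3: the center label followed
#' by the sorted neighbor labels joined by \code{+} in parentheses.
#'
#' @inheritParams extractAtoms
#' @return list of instances.
#' @export
extractVicinities <- function(mol, labels) {
  adj <- .adjacency(atomCount(mol), mol@bonds)
  out <- list()
  for (v in seq_along(adj)) {
    nbs <- adj[[v]]
    if (length(nbs) < 3L) next
    out[[length(out) + 1L]] <- .instance(
      "VICINITY",
      paste0(labels[v], .group_plus(labels[nbs])),
      c(v, nbs))
  }
  out
}

#' Enumerate RING instances
#'
#' One instance per SSSR ring of size 3-12, plus one condensed instance per
#' ortho-fused ring system whose perimeter is a single cycle covering every
#' system atom with length <= 12. Branch atoms are the heavy neighbors of
#' ring atoms lying outside the fused ring system to which the ring
#' belongs; each ring atom's branch labels form one sorted \code{+} group.
#'
#' @inheritParams extractAtoms
#' @param rings ring information from \code{\link{perceiveAromaticity}}.
#' @return list of instances (condensed entries carry
#'   \code{is_condensed = TRUE}).
#' @export
extractRings <- function(mol, labels, rings) {
  adj <- .adjacency(atomCount(mol), mol@bonds)
  out <- list()
  # which fused system does each ring belong to (0 = none)
  sys_of_ring <- integer(length(rings$rings))
  for (s in seq_along(rings$fused)) {
    sys_of_ring[rings$fused[[s]]$ring_idx] <- s
  }
  ring_entry <- function(cycle, exclude, condensed) {
    branch_atoms <- integer(0)
    attach <- lapply(cycle, function(v) {
      bs <- setdiff(adj[[v]], exclude)
      branch_atoms <<- c(branch_atoms, bs)
      .group_plus(labels[bs])
    })
    ins <- .instance("RING",
                     canonicalLinearString(labels[cycle], attach, cyclic = TRUE),
                     c(cycle, branch_atoms))
    ins$is_condensed <- condensed
    ins$backbone_size <- length(cycle)
    ins
  }
  for (ri in seq_along(rings$rings)) {
    p <- rings$rings[[ri]]
    if (length(p) > 12L) next
    excl <- if (sys_of_ring[ri] > 0L) rings$fused[[sys_of_ring[ri]]]$atoms else p
    out[[length(out) + 1L]] <- ring_entry(p, excl, FALSE)
  }
  for (s in seq_along(rings$fused)) {
    fs <- rings$fused[[s]]
    perim <- .perimeter_cycle(rings$rings[fs$ring_idx], fs$atoms, mol@bonds)
    if (is.null(perim)) {
      .warnf("fused system of %d atoms has no perimeter cycle covering all atoms; no condensed RING entry",
             length(fs$atoms))
      next
    }
    if (length(perim) > 12L) next
    out[[length(out) + 1L]] <- ring_entry(perim, fs$atoms, TRUE)
  }
  out
}

# perimeter of an ortho-fused system: the edges belonging to exactly one of
# its SSSR rings, required to form one simple cycle over all system atoms
.perimeter_cycle <- function(ring_list, sys_atoms, bonds) {
  eid <- function(u, v) paste(pmin(u, v), pmax(u, v))
  tab <- table(unlist(lapply(ring_list, function(p) {
    m <- length(p)
    vapply(seq_len(m), function(i) eid(p[i], p[if (i == m) 1L else i + 1L]),
           character(1))
  })))
  perim_edges <- names(tab)[tab == 1L]
  if (!length(perim_edges)) return(NULL)
  ends <- do.call(rbind, strsplit(perim_edges, " "))
  ends <- cbind(as.integer(ends[, 1]), as.integer(ends[, 2]))
  verts <- sort(unique(as.vector(ends)))
  if (!identical(verts, sys_atoms)) return(NULL)
  nb <- lapply(verts, function(v) {
    c(ends[ends[, 1] == v, 2], ends[ends[, 2] == v, 1])
  })
  names(nb) <- verts
  if (any(lengths(nb) != 2L)) return(NULL)
  # walk the cycle
  start <- verts[1]
  cyc <- start
  prev <- NA_integer_
  cur <- start
  repeat {
    nxt <- setdiff(nb[[as.character(cur)]], prev)
    if (!length(nxt)) return(NULL)
    nxt <- nxt[1]
    if (nxt == start) break
    cyc <- c(cyc, nxt)
    prev <- cur
    cur <- nxt
  }
  if (length(cyc) != length(verts)) return(NULL)
  cyc
}

#' Enumerate SKELETON instances
#'
#' One instance per connected component of the carbon-induced subgraph with
#' at least two carbons. The backbone is a longest simple carbon path (ties
#' resolved by the smallest bare label sequence, then the smallest full
#' rendering); remaining carbons are bundled as recursively rendered branch
#' groups, and non-carbon neighbors of every carbon are annotated as
#' one-shell label groups.
#'
#' @inheritParams extractAtoms
#' @return list of instances.
#' @export
extractSkeletons <- function(mol, labels) {
  el <- mol@atoms$element
  .chain_instances(mol, labels,
                   members = which(el == "C"),
                   attribute = "SKELETON", mode = "mixed")
}

#' Enumerate INORGANIC instances
#'
#' One instance per connected component of the non-carbon-induced subgraph
#' with at least two atoms. The backbone is a longest path; shorter chains
#' are bundled as nested parenthesized branches, and carbon neighbors are
#' appended as parenthesized labels. Every attachment forms its own group,
#' ordered by decreasing rendered length then alphabetically.
#'
#' @inheritParams extractAtoms
#' @return list of instances.
#' @export
extractInorganics <- function(mol, labels) {
  el <- mol@atoms$element
  .chain_instances(mol, labels,
                   members = which(el != "C"),
                   attribute = "INORGANIC", mode = "separate")
}

# shared machinery for SKELETON / INORGANIC
.chain_instances <- function(mol, labels, members, attribute, mode,
                             assign_cap = 64L) {
  n <- atomCount(mol)
  adj <- .adjacency(n, mol@bonds)
  member <- logical(n)
  member[members] <- TRUE
  annot <- function(v) labels[setdiff(adj[[v]], which(member))]
  annot_atoms <- function(v) setdiff(adj[[v]], which(member))
  comps <- .components(members, adj)
  out <- list()
  for (comp in comps) {
    if (length(comp) < 2L) next
    best <- NULL
    paths <- .longest_simple_paths(comp, .restrict_adj(adj, comp))
    for (path in paths) {
      for (assignment in .branch_assignments(comp, path, adj, assign_cap)) {
        attach <- .build_attachments(path, assignment, comp, adj, labels,
                                     annot, mode)
        cand <- .chain_candidate(labels[path], attach)
        best <- .better_candidate(cand, best)
      }
    }
    atoms <- c(comp, unlist(lapply(comp, annot_atoms)))
    out[[length(out) + 1L]] <- .instance(attribute, best$full, atoms)
  }
  out
}

.restrict_adj <- function(adj, vertices) {
  inset <- logical(length(adj))
  inset[vertices] <- TRUE
  lapply(seq_along(adj), function(v) {
    if (inset[v]) adj[[v]][inset[adj[[v]]]] else integer(0)
  })
}

# all ways to hang the leftover components of comp \ path onto backbone
# atoms they touch; each assignment is a list of (slot, entry, comp_atoms)
.branch_assignments <- function(comp, path, adj, cap) {
  leftover <- setdiff(comp, path)
  if (!length(leftover)) return(list(list()))
  subcomps <- .components(leftover, .restrict_adj(adj, leftover))
  options <- lapply(subcomps, function(B) {
    opts <- list()
    for (b0 in B) {
      hits <- intersect(adj[[b0]], path)
      for (p in hits) {
        opts[[length(opts) + 1L]] <- list(slot = match(p, path), entry = b0,
                                          comp_atoms = B)
      }
    }
    opts
  })
  combos <- list(list())
  for (opts in options) {
    new_combos <- list()
    for (cb in combos) {
      for (o in opts) {
        new_combos[[length(new_combos) + 1L]] <- c(cb, list(o))
        if (length(new_combos) >= cap) break
      }
      if (length(new_combos) >= cap) break
    }
    combos <- new_combos
  }
  combos
}

.build_attachments <- function(path, assignment, comp, adj, labels, annot,
                               mode) {
  multis <- rep(list(character(0)), length(path))
  for (a in assignment) {
    br <- .render_branch(a$comp_atoms, a$entry, adj, labels, annot, mode)
    multis[[a$slot]] <- c(multis[[a$slot]], br)
  }
  lapply(seq_along(path), function(i) {
    singles <- annot(path[i])
    if (mode == "separate") {
      .group_separate(c(multis[[i]], singles))
    } else {
      .group_mixed(multis[[i]], singles)
    }
  })
}

# render a branch component as a chain starting at its attachment atom
.render_branch <- function(B, b0, adj, labels, annot, mode, cap = 64L) {
  sub_adj <- .restrict_adj(adj, B)
  # longest simple paths starting at b0
  best_len <- 0L
  paths <- list()
  recurse <- function(path) {
    tip <- path[length(path)]
    extended <- FALSE
    for (w in sub_adj[[tip]]) {
      if (!(w %in% path)) { extended <- TRUE; recurse(c(path, w)) }
    }
    if (!extended) {
      if (length(path) > best_len) { best_len <<- length(path); paths <<- list(path) }
      else if (length(path) == best_len) paths[[length(paths) + 1L]] <<- path
    }
  }
  recurse(b0)
  best <- NULL
  for (path in paths) {
    for (assignment in .branch_assignments(B, path, adj, cap)) {
      attach <- .build_attachments(path, assignment, B, adj, labels, annot,
                                   mode)
      att <- vapply(attach, paste0, character(1), collapse = "")
      cand <- .render_traversal(labels[path], att)  # direction fixed at b0
      if (is.null(best) || .str_lt(cand, best)) best <- cand
    }
  }
  best
}

#' Enumerate all seven substructure attributes
#'
#' Runs the seven extractors and deduplicates instances that describe the
#' same atom set under the same attribute and canonical string (the count of
#' a canonical string is the number of distinct atom sets).
#'
#' @inheritParams extractRings
#' @return list of instances grouped in attribute order ATOM, BOND,
#'   TRIPLET, VICINITY, RING, SKELETON, INORGANIC.
#' @export
extractAll <- function(mol, labels, rings) {
  ins <- c(extractAtoms(mol, labels, 3L),
           extractBonds(mol, labels),
           extractTriplets(mol, labels),
           extractVicinities(mol, labels),
           extractRings(mol, labels, rings),
           extractSkeletons(mol, labels),
           extractInorganics(mol, labels))
  if (!length(ins)) return(list())
  key <- vapply(ins, function(x) {
    paste(x$attribute, x$canonical, paste(x$atoms, collapse = ","),
          if (is.null(x$role)) NA_integer_ else x$role)
  }, character(1))
  ins[!duplicated(key)]
}

#' Populate the substructure slot of a typed compound
#'
#' @param cpd a \code{\link{KcfCompound}}.
#' @return the compound with \code{substructures} filled at level k3.
#' @examples
#' cpd <- extractSubstructures(kcfCompound(builtinMolecule("ethanol")))
#' substructures(cpd)
#' @export
extractSubstructures <- function(cpd) {
  stopifnot(is(cpd, "KcfCompound"))
  cpd@substructures <- extractAll(cpd@graph, cpd@labels, cpd@rings)
  cpd
}
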
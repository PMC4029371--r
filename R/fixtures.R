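# Built-in molecules, a seeded random molecule generator, and a synthetic
# reaction-pair generator emulating substrate/product pairs that conserve a
# chemical core while changing a localized substructure (the property the
# pair-feature design is built to exploit).

.BUILTIN_NAMES <- c(
  "ethane", "ethanol", "benzene", "toluene", "phenol", "cyclohexane",
  "cyclohexanol", "imidazole", "glycine", "alanine", "leucine_dipeptide",
  "lactic_acid", "pyruvic_acid", "acetylacetone", "n_methylacetamide",
  "methyl_phosphate", "methanesulfonate", "ribose", "adenine", "adenosine")

#' Names of the built-in fixture molecules
#' @return character vector of 20 names.
#' @export
builtinMoleculeNames <- function() .BUILTIN_NAMES

#' Load a built-in fixture molecule
#'
#' The structures ship as plain-text V2000 Molfiles with the package.
#'
#' @param name one of \code{\link{builtinMoleculeNames}()}.
#' @return a \code{\link{MolGraph}}.
#' @examples
#' builtinMolecule("alanine")
#' @export
builtinMolecule <- function(name) {
  if (!(name %in% .BUILTIN_NAMES)) {
    .stopf("unknown molecule '%s'; available: %s", name,
           paste(.BUILTIN_NAMES, collapse = ", "))
  }
  path <- system.file("extdata", "molecules", paste0(name, ".mol"),
                      package = "kcfs")
  readMolfile(path, id = name)
}

.VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 4L)

#' Generate a random valence-respecting molecule
#'
#' Grows a connected heavy-atom graph: atoms are attached one by one to a
#' random atom with free valence; occasional double bonds and ring closures
#' are added where both endpoints retain free valence. The same seed always
#' yields the same graph.
#'
#' @param seed integer seed.
#' @param nAtoms number of heavy atoms (>= 1).
#' @param elementWeights named sampling weights for C, N, O, S, P.
#' @return a \code{\link{MolGraph}}.
#' @export
randomMolecule <- function(seed, nAtoms,
                           elementWeights = c(C = 8, N = 2, O = 3, S = 0.5, P = 0.5)) {
  if (nAtoms < 1L) .stopf("nAtoms must be >= 1")
  bad <- setdiff(names(elementWeights), names(.VALENCE))
  if (length(bad)) .stopf("unsupported element(s): %s", paste(bad, collapse = ", "))
  .with_seed(seed, {
    els <- names(elementWeights)
    element <- sample(els, nAtoms, replace = TRUE, prob = elementWeights)
    used <- integer(nAtoms)  # bond-order sum per atom
    a <- integer(0); b <- integer(0); ord <- integer(0)
    for (i in seq_len(nAtoms)[-1]) {
      free <- which(used[seq_len(i - 1L)] < .VALENCE[element[seq_len(i - 1L)]])
      if (!length(free)) {
        .stopf("infeasible valence request: no attachment point at atom %d", i)
      }
      tgt <- if (length(free) == 1L) free else sample(free, 1L)
      o <- 1L
      if (element[i] %in% c("C", "N", "O") && element[tgt] %in% c("C", "N") &&
          used[tgt] + 2L <= .VALENCE[element[tgt]] &&
          .VALENCE[element[i]] >= 2L && stats::runif(1) < 0.15) {
        o <- 2L
      }
      a <- c(a, tgt); b <- c(b, i); ord <- c(ord, o)
      used[tgt] <- used[tgt] + o
      used[i] <- used[i] + o
    }
    # ring closures
    n_ring <- if (nAtoms >= 5L) stats::rbinom(1, max(0L, nAtoms %/% 6L), 0.8) else 0L
    bonded <- function(u, v) any((a == u & b == v) | (a == v & b == u))
    for (k in seq_len(n_ring)) {
      free <- which(used < .VALENCE[element])
      if (length(free) < 2L) break
      cand <- utils::combn(free, 2L)
      ok <- apply(cand, 2, function(p) !bonded(p[1], p[2]))
      cand <- cand[, ok, drop = FALSE]
      if (!ncol(cand)) break
      pick <- cand[, sample(ncol(cand), 1L)]
      a <- c(a, pick[1]); b <- c(b, pick[2]); ord <- c(ord, 1L)
      used[pick] <- used[pick] + 1L
    }
    theta <- 2 * pi * seq_len(nAtoms) / nAtoms
    atoms <- data.frame(element = element, charge = 0L,
                        x = round(cos(theta), 4), y = round(sin(theta), 4),
                        hcount = 0L, stringsAsFactors = FALSE)
    bonds <- data.frame(a = a, b = b, order = ord, stereo = 0L)
    new("MolGraph", id = sprintf("random_%d", seed), atoms = atoms, bonds = bonds)
  })
}

#' Names of the synthetic reaction rules
#' @return character vector.
#' @export
reactionRuleNames <- function() {
  c("o_methylation", "phosphorylation", "oxidation", "amide_hydrolysis",
    "ring_cyclization")
}

# each rule: list(sites = function(mol) list of site descriptors,
#                 apply = function(mol, site) MolGraph)
.rules <- function() {
  # alcohol hydroxyls only (O1a context): single-bonded terminal O on a
  # carbon that carries no carbonyl, so methylation yields an ether (O2a)
  # rather than an ester
  hydroxyl_sites <- function(mol) {
    at <- mol@atoms; bd <- mol@bonds
    adj <- .adjacency(nrow(at), bd)
    out <- list()
    for (i in which(at$element == "O")) {
      if (length(adj[[i]]) != 1L) next
      j <- adj[[i]][1]
      o <- bd$order[(bd$a == i & bd$b == j) | (bd$a == j & bd$b == i)]
      if (o != 1L || at$element[j] != "C") next
      carbonyl <- any(bd$order == 2L &
                      ((bd$a == j & at$element[bd$b] == "O") |
                       (bd$b == j & at$element[bd$a] == "O")))
      if (!carbonyl) out[[length(out) + 1L]] <- i
    }
    out
  }
  add_atom <- function(mol, el, near) {
    at <- mol@atoms
    k <- nrow(at) + 1L
    at[k, ] <- list(el, 0L, round(at$x[near] + 0.5 + 0.1 * k, 4),
                    round(at$y[near] + 0.5, 4), 0L)
    mol@atoms <- at
    list(mol = mol, idx = k)
  }
  add_bond <- function(mol, u, v, o = 1L) {
    mol@bonds <- rbind(mol@bonds, data.frame(a = u, b = v, order = o, stereo = 0L))
    mol
  }
  list(
    o_methylation = list(
      sites = hydroxyl_sites,
      apply = function(mol, site) {
        r <- add_atom(mol, "C", site)
        add_bond(r$mol, site, r$idx, 1L)
      }),
    phosphorylation = list(
      sites = hydroxyl_sites,
      apply = function(mol, site) {
        r <- add_atom(mol, "P", site)
        mol <- add_bond(r$mol, site, r$idx, 1L)
        p <- r$idx
        for (k in 1:3) {
          r2 <- add_atom(mol, "O", p)
          mol <- add_bond(r2$mol, p, r2$idx, 1L)
        }
        mol
      }),
    oxidation = list(
      # secondary/primary alcohol carbon with a spare hydrogen -> carbonyl
      sites = function(mol) {
        at <- mol@atoms; bd <- mol@bonds
        adj <- .adjacency(nrow(at), bd)
        out <- list()
        for (i in which(at$element == "O")) {
          if (length(adj[[i]]) != 1L) next
          j <- adj[[i]][1]
          sel <- (bd$a == i & bd$b == j) | (bd$a == j & bd$b == i)
          if (bd$order[sel] != 1L || at$element[j] != "C") next
          ords <- bd$order[bd$a == j | bd$b == j]
          if (length(adj[[j]]) <= 3L && all(ords == 1L)) {
            out[[length(out) + 1L]] <- c(o = i, c = j)
          }
        }
        out
      },
      apply = function(mol, site) {
        sel <- (mol@bonds$a == site[["o"]] & mol@bonds$b == site[["c"]]) |
               (mol@bonds$a == site[["c"]] & mol@bonds$b == site[["o"]])
        mol@bonds$order[sel] <- 2L
        mol
      }),
    amide_hydrolysis = list(
      # split the C-N amide bond, cap the carbon with a hydroxyl, keep the
      # larger fragment (acyl side on ties)
      sites = function(mol) {
        at <- mol@atoms; bd <- mol@bonds
        adj <- .adjacency(nrow(at), bd)
        out <- list()
        for (j in seq_len(nrow(bd))) {
          u <- bd$a[j]; v <- bd$b[j]
          for (p in list(c(u, v), c(v, u))) {
            cc <- p[1]; nn <- p[2]
            if (at$element[cc] != "C" || at$element[nn] != "N" ||
                bd$order[j] != 1L) next
            dbl_o <- any(vapply(seq_len(nrow(bd)), function(q) {
              bd$order[q] == 2L && ((bd$a[q] == cc && at$element[bd$b[q]] == "O") ||
                                    (bd$b[q] == cc && at$element[bd$a[q]] == "O"))
            }, logical(1)))
            if (dbl_o) out[[length(out) + 1L]] <- c(c = cc, n = nn, bond = j)
          }
        }
        out
      },
      apply = function(mol, site) {
        mol@bonds <- mol@bonds[-site[["bond"]], , drop = FALSE]
        at <- mol@atoms
        k <- nrow(at) + 1L
        at[k, ] <- list("O", 0L, round(at$x[site[["c"]]] + 0.6, 4),
                        round(at$y[site[["c"]]] - 0.6, 4), 0L)
        mol@atoms <- at
        mol@bonds <- rbind(mol@bonds,
                           data.frame(a = site[["c"]], b = k, order = 1L, stereo = 0L))
        adj <- .adjacency(nrow(mol@atoms), mol@bonds)
        comps <- .components(seq_len(nrow(mol@atoms)), adj)
        sizes <- lengths(comps)
        keep <- comps[[order(-sizes, !vapply(comps, function(cp) site[["c"]] %in% cp,
                                             logical(1)))[1]]]
        .induced_subgraph(mol, keep)
      }),
    ring_cyclization = list(
      # hydroxyl oxygen attacks a carbon 4-5 bonds away -> cyclic ether
      sites = function(mol) {
        at <- mol@atoms; bd <- mol@bonds
        n <- nrow(at)
        adj <- .adjacency(n, bd)
        used <- integer(n)
        for (j in seq_len(nrow(bd))) {
          used[bd$a[j]] <- used[bd$a[j]] + bd$order[j]
          used[bd$b[j]] <- used[bd$b[j]] + bd$order[j]
        }
        out <- list()
        for (i in which(at$element == "O")) {
          if (length(adj[[i]]) != 1L) next
          for (cc in which(at$element == "C")) {
            if (used[cc] >= 4L) next
            p <- .shortest_path(i, cc, adj)
            if (!is.null(p) && length(p) %in% c(5L, 6L)) {
              out[[length(out) + 1L]] <- c(o = i, c = cc)
            }
          }
        }
        out
      },
      apply = function(mol, site) {
        mol@bonds <- rbind(mol@bonds,
                           data.frame(a = site[["o"]], b = site[["c"]],
                                      order = 1L, stereo = 0L))
        mol
      })
  )
}

.induced_subgraph <- function(mol, keep) {
  keep <- sort(keep)
  remap <- integer(nrow(mol@atoms))
  remap[keep] <- seq_along(keep)
  at <- mol@atoms[keep, , drop = FALSE]
  rownames(at) <- NULL
  bd <- mol@bonds
  sel <- bd$a %in% keep & bd$b %in% keep
  bd <- bd[sel, , drop = FALSE]
  bd$a <- remap[bd$a]; bd$b <- remap[bd$b]
  rownames(bd) <- NULL
  new("MolGraph", id = mol@id, atoms = at, bonds = bd)
}

#' Generate synthetic enzymatic reaction pairs
#'
#' Applies rule-based graph edits (O-methylation, phosphorylation, alcohol
#' oxidation, amide hydrolysis, ring cyclization) to the built-in scaffold
#' molecules and their products, emitting substrate/product pairs. Each
#' transformation conserves the molecular core (the pair's weighted Jaccard
#' at k3 is checked to be >= 0.5; violating edits are discarded and
#' redrawn) and changes a localized substructure. Both directions of a
#' transformation are emitted as ordered positive pairs.
#'
#' @param seed integer seed.
#' @param nPairs number of directed positive pairs to emit (rounded down to
#'   an even number; each transformation yields two).
#' @param rules subset of \code{\link{reactionRuleNames}()}.
#' @return list with \code{compounds} (named list of \code{MolGraph}),
#'   \code{descriptors} (named list of k3 \code{KcfsDescriptor}),
#'   \code{positives} (data.frame id1/id2/rule covering both directions).
#' @export
syntheticReactionPairs <- function(seed, nPairs = 60L,
                                   rules = reactionRuleNames()) {
  bad <- setdiff(rules, reactionRuleNames())
  if (length(bad)) .stopf("unknown rule(s): %s", paste(bad, collapse = ", "))
  rule_defs <- .rules()[rules]
  compounds <- list()
  descriptors <- list()
  add_compound <- function(id, mol) {
    mol@id <- id
    compounds[[id]] <<- mol
    descriptors[[id]] <<- buildDescriptor(
      extractSubstructures(kcfCompound(mol)), level = 3)
    id
  }
  for (nm in .BUILTIN_NAMES) add_compound(nm, builtinMolecule(nm))

  n_tr <- nPairs %/% 2L
  .with_seed(seed, {
    # enumerate all (scaffold, rule, site) applications lazily, sampling
    # without replacement until enough conserved transformations are found
    pos <- list()
    emitted <- character(0)
    tries <- 0L
    repeat {
      if (length(pos) >= n_tr || tries > 50L * n_tr) break
      tries <- tries + 1L
      sub_id <- sample(names(compounds), 1L)
      rule <- sample(names(rule_defs), 1L)
      sites <- rule_defs[[rule]]$sites(compounds[[sub_id]])
      if (!length(sites)) next
      si <- sample(length(sites), 1L)
      key <- paste(sub_id, rule, si)
      if (key %in% emitted) next
      emitted <- c(emitted, key)
      prod <- tryCatch(rule_defs[[rule]]$apply(compounds[[sub_id]], sites[[si]]),
                       error = function(e) NULL)
      if (is.null(prod) || !isTRUE(validObject(prod, test = TRUE))) next
      if (atomCount(prod) < 2L) next
      prod_id <- sprintf("%s_%s_%d", sub_id, rule, si)
      add_compound(prod_id, prod)
      if (weightedJaccard(descriptors[[sub_id]], descriptors[[prod_id]]) < 0.5) {
        compounds[[prod_id]] <- NULL
        descriptors[[prod_id]] <- NULL
        next
      }
      pos[[length(pos) + 1L]] <- data.frame(
        id1 = sub_id, id2 = prod_id, rule = rule, stringsAsFactors = FALSE)
    }
    if (length(pos) < n_tr) {
      .stopf("could not generate %d conserved transformations (got %d)",
             n_tr, length(pos))
    }
    fwd <- do.call(rbind, pos)
    bwd <- data.frame(id1 = fwd$id2, id2 = fwd$id1, rule = fwd$rule,
                      stringsAsFactors = FALSE)
    positives <- rbind(fwd, bwd)
    rownames(positives) <- NULL
    list(compounds = compounds, descriptors = descriptors,
         positives = positives)
  })
}
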
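# Shared helpers: cached fixture compounds, direct MolGraph construction,
# permutation utilities and the independent oracles used by the suite.

.fixture_cache <- new.env(parent = emptyenv())

fixture_cpd <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- extractSubstructures(kcfCompound(builtinMolecule(name)))
  }
  .fixture_cache[[name]]
}

fixture_desc <- function(name, level = 3) {
  key <- paste0(name, "_k", level)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- buildDescriptor(fixture_cpd(name), level = level)
  }
  .fixture_cache[[key]]
}

# build a MolGraph directly from an element vector and a bond matrix
# (rows: a, b, order)
make_mol <- function(elements, bonds = NULL, charges = 0L, id = "test") {
  n <- length(elements)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 3)
  bd <- data.frame(a = as.integer(bonds[, 1]), b = as.integer(bonds[, 2]),
                   order = as.integer(bonds[, 3]),
                   stereo = rep(0L, nrow(bonds)))
  theta <- 2 * pi * seq_len(n) / max(n, 1)
  new("MolGraph", id = id,
      atoms = data.frame(element = elements, charge = rep_len(as.integer(charges), n),
                         x = round(cos(theta), 4), y = round(sin(theta), 4),
                         hcount = 0L, stringsAsFactors = FALSE),
      bonds = bd)
}

# apply an atom permutation: atom i of the result is atom perm[i] of mol
permute_mol <- function(mol, perm) {
  inv <- order(perm)
  at <- mol@atoms[perm, , drop = FALSE]
  rownames(at) <- NULL
  bd <- mol@bonds
  bd$a <- inv[bd$a]
  bd$b <- inv[bd$b]
  new("MolGraph", id = mol@id, atoms = at, bonds = bd)
}

# minimal descriptor with arbitrary keys, for similarity/algebra tests
# (zero entries are treated as absent)
mk_desc <- function(counts, level = 3) {
  counts <- counts[counts > 0]
  if (!length(counts)) {
    return(new("KcfsDescriptor", level = as.integer(level),
               counts = stats::setNames(integer(0), character(0)),
               attrs = character(0)))
  }
  keys <- paste0("ATOM:", names(counts))
  new("KcfsDescriptor", level = as.integer(level),
      counts = stats::setNames(as.integer(counts), keys),
      attrs = rep("ATOM", length(counts)))
}

# byte-wise minimum over all rotations/reflections of a decorated cycle (or
# both directions of a path): the exhaustive-traversal oracle
brute_traversal_min <- function(labels, att = NULL, cyclic = FALSE) {
  n <- length(labels)
  if (is.null(att)) att <- rep("", n)
  render <- function(ix) paste(paste0(labels[ix], att[ix]), collapse = "-")
  cands <- character(0)
  if (cyclic) {
    for (s in seq_len(n)) {
      fwd <- ((seq_len(n) - 1 + s - 1) %% n) + 1
      rev_ <- ((s - seq_len(n)) %% n) + 1
      cands <- c(cands, render(fwd), render(rev_))
    }
  } else {
    cands <- c(render(seq_len(n)), render(rev(seq_len(n))))
  }
  cands[order(cands, method = "radix")[1]]
}

# direct-summation hypergeometric upper tail: P(X >= a) for a 2x2 table
# with margins (a+b | c+d) and containment totals a+c
hyper_tail <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + c_       # molecules containing the substructure
  n <- a + b        # size of set A
  ks <- seq(a, min(K, n))
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Mann-Whitney formulation of the AUC (ties count 1/2)
mw_auc <- function(scores, labels) {
  pos <- scores[labels %in% c(1, TRUE)]
  neg <- scores[!(labels %in% c(1, TRUE))]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# do two partitions agree up to cluster renaming?
same_partition <- function(p1, p2) {
  length(p1) == length(p2) &&
    length(unique(p1)) == length(unique(p2)) &&
    length(unique(paste(p1, p2))) == length(unique(p1))
}

random_similarity <- function(seed, n) {
  set.seed(seed)
  S <- matrix(runif(n * n), n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

all_fixture_names <- builtinMoleculeNames()

# substructure multiset (attribute + canonical, sorted) of a compound
substr_multiset <- function(cpd) {
  s <- substructures(cpd)
  sort(paste(s$attribute, s$canonical))
}

# benzyl fragment (benzyl alcohol): phenyl ring attached through a
# methylene, the context of the printed phenyl ring string
benzyl_mol <- function() {
  make_mol(c("O", "C", "C", "C", "C", "C", "C", "C"),
           rbind(c(1, 2, 1),            # O-CH2
                 c(2, 3, 1),            # CH2-ring
                 c(3, 4, 2), c(4, 5, 1), c(5, 6, 2),
                 c(6, 7, 1), c(7, 8, 2), c(8, 3, 1)),
           id = "benzyl_alcohol")
}
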
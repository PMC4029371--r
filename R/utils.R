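# Small graph helpers shared across modules. Molecular graphs are tiny
# (<= a few hundred atoms), so plain adjacency lists are adequate.

# adjacency list (list of integer vectors) from a bond table
.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  if (n == 0L || nrow(bonds) == 0L) {
    return(lapply(adj, function(x) integer(0)))
  }
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

# connected components over a vertex subset; returns list of integer vectors
.components <- function(vertices, adj) {
  vs <- sort(vertices)
  seen <- logical(length(adj))
  out <- list()
  inset <- logical(length(adj))
  inset[vs] <- TRUE
  for (v in vs) {
    if (seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) {
        if (inset[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

# BFS shortest path between two vertices, optionally excluding one edge;
# returns integer vector of vertices (or NULL if unreachable)
.shortest_path <- function(from, to, adj, skip_edge = NULL) {
  n <- length(adj)
  prev <- integer(n)
  seen <- logical(n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    if (u == to) {
      path <- u
      while (path[1] != from) path <- c(prev[path[1]], path)
      return(path)
    }
    for (w in adj[[u]]) {
      if (!is.null(skip_edge) &&
          ((u == skip_edge[1] && w == skip_edge[2]) ||
           (u == skip_edge[2] && w == skip_edge[1]))) next
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- u
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

# all maximum-length simple paths within a vertex subset (small components
# only; enumeration is DFS with an explicit stack of partial paths)
.longest_simple_paths <- function(vertices, adj, cap = 20000L) {
  best_len <- 1L
  paths <- list()
  inset <- logical(length(adj))
  inset[vertices] <- TRUE
  n_seen <- 0L
  recurse <- function(path) {
    if (n_seen > cap) return()
    n_seen <<- n_seen + 1L
    tip <- path[length(path)]
    extended <- FALSE
    for (w in adj[[tip]]) {
      if (inset[w] && !(w %in% path)) {
        extended <- TRUE
        recurse(c(path, w))
      }
    }
    if (!extended) {
      if (length(path) > best_len) {
        best_len <<- length(path)
        paths <<- list(path)
      } else if (length(path) == best_len) {
        paths[[length(paths) + 1L]] <<- path
      }
    }
  }
  for (v in vertices) recurse(v)
  # drop reversed duplicates
  uniq <- !duplicated(vapply(paths, function(p) {
    f <- paste(p, collapse = ",")
    r <- paste(rev(p), collapse = ",")
    if (f < r) f else r
  }, character(1)))
  paths[uniq]
}

# byte-wise (C-locale) string ordering, independent of the session locale;
# canonical-string selection is specified as byte-wise lexicographic
.byte_sort <- function(x) x[order(x, method = "radix")]
.byte_min <- function(x) x[order(x, method = "radix")[1L]]
.str_lt <- function(a, b) !identical(a, b) && order(c(a, b), method = "radix")[1L] == 1L
.str_le <- function(a, b) identical(a, b) || .str_lt(a, b)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
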
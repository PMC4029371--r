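# The KCF flat file (ENTRY/ATOM/BOND sections) and its KCF-S extension
# (SUBSTR subsections). The precise plain-text dialect is frozen here and by
# golden-file tests: 12-character left-justified section keys, single-space
# separated fields, coordinates with 4 decimals, continuation lines indented
# by 12 spaces, "///" terminator. Rendering is deterministic, so identical
# documents produce identical bytes.

.KCF_ATTRS <- c("ATOM", "BOND", "TRIPLET", "VICINITY", "RING", "SKELETON",
                "INORGANIC")

.kcf_key <- function(key) sprintf("%-12s", key)

#' Render a typed compound as KCF text
#'
#' ENTRY line, ATOM section (index, k3 label, element, 2D coordinates),
#' BOND section (index, atom pair, order) and the \code{///} terminator.
#'
#' @param cpd a \code{\link{KcfCompound}}.
#' @return character(1) KCF text.
#' @examples
#' cat(renderKcf(kcfCompound(builtinMolecule("ethanol"))))
#' @export
renderKcf <- function(cpd) {
  stopifnot(is(cpd, "KcfCompound"))
  .check_labels(cpd@labels)
  at <- cpd@graph@atoms
  bd <- cpd@graph@bonds
  out <- paste0(.kcf_key("ENTRY"), molId(cpd), " ", cpd@kind)
  out <- c(out, paste0(.kcf_key("ATOM"), nrow(at)))
  for (i in seq_len(nrow(at))) {
    out <- c(out, paste0(strrep(" ", 12),
                         paste(i, cpd@labels[i], at$element[i],
                               sprintf("%.4f", at$x[i]), sprintf("%.4f", at$y[i]))))
  }
  out <- c(out, paste0(.kcf_key("BOND"), nrow(bd)))
  for (j in seq_len(nrow(bd))) {
    out <- c(out, paste0(strrep(" ", 12),
                         paste(j, bd$a[j], bd$b[j], bd$order[j])))
  }
  out <- c(out, "///")
  paste0(paste(out, collapse = "\n"), "\n")
}

.check_labels <- function(labels) {
  bad <- setdiff(labels, keggAtomTypes()$label)
  if (!length(labels)) return(invisible(TRUE))
  if (any(!nzchar(labels))) .stopf("untyped atom: empty label")
  if (length(bad)) .stopf("unknown atom type label(s): %s", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Render a typed compound as KCF-S text
#'
#' The KCF body followed by the SUBSTR section: seven subsections in fixed
#' order (ATOM, BOND, TRIPLET, VICINITY, RING, SKELETON, INORGANIC), each
#' header carrying the number of distinct canonical strings. Every entry
#' line holds the canonical string, the instance count in parentheses, and
#' the instance atom lists (1-based indices, ascending, comma-joined;
#' instances separated by semicolons). Entries are sorted lexicographically.
#'
#' @param cpd a \code{\link{KcfCompound}} with extracted substructures.
#' @return character(1) KCF-S text.
#' @export
renderKcfs <- function(cpd) {
  stopifnot(is(cpd, "KcfCompound"))
  if (atomCount(cpd) > 0L && !length(cpd@substructures)) {
    .stopf("substructures not extracted; run extractSubstructures() first")
  }
  body <- sub("///\n$", "", renderKcf(cpd))
  ins <- cpd@substructures
  attr_of <- vapply(ins, `[[`, character(1), "attribute")
  out <- character(0)
  for (a in .KCF_ATTRS) {
    sub <- ins[attr_of == a]
    canon <- vapply(sub, `[[`, character(1), "canonical")
    groups <- split(sub, canon)
    groups <- groups[order(names(groups), method = "radix")]
    out <- c(out, paste0(.kcf_key("SUBSTR"), a, " ", length(groups)))
    for (g in names(groups)) {
      sets <- lapply(groups[[g]], `[[`, "atoms")
      sets <- sets[!duplicated(vapply(sets, paste, character(1), collapse = ","))]
      ord <- order(vapply(sets, function(s) {
        paste(sprintf("%06d", s), collapse = ",")
      }, character(1)))
      sets <- sets[ord]
      out <- c(out, paste0(strrep(" ", 12), g, " (", length(sets), ") ",
                           paste(vapply(sets, paste, character(1), collapse = ","),
                                 collapse = ";")))
    }
  }
  paste0(body, paste(out, collapse = "\n"), "\n///\n")
}

#' Parse KCF text
#'
#' Inverse of \code{\link{renderKcf}}. Atom type labels are trusted (not
#' re-derived); header counts must match block lengths and the document must
#' end with \code{///}.
#'
#' @param text character: path, single string, or vector of lines.
#' @return a \code{\link{KcfCompound}} (substructures empty).
#' @export
parseKcf <- function(text) {
  .parse_kcf_impl(text, with_substr = FALSE)
}

#' Parse KCF-S text
#'
#' Inverse of \code{\link{renderKcfs}}; reconstructs the substructure
#' instances. Unknown subsection names, count mismatches and a missing
#' \code{///} terminator are errors naming the offending line.
#'
#' @param text character: path, single string, or vector of lines.
#' @return a \code{\link{KcfCompound}} with substructures populated.
#' @export
parseKcfs <- function(text) {
  .parse_kcf_impl(text, with_substr = TRUE)
}

.parse_kcf_impl <- function(text, with_substr) {
  lines <- .as_lines(text)
  while (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (!length(lines)) .stopf("line 1: empty KCF document")
  if (lines[length(lines)] != "///") {
    .stopf("line %d: missing '///' terminator", length(lines))
  }
  i <- 1L
  id <- NULL; kind <- "Compound"
  atoms <- NULL; bonds <- NULL; labels <- character(0)
  substr_ins <- list()
  while (i < length(lines)) {
    line <- lines[i]
    key <- trimws(substr(line, 1, 12))
    rest <- trimws(substr(line, 13, nchar(line)))
    if (key == "ENTRY") {
      fields <- strsplit(rest, "\\s+")[[1]]
      id <- fields[1]
      if (length(fields) > 1L) kind <- fields[2]
      i <- i + 1L
    } else if (key == "ATOM") {
      n <- suppressWarnings(as.integer(rest))
      if (is.na(n)) .stopf("line %d: bad ATOM count '%s'", i, rest)
      block <- .take_block(lines, i, n)
      if (length(block) != n) {
        .stopf("line %d: ATOM header says %d but %d atom lines follow",
               i, n, length(block))
      }
      atoms <- data.frame(element = character(n), charge = 0L,
                          x = numeric(n), y = numeric(n), hcount = 0L,
                          stringsAsFactors = FALSE)
      labels <- character(n)
      for (k in seq_len(n)) {
        f <- strsplit(trimws(block[k]), "\\s+")[[1]]
        if (length(f) < 5L) .stopf("line %d: malformed KCF atom line", i + k)
        idx <- as.integer(f[1])
        if (is.na(idx) || idx != k) .stopf("line %d: atom index %s out of order", i + k, f[1])
        labels[k] <- f[2]
        atoms$element[k] <- f[3]
        atoms$x[k] <- as.numeric(f[4])
        atoms$y[k] <- as.numeric(f[5])
      }
      bad <- setdiff(labels, keggAtomTypes()$label)
      if (length(bad)) {
        .stopf("line %d: unknown atom type label(s): %s", i + 1L,
               paste(bad, collapse = ", "))
      }
      i <- i + n + 1L
    } else if (key == "BOND") {
      m <- suppressWarnings(as.integer(rest))
      if (is.na(m)) .stopf("line %d: bad BOND count '%s'", i, rest)
      block <- .take_block(lines, i, m)
      if (length(block) != m) {
        .stopf("line %d: BOND header says %d but %d bond lines follow",
               i, m, length(block))
      }
      bonds <- data.frame(a = integer(m), b = integer(m), order = integer(m),
                          stereo = rep(0L, m))
      for (k in seq_len(m)) {
        f <- strsplit(trimws(block[k]), "\\s+")[[1]]
        if (length(f) < 4L) .stopf("line %d: malformed KCF bond line", i + k)
        bonds$a[k] <- as.integer(f[2])
        bonds$b[k] <- as.integer(f[3])
        bonds$order[k] <- as.integer(f[4])
      }
      i <- i + m + 1L
    } else if (key == "SUBSTR") {
      if (!with_substr) .stopf("line %d: SUBSTR section in plain KCF", i)
      f <- strsplit(rest, "\\s+")[[1]]
      a <- f[1]
      if (!(a %in% .KCF_ATTRS)) .stopf("line %d: unknown SUBSTR subsection '%s'", i, a)
      nd <- suppressWarnings(as.integer(f[2]))
      if (is.na(nd)) .stopf("line %d: bad SUBSTR count", i)
      block <- .take_block(lines, i, NA)
      if (length(block) != nd) {
        .stopf("line %d: SUBSTR %s header says %d distinct but %d entry lines follow",
               i, a, nd, length(block))
      }
      for (k in seq_len(length(block))) {
        entry <- trimws(block[k])
        m <- regmatches(entry, regexec("^(\\S+) \\((\\d+)\\)(?: (.*))?$", entry))[[1]]
        if (!length(m)) .stopf("line %d: malformed SUBSTR entry line", i + k)
        canon <- m[2]
        cnt <- as.integer(m[3])
        lists <- if (nzchar(m[4])) strsplit(m[4], ";", fixed = TRUE)[[1]] else character(0)
        if (length(lists) != cnt) {
          .stopf("line %d: count (%d) does not match %d instance lists",
                 i + k, cnt, length(lists))
        }
        for (s in lists) {
          substr_ins[[length(substr_ins) + 1L]] <- .instance(
            a, canon, as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
        }
      }
      i <- i + length(block) + 1L
    } else if (line == "///") {
      break
    } else {
      .stopf("line %d: unknown KCF section key '%s'", i, key)
    }
  }
  if (is.null(atoms)) .stopf("missing ATOM section")
  if (is.null(bonds)) bonds <- data.frame(a = integer(0), b = integer(0),
                                          order = integer(0), stereo = integer(0))
  mol <- new("MolGraph", id = if (is.null(id)) "mol" else id,
             atoms = atoms, bonds = bonds)
  rings <- perceiveAromaticity(mol, perceiveRings(mol))
  new("KcfCompound", graph = mol, kind = kind, labels = labels,
      rings = rings, substructures = substr_ins)
}

# continuation lines (12 leading spaces) following header line i; when n is
# NA, takes all continuation lines
.take_block <- function(lines, i, n) {
  block <- character(0)
  j <- i + 1L
  while (j <= length(lines) && startsWith(lines[j], strrep(" ", 12))) {
    block <- c(block, lines[j])
    j <- j + 1L
    if (!is.na(n) && length(block) > n) break
  }
  block
}
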
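# MDL Molfile V2000 / SDF reader and writer.
#
# The reader is deliberately strict about the parts the downstream typing
# needs (counts line, atom/bond blocks, element symbols, charge semantics)
# and reports parse errors with the offending line number. Aromatic (type 4)
# bonds are kekulized to alternating 1/2 orders; explicit hydrogens are
# removed and recorded as implicit counts.

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu")

# old-style atom-block charge codes (Molfile column 37-39)
.CHARGE_CODES <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L, "4" = 0L,
                   "5" = -1L, "6" = -2L, "7" = -3L)

.parse_int <- function(s, line, what) {
  s <- trimws(s)
  if (!nzchar(s) || is.na(suppressWarnings(v <- as.integer(s)))) {
    .stopf("line %d: cannot parse %s ('%s')", line, what, s)
  }
  v
}

.parse_num <- function(s, line, what) {
  s <- trimws(s)
  if (!nzchar(s) || is.na(suppressWarnings(v <- as.numeric(s)))) {
    .stopf("line %d: cannot parse %s ('%s')", line, what, s)
  }
  v
}

#' Read a single MDL Molfile V2000 block
#'
#' Parses the counts line, atom block, bond block and \code{M  CHG}
#' properties of a V2000 Molfile into a hydrogen-suppressed
#' \code{\link{MolGraph}}. \code{M  CHG} lines override the deprecated
#' per-atom charge codes (when present, all old codes are discarded, per the
#' V2000 specification). Aromatic bonds (type 4) are kekulized to explicit
#' alternating single/double orders; explicit hydrogen atoms are removed and
#' counted into the \code{hcount} column. V3000 input is rejected.
#'
#' @param text character: either a single string with embedded newlines, a
#'   character vector of lines, or the path of an existing file.
#' @param id optional identifier; defaults to the Molfile title line (or
#'   "mol" when the title is blank).
#' @return a \code{\link{MolGraph}}.
#' @examples
#' mol <- builtinMolecule("ethanol")
#' atomCount(mol)  # 3 heavy atoms
#' @export
readMolfile <- function(text, id = NULL) {
  lines <- .as_lines(text)
  if (length(lines) < 4L) .stopf("line 1: Molfile has fewer than 4 lines")
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE)) {
    .stopf("line 4: V3000 Molfiles are not supported; supply V2000")
  }
  if (!grepl("V2000", counts, fixed = TRUE)) {
    # tolerate a missing version tag but still require two leading counts
    if (!grepl("^\\s*\\d+\\s+\\d+", counts)) {
      .stopf("line 4: malformed counts line ('%s')", counts)
    }
  }
  natoms <- .parse_int(substr(counts, 1, 3), 4L, "atom count")
  nbonds <- .parse_int(substr(counts, 4, 6), 4L, "bond count")
  if (length(lines) < 4L + natoms + nbonds) {
    .stopf("line %d: file truncated (%d atoms + %d bonds declared)",
           length(lines), natoms, nbonds)
  }
  element <- character(natoms)
  charge_code <- integer(natoms)
  x <- numeric(natoms); y <- numeric(natoms)
  for (i in seq_len(natoms)) {
    ln <- 4L + i
    line <- lines[ln]
    el <- trimws(substr(line, 32, 34))
    if (!nzchar(el)) {
      # fall back to whitespace splitting for non-column-aligned files
      fields <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(fields) < 4L) .stopf("line %d: malformed atom line", ln)
      el <- fields[4]
      x[i] <- .parse_num(fields[1], ln, "x coordinate")
      y[i] <- .parse_num(fields[2], ln, "y coordinate")
      charge_code[i] <- if (length(fields) >= 6L)
        suppressWarnings(as.integer(fields[6])) else 0L
    } else {
      x[i] <- .parse_num(substr(line, 1, 10), ln, "x coordinate")
      y[i] <- .parse_num(substr(line, 11, 20), ln, "y coordinate")
      cc <- trimws(substr(line, 37, 39))
      charge_code[i] <- if (nzchar(cc)) suppressWarnings(as.integer(cc)) else 0L
    }
    if (is.na(charge_code[i])) charge_code[i] <- 0L
    if (!(el %in% .ELEMENTS)) {
      .stopf("line %d: unknown element symbol '%s'", ln, el)
    }
    element[i] <- el
  }
  a <- integer(nbonds); b <- integer(nbonds)
  ord <- integer(nbonds); stereo <- integer(nbonds)
  for (j in seq_len(nbonds)) {
    ln <- 4L + natoms + j
    line <- lines[ln]
    a[j] <- .parse_int(substr(line, 1, 3), ln, "bond atom 1")
    b[j] <- .parse_int(substr(line, 4, 6), ln, "bond atom 2")
    ord[j] <- .parse_int(substr(line, 7, 9), ln, "bond order")
    st <- trimws(substr(line, 10, 12))
    stereo[j] <- if (nzchar(st)) suppressWarnings(as.integer(st)) else 0L
    if (is.na(stereo[j])) stereo[j] <- 0L
    if (a[j] < 1L || a[j] > natoms || b[j] < 1L || b[j] > natoms) {
      .stopf("line %d: bond references atom %d outside 1..%d",
             ln, if (a[j] < 1L || a[j] > natoms) a[j] else b[j], natoms)
    }
    if (a[j] == b[j]) .stopf("line %d: self-loop bond on atom %d", ln, a[j])
    if (!(ord[j] %in% c(1L, 2L, 3L, 4L))) {
      .stopf("line %d: unsupported bond type %d", ln, ord[j])
    }
  }
  # property block: M CHG overrides ALL old charge codes when present
  charge <- vapply(as.character(charge_code), function(cc) {
    if (cc %in% names(.CHARGE_CODES)) .CHARGE_CODES[[cc]] else 0L
  }, integer(1))
  chg_lines <- grep("^M  CHG", lines[seq.int(4L + natoms + nbonds + 1L,
                                             length.out = max(0L, length(lines) - 4L - natoms - nbonds))],
                    value = TRUE)
  if (length(chg_lines)) {
    charge <- integer(natoms)
    for (line in chg_lines) {
      fields <- strsplit(trimws(sub("^M  CHG", "", line)), "\\s+")[[1]]
      cnt <- as.integer(fields[1])
      for (k in seq_len(cnt)) {
        idx <- as.integer(fields[2L * k])
        val <- as.integer(fields[2L * k + 1L])
        if (is.na(idx) || idx < 1L || idx > natoms) {
          .stopf("M CHG line references atom %s outside 1..%d", fields[2L * k], natoms)
        }
        charge[idx] <- val
      }
    }
  }
  title <- trimws(lines[1])
  if (is.null(id)) id <- if (nzchar(title)) title else "mol"
  atoms <- data.frame(element = element, charge = charge, x = x, y = y,
                      hcount = 0L, stringsAsFactors = FALSE)
  bonds <- data.frame(a = a, b = b, order = ord, stereo = stereo)
  bonds <- .kekulize(atoms, bonds)
  g <- .suppress_hydrogens(atoms, bonds)
  new("MolGraph", id = id, atoms = g$atoms, bonds = g$bonds)
}

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1L) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}

# Assign 1/2 orders to aromatic (type 4) bonds by backtracking. Each carbon
# without a pre-existing multiple bond must receive exactly one double bond;
# O and S receive none; N is flexible (0 or 1: pyrrole- vs pyridine-type
# cannot be told apart without hydrogen placement, so the first consistent
# assignment in a fixed search order is taken).
.kekulize <- function(atoms, bonds) {
  arom <- which(bonds$order == 4L)
  if (!length(arom)) return(bonds)
  n <- nrow(atoms)
  # existing double/triple outside the aromatic system
  has_multi <- logical(n)
  for (j in seq_len(nrow(bonds))) {
    if (bonds$order[j] %in% c(2L, 3L)) {
      has_multi[bonds$a[j]] <- TRUE
      has_multi[bonds$b[j]] <- TRUE
    }
  }
  need <- rep(NA_integer_, n)  # NA = flexible
  touched <- sort(unique(c(bonds$a[arom], bonds$b[arom])))
  for (v in touched) {
    el <- atoms$element[v]
    need[v] <- if (el == "C") (if (has_multi[v]) 0L else 1L)
               else if (el %in% c("O", "S")) 0L
               else NA_integer_
  }
  got <- integer(n)
  assigned <- integer(length(arom))
  incid <- lapply(seq_len(n), function(v) which(bonds$a[arom] == v | bonds$b[arom] == v))
  ok_final <- function() {
    for (v in touched) {
      if (!is.na(need[v]) && got[v] != need[v]) return(FALSE)
      if (is.na(need[v]) && got[v] > 1L) return(FALSE)
    }
    TRUE
  }
  solve <- function(k) {
    if (k > length(arom)) return(ok_final())
    j <- arom[k]
    va <- bonds$a[j]; vb <- bonds$b[j]
    for (try_ord in c(2L, 1L)) {
      if (try_ord == 2L) {
        cap_a <- if (is.na(need[va])) 1L else need[va]
        cap_b <- if (is.na(need[vb])) 1L else need[vb]
        if (got[va] + 1L > cap_a || got[vb] + 1L > cap_b) next
        got[va] <<- got[va] + 1L; got[vb] <<- got[vb] + 1L
      } else {
        # pruning: if this was an atom's last aromatic bond and it still
        # needs a double, fail early
        fail <- FALSE
        for (v in c(va, vb)) {
          if (!is.na(need[v]) && got[v] < need[v]) {
            rest <- incid[[v]][incid[[v]] > k]
            if (!length(rest)) fail <- TRUE
          }
        }
        if (fail) next
      }
      assigned[k] <<- try_ord
      if (solve(k + 1L)) return(TRUE)
      if (try_ord == 2L) {
        got[va] <<- got[va] - 1L; got[vb] <<- got[vb] - 1L
      }
    }
    FALSE
  }
  if (!solve(1L)) {
    .stopf("cannot kekulize aromatic bond system (%d aromatic bonds)", length(arom))
  }
  bonds$order[arom] <- assigned
  bonds
}

.suppress_hydrogens <- function(atoms, bonds) {
  is_h <- atoms$element == "H"
  if (!any(is_h)) return(list(atoms = atoms, bonds = bonds))
  hcount <- atoms$hcount
  keep <- which(!is_h)
  remap <- integer(nrow(atoms))
  remap[keep] <- seq_along(keep)
  keep_bond <- logical(nrow(bonds))
  for (j in seq_len(nrow(bonds))) {
    ha <- is_h[bonds$a[j]]; hb <- is_h[bonds$b[j]]
    if (ha && hb) next
    if (ha) hcount[bonds$b[j]] <- hcount[bonds$b[j]] + 1L
    else if (hb) hcount[bonds$a[j]] <- hcount[bonds$a[j]] + 1L
    else keep_bond[j] <- TRUE
  }
  atoms$hcount <- hcount
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- bonds[keep_bond, , drop = FALSE]
  if (nrow(bonds)) {
    bonds$a <- remap[bonds$a]
    bonds$b <- remap[bonds$b]
  }
  rownames(bonds) <- NULL
  list(atoms = atoms, bonds = bonds)
}

#' Read an SDF stream into a list of molecular graphs
#'
#' Records are separated by \code{$$$$}. In lenient mode (default) a record
#' that fails to parse produces a warning naming the record index and is
#' skipped; with \code{strict = TRUE} the first failure is an error. An empty
#' stream yields an empty list.
#'
#' @param text character: path, single string, or vector of lines.
#' @param strict logical(1): stop on the first bad record instead of
#'   skipping it with a warning.
#' @return list of \code{\link{MolGraph}} objects in file order.
#' @export
readSDF <- function(text, strict = FALSE) {
  lines <- .as_lines(text)
  # drop trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (!length(lines)) return(list())
  seps <- grep("^\\${4}", lines)
  starts <- c(1L, seps + 1L)
  ends <- c(seps - 1L, length(lines))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  out <- list()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    # strip any trailing data items (> <field> blocks) after M END
    mend <- grep("^M  END", rec)
    if (length(mend)) rec <- rec[seq_len(mend[1])]
    if (!any(nzchar(trimws(rec)))) next
    mol <- tryCatch(readMolfile(rec), error = function(e) e)
    if (inherits(mol, "error")) {
      if (strict) .stopf("SDF record %d: %s", r, conditionMessage(mol))
      .warnf("SDF record %d skipped: %s", r, conditionMessage(mol))
    } else {
      out[[length(out) + 1L]] <- mol
    }
  }
  out
}

#' Write a molecular graph as an MDL Molfile V2000 block
#'
#' Coordinates are emitted with 4 decimal places; non-zero formal charges are
#' written as \code{M  CHG} property lines. The V2000 format limit of 999
#' atoms is enforced.
#'
#' @param mol a \code{\link{MolGraph}}.
#' @return character(1), the Molfile block (with trailing newline).
#' @export
writeMolfile <- function(mol) {
  stopifnot(is(mol, "MolGraph"))
  at <- mol@atoms; bd <- mol@bonds
  if (nrow(at) > 999L) {
    .stopf("V2000 Molfile supports at most 999 atoms (%d given)", nrow(at))
  }
  out <- c(mol@id, "  kcfs           2D", "")
  out <- c(out, sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                        nrow(at), nrow(bd)))
  for (i in seq_len(nrow(at))) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          at$x[i], at$y[i], 0, at$element[i]))
  }
  for (j in seq_len(nrow(bd))) {
    out <- c(out, sprintf("%3d%3d%3d%3d", bd$a[j], bd$b[j], bd$order[j], bd$stereo[j]))
  }
  chg <- which(at$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp, at$charge[grp]), collapse = "")))
    }
  }
  out <- c(out, "M  END")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write a list of molecular graphs as an SDF stream
#' @param mols list of \code{\link{MolGraph}} objects.
#' @param path optional output file; when NULL the text is returned.
#' @return character(1) SDF text (invisibly when written to a file).
#' @export
writeSDF <- function(mols, path = NULL) {
  txt <- paste0(vapply(mols, function(m) paste0(writeMolfile(m), "$$$$\n"),
                       character(1)), collapse = "")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}
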
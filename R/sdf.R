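#' Read molecules from an MDL SDF (V2000) file
#'
#' Parses a concatenation of one or more V2000 molfile records separated by
#' `$$$$`. Coordinates come from the fixed-column atom block, bond orders
#' from the bond block, and formal charges from `M  CHG` property lines
#' (when absent every atom's formal charge is 0, so `Q = 0`). The legacy
#' per-atom charge column of the atom block is ignored. Data items between
#' `M  END` and the record delimiter are skipped.
#'
#' Only V2000 is supported; V3000 records are rejected. Malformed counts
#' lines, out-of-range bond indices, unreadable coordinates and unknown
#' element symbols raise a format error naming the record and line.
#'
#' @param path path to an SDF file, or a character vector of lines via
#'   `text`.
#' @param text optional character vector of file lines (overrides `path`).
#' @return A named list of [eem_molecule()] objects in file order. Names
#'   are the molfile title lines; unnamed records are called `MOL_<i>`.
#' @export
read_sdf <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  # split into records on "$$$$" delimiter lines
  delim <- which(trimws(lines) == "$$$$")
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, length(lines))
  records <- Map(function(s, e) if (s <= e) lines[s:e] else character(0),
                 starts, ends)
  records <- Filter(function(r) any(nzchar(trimws(r))), records)
  if (length(records) == 0) {
    stop_format("SDF input contains no molecule records")
  }

  molecules <- vector("list", length(records))
  for (k in seq_along(records)) {
    molecules[[k]] <- parse_molfile(records[[k]], record = k)
  }
  names(molecules) <- make.unique(molecule_names(molecules))
  molecules
}

field <- function(line, from, to) {
  if (nchar(line) < from) "" else trimws(substr(line, from, to))
}

parse_int <- function(s, what, record, lineno) {
  v <- suppressWarnings(as.integer(s))
  if (length(v) != 1 || is.na(v)) {
    stop_format("SDF record %d, line %d: unreadable %s field '%s'",
                record, lineno, what, s)
  }
  v
}

parse_num <- function(s, what, record, lineno) {
  v <- suppressWarnings(as.numeric(s))
  if (length(v) != 1 || is.na(v)) {
    stop_format("SDF record %d, line %d: unreadable %s field '%s'",
                record, lineno, what, s)
  }
  v
}

parse_molfile <- function(rec, record) {
  # drop trailing blank lines
  while (length(rec) > 0 && !nzchar(trimws(rec[length(rec)]))) {
    rec <- rec[-length(rec)]
  }
  if (length(rec) < 4) {
    stop_format("SDF record %d: truncated header (need 4 header lines)", record)
  }
  name <- trimws(rec[1])
  if (!nzchar(name)) name <- sprintf("MOL_%d", record)

  counts <- rec[4]
  version <- field(counts, 34, 39)
  if (nzchar(version) && !identical(version, "V2000")) {
    stop_format("SDF record %d, line 4: unsupported molfile version '%s' (only V2000 is supported)",
                record, version)
  }
  n_atoms <- parse_int(field(counts, 1, 3), "atom count", record, 4)
  n_bonds <- parse_int(field(counts, 4, 6), "bond count", record, 4)
  if (n_atoms < 1) {
    stop_format("SDF record %d: atom count must be >= 1", record)
  }
  if (length(rec) < 4 + n_atoms + n_bonds) {
    stop_format("SDF record %d: fewer lines than the counts line declares", record)
  }

  atom_lines <- rec[4 + seq_len(n_atoms)]
  atoms <- tibble(
    element = character(n_atoms),
    x = double(n_atoms), y = double(n_atoms), z = double(n_atoms),
    formal_charge = integer(n_atoms)
  )
  for (i in seq_len(n_atoms)) {
    ln <- atom_lines[i]
    lineno <- 4 + i
    atoms$x[i] <- parse_num(field(ln, 1, 10), "x coordinate", record, lineno)
    atoms$y[i] <- parse_num(field(ln, 11, 20), "y coordinate", record, lineno)
    atoms$z[i] <- parse_num(field(ln, 21, 30), "z coordinate", record, lineno)
    el <- field(ln, 32, 34)
    if (!is_known_element(el)) {
      stop_format("SDF record %d, line %d: unknown element symbol '%s'",
                  record, lineno, el)
    }
    atoms$element[i] <- el
  }

  bond_lines <- rec[4 + n_atoms + seq_len(n_bonds)]
  bonds <- tibble(i = integer(n_bonds), j = integer(n_bonds),
                  order = integer(n_bonds))
  for (b in seq_len(n_bonds)) {
    ln <- bond_lines[b]
    lineno <- 4 + n_atoms + b
    bonds$i[b] <- parse_int(field(ln, 1, 3), "bond atom 1", record, lineno)
    bonds$j[b] <- parse_int(field(ln, 4, 6), "bond atom 2", record, lineno)
    bonds$order[b] <- parse_int(field(ln, 7, 9), "bond order", record, lineno)
    if (bonds$i[b] < 1 || bonds$i[b] > n_atoms ||
        bonds$j[b] < 1 || bonds$j[b] > n_atoms) {
      stop_format("SDF record %d, line %d: bond index out of range (N = %d)",
                  record, lineno, n_atoms)
    }
  }

  # property block: scan for M  CHG until M  END
  prop <- rec[seq.int(4 + n_atoms + n_bonds + 1, length.out =
                        max(0L, length(rec) - 4 - n_atoms - n_bonds))]
  in_props <- TRUE
  for (idx in seq_along(prop)) {
    ln <- prop[idx]
    if (!in_props) break
    if (startsWith(ln, "M  END")) in_props <- FALSE
    if (startsWith(ln, "M  CHG")) {
      lineno <- 4 + n_atoms + n_bonds + idx
      toks <- strsplit(trimws(substring(ln, 7)), "\\s+")[[1]]
      cnt <- parse_int(toks[1], "M CHG count", record, lineno)
      if (length(toks) != 1 + 2 * cnt) {
        stop_format("SDF record %d, line %d: M  CHG declares %d pairs but carries %d fields",
                    record, lineno, cnt, length(toks) - 1)
      }
      for (p in seq_len(cnt)) {
        ai <- parse_int(toks[2 * p], "M CHG atom index", record, lineno)
        ch <- parse_int(toks[2 * p + 1], "M CHG charge", record, lineno)
        if (ai < 1 || ai > n_atoms) {
          stop_format("SDF record %d, line %d: M  CHG atom index %d out of range",
                      record, lineno, ai)
        }
        atoms$formal_charge[ai] <- ch
      }
    }
  }

  eem_molecule(name, atoms, bonds)
}

#' Write molecules to an MDL SDF (V2000) file
#'
#' Coordinates are written in the fixed 10.4f V2000 columns; non-zero
#' formal charges are emitted as `M  CHG` lines.
#'
#' @param molecules a list of [eem_molecule()] objects.
#' @param path output path; omit to return the lines invisibly.
#' @return Invisibly, the character vector of file lines.
#' @export
write_sdf <- function(molecules, path = NULL) {
  check_molecule_list(molecules)
  out <- unlist(lapply(molecules, format_molfile), use.names = FALSE)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

format_molfile <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  lines <- c(
    mol$name, "  eemkit", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element)
  )
  if (nrow(b) > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", b$i, b$j, b$order))
  }
  charged <- which(a$formal_charge != 0L)
  if (length(charged) > 0) {
    # MDL allows at most 8 pairs per M CHG line
    for (chunk in split(charged, ceiling(seq_along(charged) / 8))) {
      lines <- c(lines, paste0(
        "M  CHG", sprintf("%3d", length(chunk)),
        paste0(sprintf("%4d%4d", chunk, a$formal_charge[chunk]),
               collapse = "")))
    }
  }
  c(lines, "M  END", "$$$$")
}
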
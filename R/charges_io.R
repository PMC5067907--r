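#' Charge sets
#'
#' A charge set maps molecule names to per-atom charge vectors (elementary
#' charge units) aligned with the molecule's atom order. Both reference
#' (quantum-mechanical) charges and EEM-computed charges travel in this
#' container, so calculation output can feed validation input directly.
#'
#' @param charges a named list of numeric vectors.
#' @return An object of class `eem_charge_set` (a named list).
#' @export
charge_set <- function(charges = list()) {
  if (length(charges) > 0) {
    if (is.null(names(charges)) || any(!nzchar(names(charges)))) {
      stop_usage("charge_set: every molecule vector must be named")
    }
    if (anyDuplicated(names(charges))) {
      stop_format("charge_set: duplicate molecule name(s): %s",
                  paste(unique(names(charges)[duplicated(names(charges))]),
                        collapse = ", "))
    }
    charges <- lapply(charges, as.numeric)
  }
  structure(charges, class = "eem_charge_set")
}

#' @export
print.eem_charge_set <- function(x, ...) {
  cat(sprintf("<eem_charge_set> %d molecule(s), %d atoms total\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' @export
as_tibble.eem_charge_set <- function(x, ...) {
  if (length(x) == 0) {
    return(tibble(molecule = character(), atom = integer(),
                  charge = double()))
  }
  dplyr::bind_rows(purrr::imap(unclass(x), function(q, nm) {
    tibble(molecule = nm, atom = seq_along(q), charge = as.numeric(q))
  }))
}

#' Read a per-atom charge file
#'
#' Plain-text format, one block per molecule: line 1 the molecule name,
#' line 2 the atom count N, then N lines `"<1-based index> <element>
#' <charge>"`; blocks separated by one blank line. A count line that
#' disagrees with the number of charge lines, a non-numeric charge, or a
#' duplicate molecule name is a format error. An empty file yields an
#' empty charge set.
#'
#' @param path path to the charge file, or lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return An [charge_set()] in file order.
#' @export
read_charges <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  charges <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    name <- trimws(lines[i])
    if (name %in% names(charges)) {
      stop_format("charge file line %d: duplicate molecule name '%s'", i, name)
    }
    if (i + 1L > n_lines) {
      stop_format("charge file line %d: molecule '%s' lacks an atom count line",
                  i, name)
    }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n < 1) {
      stop_format("charge file line %d: unreadable atom count '%s'",
                  i + 1L, trimws(lines[i + 1L]))
    }
    block_end <- i + 1L + n
    if (block_end > n_lines ||
        any(!nzchar(trimws(lines[seq.int(i + 2L, block_end)])))) {
      stop_format("charge file: molecule '%s' declares %d atoms but the block has fewer charge lines",
                  name, n)
    }
    if (block_end < n_lines && nzchar(trimws(lines[block_end + 1L]))) {
      stop_format("charge file: molecule '%s' declares %d atoms but the block has more charge lines",
                  name, n)
    }
    q <- numeric(n)
    for (k in seq_len(n)) {
      toks <- strsplit(trimws(lines[i + 1L + k]), "\\s+")[[1]]
      if (length(toks) < 3) {
        stop_format("charge file line %d: expected '<index> <element> <charge>'",
                    i + 1L + k)
      }
      val <- suppressWarnings(as.numeric(toks[3]))
      if (is.na(val)) {
        stop_format("charge file line %d: non-numeric charge '%s'",
                    i + 1L + k, toks[3])
      }
      q[k] <- val
    }
    charges[[name]] <- q
    i <- block_end + 1L
  }
  charge_set(charges)
}

#' Write a per-atom charge file
#'
#' Inverse of [read_charges()]. Element symbols are taken from `molecules`
#' when supplied (matched by name), otherwise written as `"X"`.
#'
#' @param charges an [charge_set()].
#' @param path output path; omit to return lines invisibly.
#' @param molecules optional list of molecules supplying element symbols.
#' @return Invisibly, the character vector of file lines.
#' @export
write_charges <- function(charges, path = NULL, molecules = NULL) {
  if (!inherits(charges, "eem_charge_set")) {
    stop_usage("`charges` must be an eem_charge_set")
  }
  mol_by_name <- if (!is.null(molecules)) {
    setNames(molecules, molecule_names(molecules))
  }
  blocks <- purrr::imap(unclass(charges), function(q, nm) {
    elements <- if (!is.null(mol_by_name) && nm %in% names(mol_by_name)) {
      mol_by_name[[nm]]$atoms$element
    } else {
      rep("X", length(q))
    }
    c(nm, as.character(length(q)),
      sprintf("%d %s %.17g", seq_along(q), elements, q), "")
  })
  out <- head(unlist(blocks, use.names = FALSE), -1)
  if (length(out) == 0) out <- character(0)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Match a charge set to a molecule list
#'
#' Matches by molecule name, or by position when `by_order = TRUE` (for
#' charge files whose names do not match the SDF titles). A count or
#' length mismatch is always fatal.
#'
#' @param molecules list of molecules.
#' @param charges an [charge_set()].
#' @param by_order match blocks to molecules by position instead of name.
#' @return A charge set named and ordered like `molecules`.
#' @export
align_charges <- function(molecules, charges, by_order = FALSE) {
  check_molecule_list(molecules)
  nms <- molecule_names(molecules)
  if (by_order) {
    if (length(charges) != length(molecules)) {
      stop_format("charge file has %d block(s) but there are %d molecule(s)",
                  length(charges), length(molecules))
    }
    out <- setNames(unclass(charges), nms)
  } else {
    missing <- setdiff(nms, names(charges))
    if (length(missing) > 0) {
      stop_format("no reference charges for molecule(s): %s",
                  paste(missing, collapse = ", "))
    }
    out <- unclass(charges)[nms]
  }
  n_atoms <- vapply(molecules, function(m) nrow(m$atoms), integer(1))
  bad <- which(lengths(out) != n_atoms)
  if (length(bad) > 0) {
    stop_format("charge vector length mismatch for molecule(s): %s",
                paste(nms[bad], collapse = ", "))
  }
  charge_set(out)
}
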
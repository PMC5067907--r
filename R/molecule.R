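#' Construct a molecule
#'
#' A molecule is an ordered set of atoms with 3D coordinates and formal
#' charges, plus a bond list carrying integer bond orders. The total charge
#' `Q` is the sum of the atomic formal charges. Atom types (element plus
#' maximal incident bond order, e.g. `"N3"`) are assigned separately by
#' [assign_atom_types()].
#'
#' @param name molecule identifier.
#' @param atoms a data frame with columns `element` (chemical symbol,
#'   case-sensitive), `x`, `y`, `z` (coordinates in Angstrom) and optionally
#'   `formal_charge` (integer, default 0).
#' @param bonds a data frame with columns `i`, `j` (1-based atom indices)
#'   and `order` (integer bond order); may have zero rows.
#'
#' @return An object of class `eem_molecule`: a list with `name`, an
#'   `atoms` tibble (gaining `max_bond_order` and `atom_type` columns once
#'   typed), a `bonds` tibble, and `total_charge`.
#' @seealso [read_sdf()], [assign_atom_types()]
#' @export
eem_molecule <- function(name, atoms, bonds = NULL) {
  atoms <- as_tibble(atoms)
  required <- c("element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop_format("molecule '%s': atoms lack column(s) %s",
                name, paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) < 1) stop_format("molecule '%s': needs at least one atom", name)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop_format("molecule '%s': non-finite coordinates", name)
  }
  unknown <- unique(atoms$element[!is_known_element(atoms$element)])
  if (length(unknown) > 0) {
    stop_format("molecule '%s': unknown element symbol(s): %s",
                name, paste(unknown, collapse = ", "))
  }
  if (!"formal_charge" %in% names(atoms)) atoms$formal_charge <- 0L
  atoms$formal_charge <- as.integer(atoms$formal_charge)

  if (is.null(bonds) || nrow(as_tibble(bonds)) == 0) {
    bonds <- tibble(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as_tibble(bonds)
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    n <- nrow(atoms)
    if (any(bonds$i == bonds$j)) {
      stop_format("molecule '%s': bond with identical endpoints", name)
    }
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)) {
      stop_format("molecule '%s': bond index out of range (N = %d)", name, n)
    }
  }

  structure(
    list(
      name = as.character(name),
      atoms = atoms,
      bonds = bonds,
      total_charge = sum(atoms$formal_charge)
    ),
    class = "eem_molecule"
  )
}

#' @export
print.eem_molecule <- function(x, ...) {
  typed <- "atom_type" %in% names(x$atoms)
  cat(sprintf("<eem_molecule> %s: %d atoms, %d bonds, Q = %d%s\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$total_charge,
              if (typed) paste0(" [", paste(sort(unique(x$atoms$atom_type)),
                                            collapse = " "), "]")
              else " (untyped)"))
  invisible(x)
}

#' @export
as_tibble.eem_molecule <- function(x, ...) {
  dplyr::mutate(x$atoms, molecule = x$name, atom = dplyr::row_number(),
                .before = 1)
}

#' Flatten a molecule list into one atom-level tibble
#'
#' @param molecules a list of [eem_molecule()] objects.
#' @return A tibble with one row per atom: `molecule`, `atom` (1-based
#'   index), `element`, coordinates, `formal_charge`, and the typing
#'   columns if assigned.
#' @export
molecule_table <- function(molecules) {
  if (length(molecules) == 0) {
    return(tibble(molecule = character(), atom = integer(),
                  element = character(), x = double(), y = double(),
                  z = double(), formal_charge = integer()))
  }
  dplyr::bind_rows(lapply(molecules, as_tibble))
}

molecule_names <- function(molecules) {
  unname(vapply(molecules, function(m) m$name, character(1)))
}

check_molecule_list <- function(molecules, arg = "molecules") {
  ok <- is.list(molecules) &&
    all(vapply(molecules, inherits, logical(1), "eem_molecule"))
  if (!ok) stop_usage("`%s` must be a list of eem_molecule objects", arg)
  invisible(molecules)
}

check_typed <- function(molecules) {
  untyped <- vapply(molecules, function(m) {
    !"atom_type" %in% names(m$atoms)
  }, logical(1))
  if (any(untyped)) {
    stop_usage("atom types not assigned for molecule(s): %s (run assign_atom_types())",
               paste(molecule_names(molecules)[untyped], collapse = ", "))
  }
  invisible(molecules)
}
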
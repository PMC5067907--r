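#' Assign EEM atom types
#'
#' An atom type is the element symbol concatenated with the atom's maximal
#' incident bond order, e.g. `"N3"` for a nitrogen involved in at least one
#' triple bond. An isolated atom (no bonds) is assigned order 1, the lowest
#' order in the type vocabulary.
#'
#' Aromatic bond order 4 has no place in the element-plus-order vocabulary
#' (orders 1-3 only). By default such records are rejected with advice to
#' kekulize the input; `map_aromatic = TRUE` maps order 4 to 2 instead.
#'
#' @param molecule an [eem_molecule()].
#' @param map_aromatic map aromatic order 4 to 2 instead of erroring.
#' @return The molecule with `max_bond_order` and `atom_type` columns
#'   filled in on its `atoms` tibble.
#' @export
assign_atom_types <- function(molecule, map_aromatic = FALSE) {
  if (!inherits(molecule, "eem_molecule")) {
    stop_usage("`molecule` must be an eem_molecule")
  }
  bonds <- molecule$bonds
  orders <- bonds$order
  if (any(orders == 4L)) {
    if (!map_aromatic) {
      stop_format(paste0(
        "molecule '%s': aromatic bond order 4 present; supply a kekulized ",
        "structure or use map_aromatic = TRUE to map order 4 -> 2"),
        molecule$name)
    }
    orders[orders == 4L] <- 2L
  }
  if (any(!orders %in% 1:3)) {
    stop_format("molecule '%s': bond order outside 1-3", molecule$name)
  }

  n <- nrow(molecule$atoms)
  max_order <- rep(1L, n)  # isolated atoms default to order 1
  if (nrow(bonds) > 0) {
    incident <- c(bonds$i, bonds$j)
    per_atom <- tapply(c(orders, orders), incident, max)
    max_order[as.integer(names(per_atom))] <- as.integer(per_atom)
  }
  molecule$atoms$max_bond_order <- max_order
  molecule$atoms$atom_type <- paste0(molecule$atoms$element, max_order)
  molecule
}

#' Atom types present in a molecule collection
#'
#' @param molecules list of typed molecules.
#' @return Sorted character vector: the union of atom types over all
#'   molecules.
#' @export
dataset_atom_types <- function(molecules) {
  check_molecule_list(molecules)
  check_typed(molecules)
  sort(unique(unlist(lapply(molecules, function(m) m$atoms$atom_type))))
}
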
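#' Interatomic distance matrix
#'
#' @param molecule an [eem_molecule()].
#' @return The N x N symmetric matrix of Euclidean distances in Angstrom
#'   (zero diagonal). Any off-diagonal distance below `1e-6` Angstrom is a
#'   degenerate-geometry error: the EEM coupling `kappa / R_ij` would blow
#'   up.
#' @export
distance_matrix <- function(molecule) {
  if (!inherits(molecule, "eem_molecule")) {
    stop_usage("`molecule` must be an eem_molecule")
  }
  xyz <- as.matrix(molecule$atoms[, c("x", "y", "z")])
  R <- as.matrix(stats::dist(xyz))
  dimnames(R) <- NULL
  if (nrow(R) > 1) {
    off <- R[upper.tri(R)]
    if (any(off < 1e-6)) {
      stop_numeric("molecule '%s': degenerate geometry (interatomic distance < 1e-6 Angstrom)",
                   molecule$name)
    }
  }
  R
}

# 1/R with zero diagonal; shared precomputation for the solve paths.
inverse_distance <- function(molecule) {
  R <- distance_matrix(molecule)
  invR <- matrix(0, nrow(R), ncol(R))
  if (nrow(R) > 1) {
    nz <- R > 0
    invR[nz] <- 1 / R[nz]
  }
  invR
}

#' Assemble the EEM linear system for one molecule
#'
#' Builds the (N+1) x (N+1) bordered system: row `i <= N` has diagonal
#' `B_type(i)`, off-diagonal `kappa / R_ij`, last column `-1` and
#' right-hand side `-A_type(i)`; the final row is ones over the charge
#' columns with zero in the corner and right-hand side `Q`. Solving it
#' yields the charges `q_1..q_N` and the molecular electronegativity.
#'
#' @param molecule a typed [eem_molecule()].
#' @param set an [parameter_set()] covering all the molecule's atom types.
#' @return A list with `matrix` ((N+1) x (N+1)) and `rhs` (length N+1).
#' @export
build_eem_system <- function(molecule, set) {
  check_typed(list(molecule))
  if (!inherits(set, "eem_parameter_set")) {
    stop_usage("`set` must be an eem_parameter_set")
  }
  types <- molecule$atoms$atom_type
  par <- tryCatch(param_lookup(set, types), eem_usage_error = function(e) {
    stop_usage("molecule '%s' is not covered: %s", molecule$name,
               conditionMessage(e))
  })
  n <- length(types)
  invR <- inverse_distance(molecule)
  M <- matrix(0, n + 1, n + 1)
  M[seq_len(n), seq_len(n)] <- set$kappa * invR
  diag(M)[seq_len(n)] <- par$B
  M[seq_len(n), n + 1] <- -1
  M[n + 1, seq_len(n)] <- 1
  M[n + 1, n + 1] <- 0
  rhs <- c(-par$A, molecule$total_charge)
  list(matrix = M, rhs = rhs)
}

#' Solve EEM charges for one molecule
#'
#' Solves the bordered system of [build_eem_system()] by a dense direct
#' method with a reciprocal-condition singularity check (default
#' threshold `1e-12`). The solution satisfies charge conservation
#' (`sum(q) = Q`) and electronegativity equalization by construction, to
#' numerical precision.
#'
#' @inheritParams build_eem_system
#' @param rcond_min reciprocal-condition threshold below which the system
#'   is treated as numerically singular.
#' @return An `eem_solution`: list with `charges` (length N) and
#'   `chi_bar` (the molecular electronegativity).
#' @export
solve_charges <- function(molecule, set, rcond_min = 1e-12) {
  check_typed(list(molecule))
  types <- molecule$atoms$atom_type
  par <- tryCatch(param_lookup(set, types), eem_usage_error = function(e) {
    stop_usage("molecule '%s' is not covered: %s", molecule$name,
               conditionMessage(e))
  })
  invR <- inverse_distance(molecule)
  idx <- match(types, set$entries$atom_type) - 1L
  res <- .eem_solve_cpp(invR, idx, set$entries$A, set$entries$B,
                        set$kappa, molecule$total_charge, rcond_min)
  if (!isTRUE(res$ok)) {
    stop_numeric("molecule '%s': EEM system is numerically singular",
                 molecule$name)
  }
  structure(list(charges = res$charges, chi_bar = res$chi),
            class = "eem_solution")
}

#' @export
print.eem_solution <- function(x, ...) {
  cat(sprintf("<eem_solution> %d charges (sum = %.6g), chi_bar = %.6g\n",
              length(x$charges), sum(x$charges), x$chi_bar))
  invisible(x)
}

#' Calculate EEM charges for a molecule collection
#'
#' Per-molecule solves are independent and share no mutable state, so any
#' evaluation order — including concurrent — yields bit-identical results
#' in input order; `threads` is a pure speed option.
#'
#' @param molecules list of typed molecules.
#' @param set an [parameter_set()].
#' @param skip_uncovered drop (and message about) molecules containing an
#'   atom type absent from the set instead of erroring.
#' @param threads number of worker processes for the per-molecule loop
#'   (uses forked workers where available; 1 = serial).
#' @inheritParams solve_charges
#' @return An [charge_set()] with one vector per (covered) molecule, in
#'   input order.
#' @export
calculate_charges <- function(molecules, set, skip_uncovered = FALSE,
                              threads = 1L, rcond_min = 1e-12) {
  check_molecule_list(molecules)
  if (length(molecules) == 0) return(charge_set())
  check_typed(molecules)

  known <- set$entries$atom_type
  uncovered <- vapply(molecules, function(m) {
    !all(m$atoms$atom_type %in% known)
  }, logical(1))
  if (any(uncovered)) {
    nms <- molecule_names(molecules)[uncovered]
    if (!skip_uncovered) {
      stop_usage("molecule(s) not covered by parameter set '%s': %s",
                 set$name, paste(nms, collapse = ", "))
    }
    inform(sprintf("skipping %d uncovered molecule(s): %s",
                   length(nms), paste(nms, collapse = ", ")))
    molecules <- molecules[!uncovered]
    if (length(molecules) == 0) return(charge_set())
  }

  solve_fun <- function(m) solve_charges(m, set, rcond_min)$charges
  results <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(molecules, solve_fun, mc.cores = threads)
  } else {
    lapply(molecules, solve_fun)
  }
  err <- vapply(results, inherits, logical(1), "try-error")
  if (any(err)) stop_numeric("EEM solve failed for %d molecule(s)", sum(err))
  charge_set(setNames(results, molecule_names(molecules)))
}

# --- internal fast path used by parameterization --------------------------

# Precompute per-molecule solver inputs keyed to a fixed, sorted type
# vocabulary: 0-based type indices, 1/R matrix, total charge, plus pooled
# reference charges and pooled type codes for metric evaluation.
solver_data <- function(molecules, ref_charges, types = NULL) {
  check_typed(molecules)
  types <- types %||% dataset_atom_types(molecules)
  ref <- align_charges(molecules, ref_charges)
  mols <- lapply(molecules, function(m) {
    idx <- match(m$atoms$atom_type, types) - 1L
    if (anyNA(idx)) {
      stop_usage("molecule '%s' has type(s) outside the fitting vocabulary",
                 m$name)
    }
    list(invR = inverse_distance(m), types = idx,
         Q = as.numeric(m$total_charge))
  })
  list(
    types = types,
    mols = mols,
    n_atoms = vapply(molecules, function(m) nrow(m$atoms), integer(1)),
    names = molecule_names(molecules),
    ref_pooled = unlist(unclass(ref), use.names = FALSE),
    type_pooled = unlist(lapply(molecules, function(m) m$atoms$atom_type),
                         use.names = FALSE)
  )
}

# Pooled EEM charges under flat (A, B, kappa) for precomputed solver data.
# Returns NULL when any per-molecule system is singular.
pooled_charges <- function(sd, A, B, kappa, rcond_min = 1e-12) {
  res <- .eem_pooled_cpp(sd$mols, A, B, kappa, rcond_min)
  if (!isTRUE(res$ok)) return(NULL)
  res$charges
}
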
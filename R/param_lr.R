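# Linear-regression parameterization.
#
# For fixed kappa, every atom i of molecule m satisfies (with reference
# charges q):
#     A_t(i) + B_t(i) q_i + kappa * S_i = chi_m,   S_i = sum_{j != i} q_j / R_ij
# The per-molecule electronegativities chi_m are nuisance unknowns; they
# are eliminated exactly by centering each molecule's rows (fixed-effects
# absorption). What remains is a joint linear least-squares problem in
# {A_t, B_t}. Two exact gauge freedoms make the unnormalized problem
# kappa-flat: a uniform shift of all A (a null direction of the centered
# design) and a joint positive scaling of (A, B, kappa). The scale gauge
# is fixed by constraining B of a reference atom type to 1 during the fit;
# the shift gauge is handled by a minimum-norm (SVD) solution.

#' Centered electronegativity design for LR parameterization
#'
#' Builds one row per atom encoding
#' `A_type(i) + B_type(i) * q_i + kappa * S_i - chi_m ~ 0`, with the
#' per-molecule electronegativity `chi_m` eliminated by within-molecule
#' centering. Columns are A indicators per atom type followed by B
#' columns (`q_i` in the atom's type column).
#'
#' Identifiability requires every atom type to appear on at least 2 atoms
#' with at least 2 distinct reference-charge values across the training
#' set; a degenerate type raises an error naming it.
#'
#' @param molecules list of typed molecules.
#' @param ref_charges reference [charge_set()].
#' @param kappa the fixed distance-coupling scale for the targets.
#' @return A list: `X` (centered design, one row per atom), `y` (centered
#'   targets `-kappa * S_i`), `types` (sorted type vocabulary), `molecule`
#'   (row grouping), `atom_type` (per-row type).
#' @export
electronegativity_design <- function(molecules, ref_charges, kappa) {
  d <- lr_design(molecules, ref_charges)
  list(X = d$X, y = -kappa * d$s, types = d$types, molecule = d$molecule,
       atom_type = d$atom_type)
}

# kappa-independent pieces: centered design X and centered Coulomb sums s,
# so that the target vector at any kappa is just -kappa * s.
lr_design <- function(molecules, ref_charges) {
  check_molecule_list(molecules)
  check_typed(molecules)
  ref <- align_charges(molecules, ref_charges)
  types <- dataset_atom_types(molecules)

  type_pooled <- unlist(lapply(molecules, function(m) m$atoms$atom_type),
                        use.names = FALSE)
  q_pooled <- unlist(unclass(ref), use.names = FALSE)

  # identifiability screen per type
  for (t in types) {
    qs <- q_pooled[type_pooled == t]
    if (length(qs) < 2 || length(unique(qs)) < 2) {
      stop_numeric(paste0(
        "atom type '%s' is not identifiable: needs >= 2 atoms with >= 2 ",
        "distinct reference charges in the training set"), t)
    }
  }

  Tn <- length(types)
  n_atoms <- vapply(molecules, function(m) nrow(m$atoms), integer(1))
  n_rows <- sum(n_atoms)
  X <- matrix(0, n_rows, 2 * Tn)
  s <- numeric(n_rows)
  mol_id <- rep(molecule_names(molecules), n_atoms)

  row0 <- 0L
  for (m in molecules) {
    n <- nrow(m$atoms)
    q <- ref[[m$name]]
    invR <- inverse_distance(m)
    S <- as.numeric(invR %*% q)
    t_idx <- match(m$atoms$atom_type, types)
    rows <- row0 + seq_len(n)
    X[cbind(rows, t_idx)] <- 1          # A columns
    X[cbind(rows, Tn + t_idx)] <- q     # B columns
    s[rows] <- S
    # within-molecule centering absorbs chi_m exactly
    X[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                       colMeans(X[rows, , drop = FALSE]))
    s[rows] <- S - mean(S)
    row0 <- row0 + n
  }
  colnames(X) <- c(paste0("A_", types), paste0("B_", types))
  list(X = X, s = s, types = types, molecule = mol_id,
       atom_type = type_pooled, q = q_pooled)
}

# reference type for the scale gauge: H1 if present, else most frequent
pick_reference_type <- function(types, type_pooled) {
  if ("H1" %in% types) return("H1")
  names(sort(table(type_pooled), decreasing = TRUE))[1]
}

# SVD machinery shared across the kappa grid: with B_t0 fixed to 1, the
# t0 B column moves to the response and the rest is solved minimum-norm.
lr_solver <- function(design, reference_type = NULL) {
  types <- design$types
  t0 <- reference_type %||% pick_reference_type(types, design$atom_type)
  if (!t0 %in% types) {
    stop_usage("reference type '%s' not present in the training set", t0)
  }
  b0_col <- length(types) + match(t0, types)
  X <- design$X[, -b0_col, drop = FALSE]
  x_b0 <- design$X[, b0_col]
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > tol
  # after fixing the scale gauge, exactly one null direction is expected
  # (the uniform shift of all A); more signals genuine rank deficiency
  n_null <- sum(!keep)
  if (n_null > 1) {
    offending <- unique(unlist(lapply(which(!keep), function(k) {
      v <- sv$v[, k]
      sub("^[AB]_", "", colnames(X)[abs(v) > 0.1])
    })))
    stop_numeric("design is rank-deficient beyond the uniform-shift gauge (affected type(s): %s)",
                 paste(sort(offending), collapse = ", "))
  }
  list(sv = sv, keep = keep, x_b0 = x_b0, t0 = t0, types = types)
}

lr_solve_at <- function(solver, design, kappa) {
  # response: centered -kappa*S minus the pinned B_t0 column (coefficient 1)
  y <- -kappa * design$s - solver$x_b0
  sv <- solver$sv
  d_inv <- ifelse(solver$keep, 1 / sv$d, 0)
  beta <- sv$v %*% (d_inv * crossprod(sv$u, y))
  types <- solver$types
  Tn <- length(types)
  A <- beta[seq_len(Tn)]
  B_rest <- beta[Tn + seq_len(Tn - 1)]
  B <- numeric(Tn)
  B[match(solver$t0, types)] <- 1
  B[-match(solver$t0, types)] <- B_rest
  list(A = as.numeric(A), B = B, types = types, t0 = solver$t0)
}

#' Least-squares fit of (A, B) at a fixed kappa
#'
#' Fits all per-type `A_t` and `B_t` jointly against reference charges at
#' one value of `kappa`, with the scale gauge fixed by `B = 1` for the
#' reference atom type (`"H1"` when present, otherwise the most frequent
#' type) and the uniform-A-shift gauge resolved by the minimum-norm
#' solution. Fitted `B` values are not sign-constrained; non-positive
#' ones are let through with a warning (the candidate can still be
#' evaluated, and candidates whose EEM solve fails score worst during
#' selection).
#'
#' @inheritParams electronegativity_design
#' @param reference_type atom type whose `B` is pinned to 1; default
#'   `"H1"` if present, else the most frequent type.
#' @param name name for the returned parameter set.
#' @param qm_label reference-method label for the returned set.
#' @return An [parameter_set()] with the given `kappa`.
#' @export
fit_at_kappa <- function(molecules, ref_charges, kappa,
                         reference_type = NULL, name = "lr_fit",
                         qm_label = "reference") {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0) {
    stop_usage("`kappa` must be a single positive number")
  }
  design <- lr_design(molecules, ref_charges)
  solver <- lr_solver(design, reference_type)
  fit <- lr_solve_at(solver, design, kappa)
  if (any(fit$B <= 0)) {
    warn(sprintf("fit at kappa = %g: non-positive B for type(s) %s (weak identifiability)",
                 kappa, paste(fit$types[fit$B <= 0], collapse = ", ")))
  }
  parameter_set(kappa = kappa,
                entries = tibble(atom_type = fit$types, A = fit$A, B = fit$B),
                name = name, qm_label = qm_label, strict = FALSE)
}

# evaluate a candidate set on precomputed solver data; failures -> NULL
candidate_metrics <- function(sd, set) {
  par <- tryCatch(param_lookup(set, sd$types), error = function(e) NULL)
  if (is.null(par)) return(NULL)
  q <- pooled_charges(sd, par$A, par$B, set$kappa)
  if (is.null(q)) return(NULL)
  metric_eval(sd$ref_pooled, q, sd$type_pooled)
}

metric_value <- function(metrics, metric) {
  if (metric == "r2") metrics$R2 else metrics$avg_rmsd_a
}

metric_improves <- function(new, old, metric, tol = 1e-12) {
  if (is.na(new)) return(FALSE)
  if (is.na(old)) return(TRUE)
  if (metric == "r2") new > old + tol else new < old - tol
}

#' Linear-regression parameterization with a kappa scan
#'
#' Fits `(A_t, B_t)` by least squares at every `kappa` on a grid, computes
#' full EEM charges for each candidate, scores it by the selection metric
#' — pooled `R^2` (maximized) or the average per-atom-type RMSD
#' `avg(RMSD_a)` (minimized) — and returns the best candidate. Ties are
#' broken toward the smaller `kappa`. With `discard = "greedy"`, a greedy
#' molecule-discard search ([discard_search()]) is run instead.
#'
#' @inheritParams fit_at_kappa
#' @param kappa_min,kappa_max,kappa_step the kappa grid (defaults 0.05 to
#'   1.50 in steps of 0.05).
#' @param metric `"rmsd"` (minimize avg per-type RMSD, the default) or
#'   `"r2"` (maximize pooled squared Pearson correlation).
#' @param discard `"off"` or `"greedy"`.
#' @param max_discard_fraction cap on the fraction of molecules the greedy
#'   discard may remove.
#' @return An `eem_lr_fit` object: `set` (the winning [parameter_set()]),
#'   `quality` (its [eem_quality()] report), `profile` (per-kappa tibble
#'   with `kappa`, `R2`, `rmsd`, `avg_rmsd_a`, `ok`), `metric`, `kept` and
#'   `discarded` molecule names.
#' @export
parameterize_lr <- function(molecules, ref_charges,
                            kappa_min = 0.05, kappa_max = 1.5,
                            kappa_step = 0.05,
                            metric = c("rmsd", "r2"),
                            discard = c("off", "greedy"),
                            max_discard_fraction = 0.1,
                            reference_type = NULL,
                            name = "lr_fit", qm_label = "reference") {
  metric <- match.arg(metric)
  discard <- match.arg(discard)
  if (!is.numeric(kappa_min) || kappa_min <= 0) {
    stop_usage("kappa_min must be > 0")
  }
  if (kappa_step <= 0) stop_usage("kappa_step must be > 0")
  if (kappa_max < kappa_min) stop_usage("kappa_max must be >= kappa_min")

  if (discard == "greedy") {
    return(discard_search(molecules, ref_charges,
                          kappa_min = kappa_min, kappa_max = kappa_max,
                          kappa_step = kappa_step, metric = metric,
                          max_discard_fraction = max_discard_fraction,
                          reference_type = reference_type, name = name,
                          qm_label = qm_label))
  }

  grid <- seq(kappa_min, kappa_max, by = kappa_step)
  lr_scan(molecules, ref_charges, grid, metric, reference_type, name,
          qm_label)
}

lr_scan <- function(molecules, ref_charges, grid, metric, reference_type,
                    name, qm_label, discarded = character(0)) {
  check_molecule_list(molecules)
  design <- lr_design(molecules, ref_charges)
  solver <- lr_solver(design, reference_type)
  sd <- solver_data(molecules, ref_charges, types = design$types)

  rows <- vector("list", length(grid))
  candidates <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    kap <- grid[k]
    res <- tryCatch({
      fit <- lr_solve_at(solver, design, kap)
      # non-positive fitted B is recorded per candidate, not warned per
      # grid point; the candidate is still evaluated
      note <- if (any(fit$B <= 0)) {
        sprintf("non-positive B for type(s) %s",
                paste(fit$types[fit$B <= 0], collapse = ", "))
      } else ""
      set <- suppressWarnings(parameter_set(
        kappa = kap,
        entries = tibble(atom_type = fit$types, A = fit$A, B = fit$B),
        name = name, qm_label = qm_label, strict = FALSE))
      m <- candidate_metrics(sd, set)
      list(set = set, metrics = m,
           note = if (is.null(m)) {
             paste0("EEM solve failed",
                    if (nzchar(note)) paste0("; ", note))
           } else note)
    }, error = function(e) list(set = NULL, metrics = NULL,
                                note = conditionMessage(e)))
    m <- res$metrics
    rows[[k]] <- tibble(
      kappa = kap,
      R2 = if (is.null(m)) NA_real_ else m$R2,
      rmsd = if (is.null(m)) NA_real_ else m$rmsd,
      avg_rmsd_a = if (is.null(m)) NA_real_ else m$avg_rmsd_a,
      ok = !is.null(m),
      note = res$note
    )
    candidates[[k]] <- res$set
  }
  profile <- dplyr::bind_rows(rows)

  score <- if (metric == "r2") profile$R2 else profile$avg_rmsd_a
  score[!profile$ok | is.na(score)] <- NA_real_
  if (all(is.na(score))) {
    stop_numeric("all kappa candidates failed:\n%s",
                 paste(sprintf("  kappa = %g: %s", profile$kappa,
                               profile$note), collapse = "\n"))
  }
  # which.min/max return the first optimum; the grid is ascending, so
  # ties already break toward the smaller kappa
  best_k <- if (metric == "r2") which.max(score) else which.min(score)
  best_set <- candidates[[best_k]]

  eem <- suppressMessages(calculate_charges(molecules, best_set))
  quality <- eem_quality(molecules, ref_charges, eem, set = best_set)

  structure(
    list(set = best_set, quality = quality, profile = profile,
         metric = metric, kept = molecule_names(molecules),
         discarded = discarded),
    class = "eem_lr_fit"
  )
}

#' Greedy molecule-discard search around the LR fit
#'
#' Starting from the full-training-set LR fit, iteratively removes the
#' molecule with the worst per-molecule RMSD, refits at the incumbent
#' `kappa`, and keeps the removal only when the selection metric strictly
#' improves. The loop stops at the first non-improving removal or when
#' `max_discard_fraction` of the molecules has been removed; the kappa
#' grid is then re-scanned on the kept subset.
#'
#' @inheritParams parameterize_lr
#' @return An `eem_lr_fit` for the kept subset, with `discarded` listing
#'   the removed molecules.
#' @export
discard_search <- function(molecules, ref_charges,
                           kappa_min = 0.05, kappa_max = 1.5,
                           kappa_step = 0.05, metric = c("rmsd", "r2"),
                           max_discard_fraction = 0.1,
                           reference_type = NULL, name = "lr_fit",
                           qm_label = "reference") {
  metric <- match.arg(metric)
  if (max_discard_fraction < 0 || max_discard_fraction >= 1) {
    stop_usage("max_discard_fraction must be in [0, 1)")
  }
  grid <- seq(kappa_min, kappa_max, by = kappa_step)

  base <- lr_scan(molecules, ref_charges, grid, metric, reference_type,
                  name, qm_label)
  max_discards <- floor(max_discard_fraction * length(molecules))
  if (max_discards == 0) return(base)

  kept <- molecules
  discarded <- character(0)
  incumbent_kappa <- base$set$kappa
  incumbent_metric <- metric_value(
    list(R2 = base$quality$summary$R2, avg_rmsd_a = base$quality$avg_rmsd_a),
    metric)
  per_mol <- base$quality$per_molecule

  while (length(discarded) < max_discards && length(kept) > 2) {
    worst <- per_mol$molecule[which.max(per_mol$rmsd)]
    trial <- kept[molecule_names(kept) != worst]
    res <- tryCatch({
      set <- fit_at_kappa(trial, ref_charges, incumbent_kappa,
                          reference_type = reference_type, name = name,
                          qm_label = qm_label)
      sd <- solver_data(trial, ref_charges)
      list(set = set, metrics = candidate_metrics(sd, set), trial = trial)
    }, error = function(e) NULL)
    if (is.null(res) || is.null(res$metrics)) break
    new_metric <- metric_value(res$metrics, metric)
    if (!metric_improves(new_metric, incumbent_metric, metric)) break

    kept <- res$trial
    discarded <- c(discarded, worst)
    incumbent_metric <- new_metric
    eem <- suppressMessages(calculate_charges(kept, res$set))
    per_mol <- eem_quality(kept, ref_charges, eem)$per_molecule
  }

  if (length(discarded) == 0) return(base)
  lr_scan(kept, ref_charges, grid, metric, reference_type, name, qm_label,
          discarded = discarded)
}

#' @export
print.eem_lr_fit <- function(x, ...) {
  cat(sprintf("<eem_lr_fit> metric = %s, selected kappa = %g\n",
              x$metric, x$set$kappa))
  cat(sprintf("  R2 = %.6g  avg(RMSD_a) = %.6g e\n",
              x$quality$summary$R2, x$quality$avg_rmsd_a))
  if (length(x$discarded) > 0) {
    cat(sprintf("  discarded %d molecule(s): %s\n", length(x$discarded),
                paste(x$discarded, collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn parameterize_lr `tidy()` returns the per-kappa profile
#'   table.
#' @param x an `eem_lr_fit`.
#' @param ... unused.
#' @export
tidy.eem_lr_fit <- function(x, ...) x$profile

#' @describeIn parameterize_lr `glance()` returns a one-row summary of
#'   the winning candidate.
#' @export
glance.eem_lr_fit <- function(x, ...) {
  tibble(kappa = x$set$kappa, metric = x$metric,
         R2 = x$quality$summary$R2, rmsd = x$quality$summary$rmsd,
         avg_rmsd_a = x$quality$avg_rmsd_a,
         max_rmsd_a = x$quality$max_rmsd_a,
         n_molecules = length(x$kept), n_discarded = length(x$discarded))
}

#' @describeIn parameterize_lr `autoplot()` draws the selection metric
#'   across the kappa grid with the winner marked.
#' @param object an `eem_lr_fit`.
#' @export
autoplot.eem_lr_fit <- function(object, ...) {
  ycol <- if (object$metric == "r2") "R2" else "avg_rmsd_a"
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$kappa, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$set$kappa,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "kappa",
                  y = if (object$metric == "r2") expression(R^2)
                      else "avg(RMSD_a) (e)")
}
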
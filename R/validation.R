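# Comparison statistics between two aligned charge vectors. Correlations
# on constant (or too-short) vectors are reported as NA, never 0 or an
# error; error metrics are always defined.
safe_cor <- function(x, y, method) {
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  cor(x, y, method = method)
}

stat_block <- function(ref, eem) {
  d <- eem - ref
  R <- safe_cor(ref, eem, "pearson")
  rho <- safe_cor(ref, eem, "spearman")
  tibble(
    n = length(ref),
    R = R, R2 = R^2,
    spearman = rho, spearman2 = rho^2,
    rmsd = sqrt(mean(d^2)),
    delta = mean(abs(d)),
    delta_max = max(abs(d))
  )
}

#' Quality validation of EEM charges against reference charges
#'
#' Compares two aligned charge sets at three granularities: summary
#' statistics pooled over all atoms of all molecules; per-atom-type
#' statistics; and per-molecule statistics. The reported criteria are the
#' Pearson coefficient R and its square, the Spearman coefficient and its
#' square, the root-mean-square deviation (RMSD), the average absolute
#' difference (delta) and the maximal absolute difference (delta_max).
#'
#' The headline parameterization metric `avg_rmsd_a` is the unweighted
#' mean of per-type RMSD values over the atom types represented in the
#' data — every type counts equally regardless of abundance. `max_rmsd_a`
#' and `max_delta_a` are the corresponding per-type maxima.
#'
#' @param molecules list of typed molecules (supplies atom types and the
#'   alignment order).
#' @param ref_charges reference [charge_set()] (e.g. QM charges).
#' @param eem_charges EEM-computed [charge_set()].
#' @param set optional [parameter_set()]; its atom types absent from the
#'   data are listed in `per_type` with zero counts.
#' @return An `eem_quality` object: list with `summary` (1-row tibble),
#'   `per_type`, `per_molecule`, `avg_rmsd_a`, `max_rmsd_a`,
#'   `max_delta_a`, and the atom-level `scatter` table.
#' @export
eem_quality <- function(molecules, ref_charges, eem_charges, set = NULL) {
  check_molecule_list(molecules)
  if (length(molecules) == 0) stop_usage("empty molecule list")
  check_typed(molecules)
  ref <- align_charges(molecules, ref_charges)
  eem <- align_charges(molecules, eem_charges)

  scatter <- charge_scatter(molecules, ref, eem)
  if (nrow(scatter) < 2) {
    stop_usage("need at least 2 pooled atoms for quality statistics")
  }

  summary <- stat_block(scatter$ref, scatter$eem)

  per_type <- scatter |>
    dplyr::group_by(.data$atom_type) |>
    dplyr::reframe(stat_block(.data$ref, .data$eem)) |>
    dplyr::arrange(.data$atom_type)
  if (!is.null(set)) {
    absent <- setdiff(set$entries$atom_type, per_type$atom_type)
    if (length(absent) > 0) {
      per_type <- dplyr::bind_rows(
        per_type,
        tibble(atom_type = absent, n = 0L, R = NA_real_, R2 = NA_real_,
               spearman = NA_real_, spearman2 = NA_real_, rmsd = NA_real_,
               delta = NA_real_, delta_max = NA_real_)) |>
        dplyr::arrange(.data$atom_type)
    }
  }

  per_molecule <- scatter |>
    dplyr::group_by(molecule = .data$molecule) |>
    dplyr::reframe(stat_block(.data$ref, .data$eem))

  represented <- per_type[per_type$n > 0, ]
  structure(
    list(
      summary = summary,
      per_type = per_type,
      per_molecule = per_molecule,
      avg_rmsd_a = mean(represented$rmsd),
      max_rmsd_a = max(represented$rmsd),
      max_delta_a = max(represented$delta),
      scatter = scatter
    ),
    class = "eem_quality"
  )
}

#' @export
print.eem_quality <- function(x, digits = 4, ...) {
  s <- x$summary
  cat("<eem_quality>\n")
  cat(sprintf("  atoms: %d  molecules: %d  types: %d\n", s$n,
              nrow(x$per_molecule), sum(x$per_type$n > 0)))
  cat(sprintf("  R = %s  R2 = %s  rho = %s  rho2 = %s\n",
              format(s$R, digits = digits), format(s$R2, digits = digits),
              format(s$spearman, digits = digits),
              format(s$spearman2, digits = digits)))
  cat(sprintf("  RMSD = %s  delta = %s  delta_max = %s\n",
              format(s$rmsd, digits = digits),
              format(s$delta, digits = digits),
              format(s$delta_max, digits = digits)))
  cat(sprintf("  avg(RMSD_a) = %s  max(RMSD_a) = %s  max(delta_a) = %s\n",
              format(x$avg_rmsd_a, digits = digits),
              format(x$max_rmsd_a, digits = digits),
              format(x$max_delta_a, digits = digits)))
  invisible(x)
}

#' @describeIn eem_quality `tidy()` returns the per-type (default) or
#'   per-molecule statistics table.
#' @param x an `eem_quality` object.
#' @param level `"type"` or `"molecule"`.
#' @param ... unused.
#' @export
tidy.eem_quality <- function(x, level = c("type", "molecule"), ...) {
  level <- match.arg(level)
  if (level == "type") x$per_type else x$per_molecule
}

#' @describeIn eem_quality `glance()` returns the one-row summary plus the
#'   per-type aggregates.
#' @export
glance.eem_quality <- function(x, ...) {
  dplyr::mutate(x$summary, avg_rmsd_a = x$avg_rmsd_a,
                max_rmsd_a = x$max_rmsd_a, max_delta_a = x$max_delta_a)
}

#' @describeIn eem_quality `autoplot()` draws the reference-vs-EEM charge
#'   scatter, pooled (`by = "all"`) or faceted per atom type
#'   (`by = "type"`).
#' @param object an `eem_quality` object.
#' @param by `"all"` or `"type"`.
#' @export
autoplot.eem_quality <- function(object, by = c("all", "type"), ...) {
  by <- match.arg(by)
  p <- ggplot2::ggplot(object$scatter,
                       ggplot2::aes(x = .data$ref, y = .data$eem)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$atom_type),
                        alpha = 0.7) +
    ggplot2::labs(x = "reference charge (e)", y = "EEM charge (e)",
                  colour = "atom type")
  if (by == "type") {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$atom_type))
  }
  p
}

#' Atom-level charge comparison table
#'
#' Long-format table with one row per atom — enough to draw
#' reference-vs-EEM correlation plots for all atoms or per atom type.
#'
#' @inheritParams eem_quality
#' @return A tibble with columns `molecule`, `atom`, `element`,
#'   `atom_type`, `ref`, `eem`.
#' @export
charge_scatter <- function(molecules, ref_charges, eem_charges) {
  check_molecule_list(molecules)
  if (length(molecules) == 0) {
    return(tibble(molecule = character(), atom = integer(),
                  element = character(), atom_type = character(),
                  ref = double(), eem = double()))
  }
  check_typed(molecules)
  ref <- align_charges(molecules, ref_charges)
  eem <- align_charges(molecules, eem_charges)
  dplyr::bind_rows(lapply(molecules, function(m) {
    tibble(molecule = m$name, atom = seq_len(nrow(m$atoms)),
           element = m$atoms$element, atom_type = m$atoms$atom_type,
           ref = as.numeric(ref[[m$name]]), eem = as.numeric(eem[[m$name]]))
  }))
}

#' Coverage validation of a parameter set
#'
#' A molecule is covered by a parameter set iff every one of its atom
#' types has an entry in the set.
#'
#' @param molecules list of typed molecules.
#' @param set an [parameter_set()].
#' @return An `eem_coverage` object: `n_total`, `n_covered`,
#'   `percent_covered` (100 * covered / total), `covered_ids`,
#'   `uncovered_ids`, and `missing_types` (named list, uncovered molecule
#'   -> its uncovered atom types).
#' @export
eem_coverage <- function(molecules, set) {
  check_molecule_list(molecules)
  if (length(molecules) == 0) stop_usage("empty molecule list")
  check_typed(molecules)
  if (!inherits(set, "eem_parameter_set")) {
    stop_usage("`set` must be an eem_parameter_set")
  }
  known <- set$entries$atom_type
  nms <- molecule_names(molecules)
  missing_types <- lapply(molecules, function(m) {
    sort(setdiff(unique(m$atoms$atom_type), known))
  })
  names(missing_types) <- nms
  covered <- lengths(missing_types) == 0
  structure(
    list(
      n_total = length(molecules),
      n_covered = sum(covered),
      percent_covered = 100 * sum(covered) / length(molecules),
      covered_ids = nms[covered],
      uncovered_ids = nms[!covered],
      missing_types = missing_types[!covered]
    ),
    class = "eem_coverage"
  )
}

#' @export
print.eem_coverage <- function(x, ...) {
  cat(sprintf("<eem_coverage> %d / %d molecules covered (%.2f%%)\n",
              x$n_covered, x$n_total, x$percent_covered))
  if (length(x$uncovered_ids) > 0) {
    for (nm in x$uncovered_ids) {
      cat(sprintf("  uncovered: %s (missing %s)\n", nm,
                  paste(x$missing_types[[nm]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' @describeIn eem_coverage `tidy()` returns one row per molecule with its
#'   coverage status and missing types.
#' @param x an `eem_coverage` object.
#' @param ... unused.
#' @export
tidy.eem_coverage <- function(x, ...) {
  nms <- c(x$covered_ids, x$uncovered_ids)
  tibble(
    molecule = nms,
    covered = c(rep(TRUE, length(x$covered_ids)),
                rep(FALSE, length(x$uncovered_ids))),
    missing_types = c(rep(list(character(0)), length(x$covered_ids)),
                      unname(x$missing_types))
  )
}

#' @describeIn eem_coverage `glance()` returns the one-row count summary.
#' @export
glance.eem_coverage <- function(x, ...) {
  tibble(n_total = x$n_total, n_covered = x$n_covered,
         percent_covered = x$percent_covered)
}

# Lean metric evaluation used by the parameterization objectives: pooled
# Pearson R plus per-type RMSD aggregates, on pooled charge vectors.
metric_eval <- function(ref, eem, type_codes) {
  d <- eem - ref
  rmsd_a <- sqrt(tapply(d^2, type_codes, mean))
  R <- safe_cor(ref, eem, "pearson")
  list(R = R, R2 = R^2,
       avg_rmsd_a = mean(rmsd_a), max_rmsd_a = max(rmsd_a),
       rmsd = sqrt(mean(d^2)))
}
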
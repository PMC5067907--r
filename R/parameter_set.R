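#' Construct an EEM parameter set
#'
#' An EEM parameter set holds the global distance-coupling scale `kappa`
#' plus per-atom-type electronegativity-like offsets `A` and hardness-like
#' self-terms `B`. Atom types are element symbol plus maximal bond order
#' (e.g. `"C2"`). Because EEM charges are invariant under a uniform shift
#' of all `A` and under joint positive scaling of `(A, B, kappa)`, two
#' numerically different sets can be charge-equivalent (gauge freedom).
#'
#' @param kappa global coupling parameter, > 0.
#' @param entries a data frame with columns `atom_type` (or `element` +
#'   `order`), `A` and `B`.
#' @param name set identifier.
#' @param qm_label label of the reference QM method this set mimics, e.g.
#'   `"B3LYP/6-311G/NPA"`.
#' @param strict error (`TRUE`, default) or warn (`FALSE`) when some
#'   `B <= 0`; fitted sets may carry non-physical `B` and are let through
#'   with a warning.
#' @return An object of class `eem_parameter_set`.
#' @export
parameter_set <- function(kappa, entries, name = "unnamed",
                          qm_label = "unknown", strict = TRUE) {
  if (!is.numeric(kappa) || length(kappa) != 1 || !is.finite(kappa) ||
      kappa <= 0) {
    stop_format("parameter set '%s': kappa must be a single positive number",
                name)
  }
  entries <- as_tibble(entries)
  if (!"atom_type" %in% names(entries)) {
    if (!all(c("element", "order") %in% names(entries))) {
      stop_format("parameter set '%s': entries need `atom_type` or `element` + `order`",
                  name)
    }
    entries$atom_type <- paste0(entries$element, entries$order)
  }
  if (!"element" %in% names(entries)) {
    entries$element <- sub("[0-9]+$", "", entries$atom_type)
    entries$order <- as.integer(sub("^[A-Za-z]+", "", entries$atom_type))
  }
  if (anyDuplicated(entries$atom_type)) {
    stop_format("parameter set '%s': duplicate atom type(s): %s", name,
                paste(unique(entries$atom_type[duplicated(entries$atom_type)]),
                      collapse = ", "))
  }
  if (any(!is.finite(entries$A)) || any(!is.finite(entries$B))) {
    stop_format("parameter set '%s': non-finite A or B", name)
  }
  if (any(entries$B <= 0)) {
    bad <- entries$atom_type[entries$B <= 0]
    msg <- sprintf("parameter set '%s': non-positive B for type(s) %s",
                   name, paste(bad, collapse = ", "))
    if (strict) stop_format("%s", msg) else warn(msg)
  }
  entries <- dplyr::arrange(
    entries[, c("atom_type", "element", "order", "A", "B")],
    .data$atom_type)
  structure(
    list(name = as.character(name), qm_label = as.character(qm_label),
         kappa = kappa, entries = entries),
    class = "eem_parameter_set"
  )
}

#' @export
print.eem_parameter_set <- function(x, ...) {
  cat(sprintf("<eem_parameter_set> %s (ref: %s)\n  kappa = %g, %d atom type(s): %s\n",
              x$name, x$qm_label, x$kappa, nrow(x$entries),
              paste(x$entries$atom_type, collapse = " ")))
  invisible(x)
}

#' @describeIn parameter_set `tidy()` returns the per-type entries as a
#'   tibble with the set-level `kappa` attached to every row.
#' @param x an `eem_parameter_set`.
#' @param ... unused.
#' @export
tidy.eem_parameter_set <- function(x, ...) {
  dplyr::mutate(x$entries, kappa = x$kappa)
}

#' @describeIn parameter_set `glance()` returns a one-row summary.
#' @export
glance.eem_parameter_set <- function(x, ...) {
  tibble(name = x$name, qm_label = x$qm_label, kappa = x$kappa,
         n_types = nrow(x$entries))
}

param_lookup <- function(set, atom_types) {
  idx <- match(atom_types, set$entries$atom_type)
  if (anyNA(idx)) {
    missing <- sort(unique(atom_types[is.na(idx)]))
    stop_usage("atom type(s) %s absent from parameter set '%s'",
               paste(missing, collapse = ", "), set$name)
  }
  list(A = set$entries$A[idx], B = set$entries$B[idx])
}

#' Read / write EEM parameter sets (JSON)
#'
#' The on-disk dialect is JSON:
#' `{"name": str, "qm_label": str, "kappa": number,
#'   "parameters": [{"element": str, "order": int, "A": number,
#'   "B": number}, ...]}`.
#' Values are serialized at 17 significant digits, so a write-then-read
#' round trip reproduces `kappa` and every `(A, B)` exactly. Missing
#' `kappa`, duplicate atom types and `B <= 0` are format errors.
#'
#' @param path file path (or a JSON string via `text` for reading).
#' @param text optional JSON string (overrides `path`).
#' @return `read_parameter_set()`: an [parameter_set()];
#'   `write_parameter_set()`: invisibly, the JSON string.
#' @export
read_parameter_set <- function(path = NULL, text = NULL) {
  doc <- tryCatch(
    jsonlite::fromJSON(if (!is.null(text)) text else path,
                       simplifyDataFrame = TRUE),
    error = function(e) stop_format("parameter file: invalid JSON (%s)",
                                    conditionMessage(e)))
  if (is.null(doc$kappa)) stop_format("parameter file: missing kappa")
  if (is.null(doc$parameters) || NROW(doc$parameters) == 0) {
    stop_format("parameter file: missing or empty parameters array")
  }
  entries <- as_tibble(doc$parameters)
  tryCatch(
    parameter_set(kappa = doc$kappa, entries = entries,
                  name = doc$name %||% "unnamed",
                  qm_label = doc$qm_label %||% "unknown"),
    eem_format_error = function(e) stop_format("parameter file: %s",
                                               conditionMessage(e)))
}

#' @param set an [parameter_set()] to write.
#' @rdname read_parameter_set
#' @export
write_parameter_set <- function(set, path = NULL) {
  if (!inherits(set, "eem_parameter_set")) {
    stop_usage("`set` must be an eem_parameter_set")
  }
  doc <- list(
    name = set$name, qm_label = set$qm_label, kappa = set$kappa,
    parameters = set$entries[, c("element", "order", "A", "B")]
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}
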
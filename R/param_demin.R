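# DE-MIN parameterization: differential evolution over flat candidate
# vectors (kappa, A_1..A_T, B_1..B_T) — types in sorted order — with
# derivative-free local minimization of promising candidates and a final
# polish of the incumbent best. The evolution operator is classic
# DE/rand/1/bin (base vector plus F times the difference of two others,
# binomial crossover at rate CR); out-of-bounds trial components are
# reflected back into the box. One master seed drives a single
# deterministic RNG stream, so identical inputs give bit-identical output.

#' Differential-evolution configuration
#'
#' @param metric `"rmsd"` (minimize the average per-atom-type RMSD) or
#'   `"r2"` (maximize the pooled squared Pearson correlation).
#' @param seed master seed for the single RNG stream.
#' @param population_size number of vectors; default
#'   `max(50, 10 * (2T + 1))` for `T` atom types, resolved at run time.
#' @param generations maximum number of evolution iterations.
#' @param early_stop stop after this many consecutive generations without
#'   a material improvement of the incumbent best.
#' @param F differential weight.
#' @param CR crossover rate in `[0, 1]`.
#' @param promising_r2 a vector is "promising" — and gets local
#'   minimization — when its pooled `R^2` exceeds this and `R > 0`; the
#'   screen is applied both at initialization and to every trial, and
#'   always uses the `R^2`/`R` criterion regardless of `metric`.
#' @param local_budget objective evaluations allowed per local
#'   minimization run.
#' @param polish_budget objective evaluations for the final polish of the
#'   best vector.
#' @param kappa_bounds,A_bounds,B_bounds component box constraints
#'   (`kappa > 0`, `B > 0` enforced).
#' @return A list of class `eem_de_config`.
#' @export
de_config <- function(metric = c("rmsd", "r2"), seed = 1L,
                      population_size = NULL, generations = 500L,
                      early_stop = 50L, F = 0.8, CR = 0.9,
                      promising_r2 = 0.2, local_budget = 200L,
                      polish_budget = 1000L,
                      kappa_bounds = c(0.05, 3),
                      A_bounds = c(0, 6), B_bounds = c(0.1, 10)) {
  metric <- match.arg(metric)
  if (!is.null(population_size) && population_size < 4) {
    stop_usage("population_size must be >= 4")
  }
  if (CR < 0 || CR > 1) stop_usage("CR must be in [0, 1]")
  if (kappa_bounds[1] <= 0) stop_usage("kappa lower bound must be > 0")
  if (B_bounds[1] <= 0) stop_usage("B lower bound must be > 0")
  structure(list(metric = metric, seed = as.integer(seed),
                 population_size = population_size,
                 generations = as.integer(generations),
                 early_stop = as.integer(early_stop), F = F, CR = CR,
                 promising_r2 = promising_r2,
                 local_budget = as.integer(local_budget),
                 polish_budget = as.integer(polish_budget),
                 kappa_bounds = kappa_bounds, A_bounds = A_bounds,
                 B_bounds = B_bounds),
            class = "eem_de_config")
}

decode_vector <- function(v, types) {
  Tn <- length(types)
  list(kappa = v[1], A = v[1 + seq_len(Tn)], B = v[1 + Tn + seq_len(Tn)])
}

# raw evaluation: c(ok, R, R2, rmsd, avg_rmsd_a, max_rmsd_a)
eval_vector_raw <- function(v, sd, type_codes) {
  Tn <- length(sd$types)
  p <- decode_vector(v, sd$types)
  if (p$kappa <= 0 || any(p$B <= 0)) {
    return(c(0, NA, NA, NA, NA, NA))
  }
  .eem_fitness_cpp(sd$mols, p$A, p$B, p$kappa, 1e-12, sd$ref_pooled,
                   type_codes, Tn)
}

# internal minimized fitness from a raw evaluation
raw_to_fitness <- function(raw, metric) {
  if (raw[1] == 0) return(Inf)
  val <- if (metric == "r2") {
    if (is.na(raw[3])) NA_real_ else -raw[3]
  } else {
    raw[5]
  }
  if (is.na(val) || !is.finite(val)) Inf else val
}

#' Fitness of a DE candidate vector
#'
#' Decodes a flat `(kappa, A_1..A_T, B_1..B_T)` vector (atom types in
#' sorted order), computes EEM charges for the whole training set and
#' compares them with the reference charges. Returns pooled `R^2` for
#' `metric = "r2"` (higher is better) or `avg(RMSD_a)` for
#' `metric = "rmsd"` (lower is better). Any failed per-molecule solve —
#' or a vector with non-positive `kappa` or `B` — maps to the worst
#' fitness sentinel (`-Inf` resp. `Inf`) rather than an error.
#'
#' @param vector numeric vector of length `2T + 1`.
#' @param molecules list of typed molecules.
#' @param ref_charges reference [charge_set()].
#' @param metric `"rmsd"` or `"r2"`.
#' @return A single number.
#' @export
demin_fitness <- function(vector, molecules, ref_charges,
                          metric = c("rmsd", "r2")) {
  metric <- match.arg(metric)
  sd <- solver_data(molecules, ref_charges)
  if (length(vector) != 2 * length(sd$types) + 1) {
    stop_usage("vector length %d does not match 2T + 1 = %d",
               length(vector), 2 * length(sd$types) + 1)
  }
  type_codes <- match(sd$type_pooled, sd$types) - 1L
  raw <- eval_vector_raw(vector, sd, type_codes)
  fit <- raw_to_fitness(raw, metric)
  if (metric == "r2") -fit else fit
}

#' Budgeted derivative-free local minimization
#'
#' Minimizes `objective` from `start` with a derivative-free simplex
#' search, spending at most `budget` objective evaluations. Points
#' outside `[lower, upper]` are clipped before evaluation, and the best
#' point actually evaluated is returned — so the result's objective never
#' exceeds the start's, and `budget = 0` returns the start unchanged.
#'
#' @param objective function of a numeric vector returning a scalar to
#'   minimize (may return `Inf` as a failure sentinel).
#' @param start numeric start vector.
#' @param budget maximum number of objective evaluations.
#' @param lower,upper optional box constraints (recycled to
#'   `length(start)`).
#' @return A list: `par` (best vector found), `value` (its objective,
#'   `NA` when `budget = 0`), `evaluations`.
#' @export
local_minimize <- function(objective, start, budget, lower = NULL,
                           upper = NULL) {
  if (budget <= 0) {
    return(list(par = start, value = NA_real_, evaluations = 0L))
  }
  clip <- if (is.null(lower)) identity else {
    lo <- rep_len(lower, length(start))
    hi <- rep_len(upper, length(start))
    function(v) pmin(pmax(v, lo), hi)
  }
  state <- new.env(parent = emptyenv())
  state$count <- 0L
  state$best_value <- Inf
  state$best_par <- clip(start)

  wrapped <- function(v) {
    if (state$count >= budget) return(.Machine$double.xmax)
    v <- clip(v)
    val <- objective(v)
    state$count <- state$count + 1L
    if (is.finite(val) && val < state$best_value) {
      state$best_value <- val
      state$best_par <- v
    }
    if (is.finite(val)) val else .Machine$double.xmax
  }

  wrapped(start)
  if (state$count < budget) {
    try(optim(start, wrapped, method = "Nelder-Mead",
              control = list(maxit = 10L * budget)), silent = TRUE)
  }
  list(par = state$best_par,
       value = if (is.finite(state$best_value)) state$best_value else Inf,
       evaluations = state$count)
}

reflect_into_box <- function(v, lower, upper) {
  below <- v < lower
  v[below] <- 2 * lower[below] - v[below]
  above <- v > upper
  v[above] <- 2 * upper[above] - v[above]
  pmin(pmax(v, lower), upper)  # clip anything still outside
}

#' DE-MIN parameterization
#'
#' Calibrates a full EEM parameter vector `(kappa, A_t, B_t)` by
#' differential evolution hybridized with local minimization. A random
#' population of vectors is drawn uniformly within the bounds and
#' evaluated; vectors passing the promising screen (`R^2 >
#' promising_r2` and `R > 0`) are refined by budgeted derivative-free
#' local minimization. Each generation builds trial vectors by
#' differential mutation and binomial crossover, evaluates them, locally
#' minimizes the promising ones, and replaces targets on improvement.
#' The incumbent best is finally polished with `polish_budget`
#' evaluations. The same seed gives bit-identical output; different
#' seeds give stochastically different parameter sets of similar
#' quality.
#'
#' @param molecules list of typed molecules (training set).
#' @param ref_charges reference [charge_set()].
#' @param config an [de_config()].
#' @param name,qm_label metadata for the returned parameter set.
#' @return An `eem_demin_fit` object: `set` (the winning
#'   [parameter_set()]), `quality` (its [eem_quality()] report),
#'   `convergence` (tibble: generation, best metric value, cumulative
#'   evaluations), `metric`, `seed`, `evaluations`.
#' @export
parameterize_demin <- function(molecules, ref_charges,
                               config = de_config(),
                               name = "demin_fit",
                               qm_label = "reference") {
  if (!inherits(config, "eem_de_config")) {
    stop_usage("`config` must come from de_config()")
  }
  check_molecule_list(molecules)
  sd <- solver_data(molecules, ref_charges)
  types <- sd$types
  Tn <- length(types)
  dim <- 2L * Tn + 1L
  type_codes <- match(sd$type_pooled, types) - 1L
  metric <- config$metric

  lower <- c(config$kappa_bounds[1], rep(config$A_bounds[1], Tn),
             rep(config$B_bounds[1], Tn))
  upper <- c(config$kappa_bounds[2], rep(config$A_bounds[2], Tn),
             rep(config$B_bounds[2], Tn))

  NP <- config$population_size %||% max(50L, 10L * dim)

  # prebuilt C++ evaluation context: per-molecule inputs converted once
  ctx <- .eem_ctx_cpp(sd$mols, sd$ref_pooled, type_codes, Tn)
  a_idx <- 1L + seq_len(Tn)
  b_idx <- 1L + Tn + seq_len(Tn)
  raw_ctx <- function(v) {
    if (v[1] <= 0 || any(v[b_idx] <= 0)) {
      return(c(0, NA, NA, NA, NA, NA))
    }
    .eem_fitness_ctx_cpp(ctx, v[a_idx], v[b_idx], v[1], 0)
  }
  objective <- function(v) {
    raw_to_fitness(raw_ctx(v), metric)
  }
  n_evals <- 0L
  eval_raw <- function(v) {
    n_evals <<- n_evals + 1L
    raw_ctx(v)
  }
  counted_objective <- function(v) {
    n_evals <<- n_evals + 1L
    objective(v)
  }
  promising <- function(raw) {
    raw[1] == 1 && !is.na(raw[3]) && raw[3] > config$promising_r2 &&
      raw[2] > 0
  }

  # single deterministic RNG stream under the master seed
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  # --- initialization ------------------------------------------------------
  pop <- matrix(runif(dim * NP, rep(lower, NP), rep(upper, NP)), nrow = dim)
  fitness <- numeric(NP)
  for (i in seq_len(NP)) {
    raw <- eval_raw(pop[, i])
    fitness[i] <- raw_to_fitness(raw, metric)
    if (promising(raw)) {
      loc <- local_minimize(counted_objective, pop[, i],
                            config$local_budget, lower, upper)
      if (is.finite(loc$value) && loc$value < fitness[i]) {
        pop[, i] <- loc$par
        fitness[i] <- loc$value
      }
    }
  }
  if (all(!is.finite(fitness))) {
    stop_numeric(paste0(
      "DE-MIN initialization failed: every vector of the initial ",
      "population evaluated to the worst-fitness sentinel (population ",
      "size %d, %d atom types); check bounds and training data"), NP, Tn)
  }

  best_idx <- which.min(fitness)
  best_par <- pop[, best_idx]
  best_fit <- fitness[best_idx]

  improve_tol <- function(f) max(1e-12, 1e-9 * abs(f))
  stall <- 0L
  conv <- vector("list", config$generations)

  # --- evolution loop ------------------------------------------------------
  n_gens <- 0L
  for (gen in seq_len(config$generations)) {
    n_gens <- gen
    gen_best_before <- best_fit
    for (i in seq_len(NP)) {
      r <- sample(setdiff(seq_len(NP), i), 3L)
      mutant <- pop[, r[1]] + config$F * (pop[, r[2]] - pop[, r[3]])
      mutant <- reflect_into_box(mutant, lower, upper)
      jrand <- sample.int(dim, 1L)
      mask <- runif(dim) < config$CR
      mask[jrand] <- TRUE
      trial <- pop[, i]
      trial[mask] <- mutant[mask]

      raw <- eval_raw(trial)
      trial_fit <- raw_to_fitness(raw, metric)
      if (promising(raw)) {
        loc <- local_minimize(counted_objective, trial,
                              config$local_budget, lower, upper)
        if (is.finite(loc$value) && loc$value < trial_fit) {
          trial <- loc$par
          trial_fit <- loc$value
        }
      }
      if (trial_fit < fitness[i]) {
        pop[, i] <- trial
        fitness[i] <- trial_fit
        if (trial_fit < best_fit) {
          best_fit <- trial_fit
          best_par <- trial
        }
      }
    }
    conv[[gen]] <- tibble(
      generation = gen,
      best = if (metric == "r2") -best_fit else best_fit,
      evaluations = n_evals
    )
    if (gen_best_before - best_fit > improve_tol(best_fit)) {
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stop) break
    }
  }

  # --- final polish --------------------------------------------------------
  loc <- local_minimize(counted_objective, best_par, config$polish_budget,
                        lower, upper)
  if (is.finite(loc$value) && loc$value < best_fit) {
    best_par <- loc$par
    best_fit <- loc$value
  }

  p <- decode_vector(best_par, types)
  set <- parameter_set(kappa = p$kappa,
                       entries = tibble(atom_type = types, A = p$A,
                                        B = p$B),
                       name = name, qm_label = qm_label, strict = FALSE)
  eem <- suppressMessages(calculate_charges(molecules, set))
  quality <- eem_quality(molecules, ref_charges, eem, set = set)

  structure(
    list(set = set, quality = quality,
         convergence = dplyr::bind_rows(conv[seq_len(n_gens)]),
         metric = metric, seed = config$seed, evaluations = n_evals,
         generations_run = n_gens),
    class = "eem_demin_fit"
  )
}

#' @export
print.eem_demin_fit <- function(x, ...) {
  cat(sprintf("<eem_demin_fit> metric = %s, seed = %d, %d generation(s), %d evaluation(s)\n",
              x$metric, x$seed, x$generations_run, x$evaluations))
  cat(sprintf("  kappa = %.6g  R2 = %.6g  avg(RMSD_a) = %.6g e\n",
              x$set$kappa, x$quality$summary$R2, x$quality$avg_rmsd_a))
  invisible(x)
}

#' @describeIn parameterize_demin `tidy()` returns the per-generation
#'   convergence log.
#' @param x an `eem_demin_fit`.
#' @param ... unused.
#' @export
tidy.eem_demin_fit <- function(x, ...) x$convergence

#' @describeIn parameterize_demin `glance()` returns a one-row summary.
#' @export
glance.eem_demin_fit <- function(x, ...) {
  tibble(kappa = x$set$kappa, metric = x$metric, seed = x$seed,
         R2 = x$quality$summary$R2, avg_rmsd_a = x$quality$avg_rmsd_a,
         max_rmsd_a = x$quality$max_rmsd_a,
         generations = x$generations_run, evaluations = x$evaluations)
}

#' @describeIn parameterize_demin `autoplot()` draws the convergence of
#'   the incumbent-best metric over generations.
#' @param object an `eem_demin_fit`.
#' @export
autoplot.eem_demin_fit <- function(object, ...) {
  ggplot2::ggplot(object$convergence,
                  ggplot2::aes(x = .data$generation, y = .data$best)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation",
                  y = if (object$metric == "r2") "best R2"
                      else "best avg(RMSD_a) (e)")
}
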
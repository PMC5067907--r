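# Synthetic fixtures: molecules with valid geometry and bonds, plus
# self-consistent reference charges generated from a known ground-truth
# parameter set. They stand in for quantum-mechanical training data, so
# parameterization and validation are testable without external inputs.
# Geometry is physically plausible (1.0-2.0 Angstrom placement distances,
# 0.9 Angstrom hard-sphere rejection) but not chemically optimized: EEM
# consumes only interatomic distances, so bonded realism matters only for
# atom typing. Do not mistake fixtures for conformers.

#' Fixture configuration
#'
#' @param n_molecules number of molecules to generate.
#' @param atoms_min,atoms_max per-molecule atom-count range.
#' @param palette named list: element symbol -> allowed maximal bond
#'   orders (downward-closed, e.g. `list(H = 1, C = c(1, 2))`). The
#'   default 8-type palette (H1, C1, C2, N1, N2, O1, O2, S1) mirrors a
#'   small-organic-molecule training set; [small_palette()] gives a
#'   4-type variant.
#' @param ground_truth optional [parameter_set()] used to generate
#'   reference charges; defaults to [fixture_ground_truth()] on the
#'   palette's types.
#' @param noise_sigma standard deviation (elementary charge units) of
#'   i.i.d. Gaussian noise added to the reference charges.
#' @param charged_fraction fraction of molecules given a formal charge of
#'   plus or minus 1 on one atom.
#' @param seed master seed for generation.
#' @return A list of class `eem_fixture_config`.
#' @export
fixture_config <- function(n_molecules = 30L, atoms_min = 4L,
                           atoms_max = 12L, palette = default_palette(),
                           ground_truth = NULL, noise_sigma = 0,
                           charged_fraction = 0.2, seed = 1L) {
  if (atoms_min < 1 || atoms_max < atoms_min) {
    stop_usage("need 1 <= atoms_min <= atoms_max")
  }
  if (noise_sigma < 0) stop_usage("noise_sigma must be >= 0")
  if (charged_fraction < 0 || charged_fraction > 1) {
    stop_usage("charged_fraction must be in [0, 1]")
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 atoms_min = as.integer(atoms_min),
                 atoms_max = as.integer(atoms_max), palette = palette,
                 ground_truth = ground_truth, noise_sigma = noise_sigma,
                 charged_fraction = charged_fraction,
                 seed = as.integer(seed)),
            class = "eem_fixture_config")
}

#' @rdname fixture_config
#' @export
default_palette <- function() {
  list(H = 1L, C = c(1L, 2L), N = c(1L, 2L), O = c(1L, 2L), S = 1L)
}

#' @rdname fixture_config
#' @export
small_palette <- function() {
  list(H = 1L, C = c(1L, 2L), O = 1L)
}

palette_types <- function(palette) {
  sort(unlist(lapply(names(palette), function(el) {
    paste0(el, palette[[el]])
  }), use.names = FALSE))
}

#' Ground-truth parameter set for fixtures
#'
#' Draws a random but reproducible parameter set over the given atom
#' types, with magnitudes in published ranges (`kappa` around 0.4, `A` in
#' `[2, 3]`, `B` in `[2, 8]`, arbitrary consistent units). The values
#' carry no physical meaning; recovery tests compare charges, never
#' parameter values, because of the gauge freedoms. With
#' `gauge = TRUE` (default) the whole set is rescaled so that the
#' reference type's `B` equals 1 — the same scale gauge the LR fit pins —
#' making noiseless LR recovery exact at the ground-truth `kappa`.
#'
#' @param types character vector of atom types (or a palette via
#'   [fixture_config()]'s `palette` argument upstream).
#' @param seed seed for the draw.
#' @param gauge rescale to the reference-type gauge (`B[t0] = 1`).
#' @param reference_type gauge type; default `"H1"` if present, else the
#'   first type.
#' @return An [parameter_set()].
#' @export
fixture_ground_truth <- function(types, seed = 1L, gauge = TRUE,
                                 reference_type = NULL) {
  types <- sort(types)
  with_seed(seed, {
    A <- runif(length(types), 2, 3)
    B <- runif(length(types), 2, 8)
    kappa <- 0.4
    if (gauge) {
      t0 <- reference_type %||% (if ("H1" %in% types) "H1" else types[1])
      s <- B[match(t0, types)]
      A <- A / s
      B <- B / s
      kappa <- kappa / s
    }
    parameter_set(kappa = kappa,
                  entries = tibble(atom_type = types, A = A, B = B),
                  name = "fixture_ground_truth", qm_label = "synthetic")
  })
}

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate one random fixture molecule
#'
#' Atoms are placed sequentially at 1.0-2.0 Angstrom from a randomly
#' chosen previously placed atom, rejecting any configuration with a pair
#' closer than 0.9 Angstrom (bounded retries, then a fresh regeneration).
#' Bonds form a spanning tree (each atom bonds to its anchor) plus
#' occasional extra edges; bond orders are drawn from the palette's
#' allowed orders for both endpoints, so every atom type stays inside the
#' palette vocabulary. Draws come from the current RNG stream.
#'
#' @param name molecule name.
#' @param atoms_min,atoms_max atom-count range.
#' @param palette see [fixture_config()].
#' @param charged give the molecule a formal charge of plus or minus 1.
#' @return A typed [eem_molecule()] with a connected bond graph and
#'   minimum pairwise distance >= 0.9 Angstrom.
#' @export
random_molecule <- function(name = "mol", atoms_min = 4L, atoms_max = 12L,
                            palette = default_palette(),
                            charged = FALSE) {
  for (attempt in seq_len(20L)) {
    mol <- try(random_molecule_once(name, atoms_min, atoms_max, palette,
                                    charged), silent = TRUE)
    if (!inherits(mol, "try-error")) return(mol)
  }
  stop_numeric("fixture generation: atom placement failed repeatedly for '%s'",
               name)
}

random_molecule_once <- function(name, atoms_min, atoms_max, palette,
                                 charged) {
  n <- if (atoms_max > atoms_min) {
    sample(seq.int(atoms_min, atoms_max), 1L)
  } else {
    atoms_min
  }
  elements <- sample(names(palette), n, replace = TRUE)

  xyz <- matrix(0, n, 3)
  anchor <- integer(n)
  for (k in seq_len(n)[-1]) {
    placed <- FALSE
    for (try_k in seq_len(30L)) {
      a <- sample.int(k - 1L, 1L)
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      pos <- xyz[a, ] + runif(1, 1, 2) * u
      d2 <- rowSums(sweep(xyz[seq_len(k - 1L), , drop = FALSE], 2, pos)^2)
      if (all(d2 >= 0.9^2)) {
        xyz[k, ] <- pos
        anchor[k] <- a
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("placement failed")
  }

  bond_order <- function(e1, e2) {
    allowed <- intersect(palette[[e1]], palette[[e2]])
    # favour single bonds so low-order types stay represented
    probs <- c(0.7, 0.25, 0.05)[seq_along(allowed)]
    allowed[sample.int(length(allowed), 1L, prob = probs)]
  }
  bonds <- if (n > 1) {
    tibble(
      i = 2:n, j = anchor[-1],
      order = vapply(2:n, function(k) {
        bond_order(elements[k], elements[anchor[k]])
      }, integer(1))
    )
  } else {
    NULL
  }
  # occasional ring-closing extra bond
  if (n >= 4 && runif(1) < 0.3) {
    pair <- sample.int(n, 2L)
    already <- any(bonds$i == pair[1] & bonds$j == pair[2]) ||
      any(bonds$i == pair[2] & bonds$j == pair[1])
    if (!already) {
      bonds <- dplyr::bind_rows(bonds, tibble(
        i = pair[1], j = pair[2],
        order = bond_order(elements[pair[1]], elements[pair[2]])))
    }
  }

  formal <- integer(n)
  if (charged) formal[sample.int(n, 1L)] <- sample(c(-1L, 1L), 1L)

  mol <- eem_molecule(name, tibble(element = elements, x = xyz[, 1],
                                   y = xyz[, 2], z = xyz[, 3],
                                   formal_charge = formal), bonds)
  assign_atom_types(mol)
}

#' Generate a fixture molecule collection
#'
#' Draws `n_molecules` random molecules under the configuration's seed,
#' then enforces LR identifiability: every palette atom type must occur
#' on at least two atoms across the set (molecules are redrawn, up to a
#' bound, until this holds).
#'
#' @param config an [fixture_config()].
#' @return A named list of typed [eem_molecule()] objects.
#' @export
fixture_molecules <- function(config) {
  if (!inherits(config, "eem_fixture_config")) {
    stop_usage("`config` must come from fixture_config()")
  }
  types_needed <- palette_types(config$palette)
  with_seed(config$seed, {
    mols <- lapply(seq_len(config$n_molecules), function(k) {
      random_molecule(sprintf("FIX_%03d", k), config$atoms_min,
                      config$atoms_max, config$palette,
                      charged = runif(1) < config$charged_fraction)
    })
    names(mols) <- molecule_names(mols)
    type_counts <- function(ms) {
      table(factor(unlist(lapply(ms, function(m) m$atoms$atom_type)),
                   levels = types_needed))
    }
    redraw <- 0L
    while (any(type_counts(mols) < 2) && redraw < 200L) {
      k <- sample.int(length(mols), 1L)
      mols[[k]] <- random_molecule(sprintf("FIX_%03d", k),
                                   config$atoms_min, config$atoms_max,
                                   config$palette,
                                   charged = runif(1) < config$charged_fraction)
      redraw <- redraw + 1L
    }
    if (any(type_counts(mols) < 2)) {
      stop_numeric("fixture generation: could not represent every palette type at least twice")
    }
    mols
  })
}

#' Self-consistent reference charges for fixture molecules
#'
#' Solves the EEM system under the ground-truth parameter set, optionally
#' perturbs each atom's charge with i.i.d. Gaussian noise of standard
#' deviation `noise_sigma`, and re-centers each molecule's vector so the
#' total charge `Q` is preserved exactly.
#'
#' @param molecules list of typed molecules.
#' @param ground_truth the generating [parameter_set()]; must cover all
#'   atom types present.
#' @param noise_sigma Gaussian noise level in elementary charge units.
#' @param seed optional seed for the noise draw (`NULL` uses the current
#'   RNG stream).
#' @return An [charge_set()] aligned with `molecules`.
#' @export
make_reference_charges <- function(molecules, ground_truth,
                                   noise_sigma = 0, seed = NULL) {
  check_molecule_list(molecules)
  clean <- calculate_charges(molecules, ground_truth)
  if (noise_sigma == 0) return(clean)
  add_noise <- function() {
    noisy <- purrr::imap(unclass(clean), function(q, nm) {
      qn <- q + rnorm(length(q), 0, noise_sigma)
      qn + (sum(q) - sum(qn)) / length(qn)  # restore sum(q) = Q exactly
    })
    charge_set(noisy)
  }
  if (is.null(seed)) add_noise() else with_seed(seed, add_noise())
}

#' One-call fixture dataset
#'
#' Convenience wrapper: generates molecules, a ground-truth parameter set
#' (when the configuration does not supply one) and the matching
#' reference charges.
#'
#' @param config an [fixture_config()].
#' @return A list: `molecules`, `ref_charges`, `ground_truth`, `config`.
#' @export
fixture_dataset <- function(config = fixture_config()) {
  molecules <- fixture_molecules(config)
  truth <- config$ground_truth %||%
    fixture_ground_truth(palette_types(config$palette), seed = config$seed)
  ref <- make_reference_charges(molecules, truth,
                                noise_sigma = config$noise_sigma,
                                seed = config$seed + 1L)
  list(molecules = molecules, ref_charges = ref, ground_truth = truth,
       config = config)
}
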
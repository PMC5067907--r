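# Independent oracles and shared fixtures. Everything here is deliberately
# naive: plain-R reimplementations from definitions, used only to check the
# production paths.

# Dense EEM solve built from scratch (own distance computation, own matrix
# assembly, base-R solve); independent of the package's solver.
oracle_eem_solve <- function(molecule, set) {
  a <- molecule$atoms
  n <- nrow(a)
  idx <- match(a$atom_type, set$entries$atom_type)
  A <- set$entries$A[idx]
  B <- set$entries$B[idx]
  M <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        M[i, i] <- B[i]
      } else {
        r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                    (a$z[i] - a$z[j])^2)
        M[i, j] <- set$kappa / r
      }
    }
    M[i, n + 1] <- -1
    M[n + 1, i] <- 1
  }
  rhs <- c(-A, molecule$total_charge)
  sol <- solve(M, rhs)
  list(charges = sol[seq_len(n)], chi_bar = sol[n + 1])
}

# definitional statistics
bf_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_avg_rank <- function(x) {
  # average ranks for ties, from the definition
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

bf_spearman <- function(x, y) bf_pearson(bf_avg_rank(x), bf_avg_rank(y))

bf_rmsd <- function(x, y) sqrt(sum((y - x)^2) / length(x))
bf_delta <- function(x, y) sum(abs(y - x)) / length(x)
bf_delta_max <- function(x, y) max(abs(y - x))

# hand-buildable molecules -------------------------------------------------

# diatomic at distance R along x, optionally typed
diatomic <- function(elements = c("H", "H"), R = 1, charges = c(0L, 0L),
                     name = "diatomic") {
  assign_atom_types(eem_molecule(
    name,
    tibble::tibble(element = elements, x = c(0, R), y = 0, z = 0,
                   formal_charge = charges),
    tibble::tibble(i = 1L, j = 2L, order = 1L)))
}

# memoized fixture datasets shared across test files ------------------------

local_fixture_cache <- new.env(parent = emptyenv())

clean_fixtures <- function() {
  if (is.null(local_fixture_cache$clean)) {
    local_fixture_cache$clean <- fixture_dataset(
      fixture_config(n_molecules = 30, palette = small_palette(),
                     seed = 42))
  }
  local_fixture_cache$clean
}

noisy_fixtures <- function() {
  if (is.null(local_fixture_cache$noisy)) {
    local_fixture_cache$noisy <- fixture_dataset(
      fixture_config(n_molecules = 40, palette = default_palette(),
                     noise_sigma = 0.05, seed = 99))
  }
  local_fixture_cache$noisy
}
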
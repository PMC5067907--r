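two_type_set <- function(A = c(0.4, 0.6), B = c(1, 1), kappa = 0.5) {
  parameter_set(kappa, tibble::tibble(atom_type = c("H1", "O1"),
                                      A = A, B = B), name = "toy")
}

test_that("distance matrices are Euclidean, symmetric and guarded", {
  m <- assign_atom_types(eem_molecule(
    "tri", tibble::tibble(element = c("C", "C", "C"),
                          x = c(0, 3, 0), y = c(0, 4, 0), z = c(0, 0, 2)),
    tibble::tibble(i = c(1L, 1L), j = c(2L, 3L), order = 1L)))
  R <- distance_matrix(m)
  expect_equal(R[1, 2], 5)
  expect_equal(diag(R), rep(0, 3))
  expect_equal(R, t(R))

  degenerate <- eem_molecule(
    "dup", tibble::tibble(element = c("C", "C"), x = 0, y = 0, z = 0),
    tibble::tibble(i = 1L, j = 2L, order = 1L))
  expect_error(distance_matrix(degenerate), "degenerate",
               class = "eem_numeric_error")
})

test_that("the bordered EEM system has the prescribed structure", {
  m <- diatomic(c("H", "O"), R = 1)
  sys <- build_eem_system(m, two_type_set())
  M <- sys$matrix
  expect_equal(dim(M), c(3, 3))
  expect_equal(M[1, 2], 0.5)           # kappa / R
  expect_equal(M[2, 1], 0.5)
  expect_equal(diag(M)[1:2], c(1, 1))  # B by type
  expect_equal(M[1:2, 3], c(-1, -1))
  expect_equal(M[3, ], c(1, 1, 0))     # constraint row
  expect_equal(sys$rhs, c(-0.4, -0.6, 0))

  uncovered <- diatomic(c("H", "N"), R = 1)
  expect_error(build_eem_system(uncovered, two_type_set()), "N1",
               class = "eem_usage_error")
})

test_that("closed-form solves are reproduced exactly", {
  # single atom: the constraint row forces q = Q, row 1 gives chi = A + B q
  single <- assign_atom_types(eem_molecule(
    "ion", tibble::tibble(element = "O", x = 0, y = 0, z = 0,
                          formal_charge = -1L)))
  s <- solve_charges(single, parameter_set(
    0.5, tibble::tibble(atom_type = "O1", A = 0.7, B = 1.3)))
  expect_equal(s$charges, -1, tolerance = 1e-12)
  expect_equal(s$chi_bar, 0.7 - 1.3, tolerance = 1e-12)

  # symmetric neutral diatomic: charges vanish
  sym <- solve_charges(diatomic(c("H", "H"), R = 1.2),
                       parameter_set(0.5, tibble::tibble(
                         atom_type = "H1", A = 0.4, B = 1)))
  expect_equal(sym$charges, c(0, 0), tolerance = 1e-12)

  # hand-solved 3x3: A = (0.4, 0.6), B = (1, 1), kappa = 0.5, R = 1, Q = 0
  s2 <- solve_charges(diatomic(c("H", "O"), R = 1), two_type_set())
  expect_equal(s2$charges, c(0.2, -0.2), tolerance = 1e-12)
  expect_equal(s2$chi_bar, 0.5, tolerance = 1e-12)
})

test_that("solutions conserve charge, equalize electronegativity and match an independent dense solve", {
  fx <- clean_fixtures()
  set <- fx$ground_truth
  for (m in fx$molecules) {
    s <- solve_charges(m, set)
    expect_lt(abs(sum(s$charges) - m$total_charge), 1e-8)

    par <- tidy(set)
    idx <- match(m$atoms$atom_type, par$atom_type)
    R <- distance_matrix(m)
    invR <- ifelse(R > 0, 1 / R, 0)
    resid <- par$A[idx] + par$B[idx] * s$charges +
      set$kappa * as.numeric(invR %*% s$charges) - s$chi_bar
    expect_lt(max(abs(resid)), 1e-8)

    oracle <- oracle_eem_solve(m, set)
    expect_lt(max(abs(s$charges - oracle$charges)), 1e-8)
    expect_lt(abs(s$chi_bar - oracle$chi_bar), 1e-8)
  }
})

test_that("charges are invariant under rigid motion and gauge transforms", {
  fx <- clean_fixtures()
  set <- fx$ground_truth
  rot <- function(theta) {
    matrix(c(cos(theta), -sin(theta), 0,
             sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  }
  for (m in fx$molecules[1:8]) {
    base <- solve_charges(m, set)

    moved <- m
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% rot(0.83)
    moved$atoms$x <- xyz[, 1] + 5.5
    moved$atoms$y <- xyz[, 2] - 2.1
    moved$atoms$z <- xyz[, 3] + 0.4
    expect_lt(max(abs(solve_charges(moved, set)$charges - base$charges)),
              1e-8)

    # A-shift gauge: charges fixed, chi shifted by exactly c
    shift <- 0.37
    shifted <- parameter_set(set$kappa,
                             dplyr::mutate(set$entries, A = A + shift))
    s_sh <- solve_charges(m, shifted)
    expect_lt(max(abs(s_sh$charges - base$charges)), 1e-8)
    expect_lt(abs(s_sh$chi_bar - (base$chi_bar + shift)), 1e-8)

    # scale gauge: charges fixed, chi scaled by exactly s
    sc <- 2.4
    scaled <- parameter_set(sc * set$kappa,
                            dplyr::mutate(set$entries, A = sc * A,
                                          B = sc * B))
    s_sc <- solve_charges(m, scaled)
    expect_lt(max(abs(s_sc$charges - base$charges)), 1e-8)
    expect_lt(abs(s_sc$chi_bar - sc * base$chi_bar), 1e-8)
  }
})

test_that("solve results are independent of atom ordering", {
  fx <- clean_fixtures()
  m <- fx$molecules[[3]]
  base <- solve_charges(m, fx$ground_truth)
  set.seed(5)
  p <- sample(nrow(m$atoms))
  inv <- integer(length(p)); inv[p] <- seq_along(p)
  pm <- assign_atom_types(eem_molecule(
    "perm", m$atoms[p, c("element", "x", "y", "z", "formal_charge")],
    tibble::tibble(i = inv[m$bonds$i], j = inv[m$bonds$j],
                   order = m$bonds$order)))
  s <- solve_charges(pm, fx$ground_truth)
  expect_lt(max(abs(s$charges - base$charges[p])), 1e-8)
})

test_that("batch calculation matches per-molecule solves and handles coverage", {
  fx <- clean_fixtures()
  set <- fx$ground_truth
  cs <- calculate_charges(fx$molecules, set)
  expect_equal(names(cs), names(fx$molecules))
  for (nm in names(cs)[1:5]) {
    expect_identical(cs[[nm]], solve_charges(fx$molecules[[nm]], set)$charges)
  }

  expect_length(calculate_charges(list(), set), 0)

  # threads is a pure speed option: identical results
  cs2 <- calculate_charges(fx$molecules, set, threads = 2L)
  expect_identical(unclass(cs2), unclass(cs))

  # drop one type from the set -> strict error, or skip with a message
  reduced <- parameter_set(set$kappa, set$entries[-1, ], strict = FALSE)
  dropped_type <- set$entries$atom_type[1]
  affected <- vapply(fx$molecules, function(m) {
    dropped_type %in% m$atoms$atom_type
  }, logical(1))
  expect_error(calculate_charges(fx$molecules, reduced),
               class = "eem_usage_error")
  expect_message(
    part <- calculate_charges(fx$molecules, reduced, skip_uncovered = TRUE),
    "skipping")
  expect_equal(names(part), names(fx$molecules)[!affected])
})
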
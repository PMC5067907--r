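c1_molecule <- function(name, n, element = "C") {
  # n collinear atoms, 1.5 A apart, single bonds
  assign_atom_types(eem_molecule(
    name,
    tibble::tibble(element = element, x = 1.5 * (seq_len(n) - 1),
                   y = 0, z = 0),
    if (n > 1) tibble::tibble(i = seq_len(n - 1), j = 2:n, order = 1L)))
}

as_cs <- function(...) charge_set(list(...))

test_that("quality of a charge set against itself is the exact fixed point", {
  fx <- clean_fixtures()
  mols <- fx$molecules[1:6]
  ref <- charge_set(unclass(fx$ref_charges)[names(mols)])
  q <- eem_quality(mols, ref, ref)
  expect_equal(q$summary$R, 1, tolerance = 1e-12)
  expect_equal(q$summary$spearman, 1, tolerance = 1e-12)
  expect_equal(q$summary$rmsd, 0)
  expect_equal(q$summary$delta, 0)
  expect_equal(q$summary$delta_max, 0)
  expect_equal(q$avg_rmsd_a, 0)
  expect_true(all(q$per_molecule$rmsd == 0))
})

test_that("error statistics follow their definitions", {
  m <- c1_molecule("m", 2)
  q <- eem_quality(list(m), as_cs(m = c(0, 0)), as_cs(m = c(0.1, -0.3)))
  expect_equal(q$summary$delta, 0.2)
  expect_equal(q$summary$delta_max, 0.3)
  expect_equal(q$summary$rmsd, sqrt(0.05))
  # constant reference: correlations are not available, never 0 or an error
  expect_true(is.na(q$summary$R))

  # perfect anticorrelation keeps the signed R
  m4 <- c1_molecule("m", 4)
  ref <- c(-0.3, -0.1, 0.1, 0.3)
  q2 <- eem_quality(list(m = m4), as_cs(m = ref), as_cs(m = -ref))
  expect_equal(q2$summary$R, -1, tolerance = 1e-12)
  expect_equal(q2$summary$R2, 1, tolerance = 1e-12)
})

test_that("avg(RMSD_a) weights atom types equally", {
  # one C1 and one N1 pair with per-type RMSD 0.1 and 0.3
  mc <- c1_molecule("mc", 2, "C")
  mn <- c1_molecule("mn", 2, "N")
  ref <- list(mc = c(0.2, -0.2), mn = c(0.4, -0.4))
  eem <- list(mc = c(0.3, -0.1), mn = c(0.7, -0.1))
  q <- eem_quality(list(mc = mc, mn = mn), charge_set(ref),
                   charge_set(eem))
  expect_equal(sort(q$per_type$rmsd), c(0.1, 0.3), tolerance = 1e-12)
  expect_equal(q$avg_rmsd_a, 0.2, tolerance = 1e-12)
  expect_equal(q$max_rmsd_a, 0.3, tolerance = 1e-12)
})

test_that("statistics agree with brute-force definitional implementations", {
  set.seed(17)
  n <- 60
  m <- c1_molecule("m", n)
  for (rep in 1:30) {
    ref <- round(rnorm(n), 2)  # rounding forces rank ties
    eem <- ref + round(rnorm(n, 0, 0.3), 2)
    q <- eem_quality(list(m = m), as_cs(m = ref), as_cs(m = eem))
    expect_equal(q$summary$R, bf_pearson(ref, eem), tolerance = 1e-12)
    expect_equal(q$summary$spearman, bf_spearman(ref, eem),
                 tolerance = 1e-12)
    expect_equal(q$summary$rmsd, bf_rmsd(ref, eem), tolerance = 1e-12)
    expect_equal(q$summary$delta, bf_delta(ref, eem), tolerance = 1e-12)
    expect_equal(q$summary$delta_max, bf_delta_max(ref, eem),
                 tolerance = 1e-12)
  }
})

test_that("pooled RMSD^2 is the atom-count-weighted mean of per-type RMSD_a^2", {
  fx <- noisy_fixtures()
  eem <- calculate_charges(fx$molecules, fx$ground_truth)
  q <- eem_quality(fx$molecules, fx$ref_charges, eem)
  pt <- q$per_type[q$per_type$n > 0, ]
  expect_equal(q$summary$rmsd^2,
               sum(pt$n * pt$rmsd^2) / sum(pt$n), tolerance = 1e-12)
})

test_that("single-atom types report errors but not correlations", {
  mc <- c1_molecule("mc", 3, "C")
  mh <- diatomic(c("H", "O"), name = "mh")
  mols <- list(mc = mc, mh = mh)
  q <- eem_quality(mols, charge_set(list(mc = c(0.1, 0, -0.1),
                                         mh = c(0.25, -0.25))),
                   charge_set(list(mc = c(0.2, 0, -0.2),
                                   mh = c(0.15, -0.15))))
  h_row <- q$per_type[q$per_type$atom_type == "H1", ]
  expect_equal(h_row$n, 1L)
  expect_true(is.na(h_row$R))
  expect_equal(h_row$rmsd, 0.1, tolerance = 1e-12)
  expect_equal(h_row$delta, 0.1, tolerance = 1e-12)
})

test_that("types in the set but absent from the data get zero-count rows", {
  m <- c1_molecule("m", 3)
  set <- parameter_set(0.4, tibble::tibble(atom_type = c("C1", "S1"),
                                           A = c(1, 2), B = c(2, 3)))
  q <- eem_quality(list(m = m), as_cs(m = c(0.1, 0, -0.1)),
                   as_cs(m = c(0.1, 0.05, -0.15)), set = set)
  s_row <- q$per_type[q$per_type$atom_type == "S1", ]
  expect_equal(s_row$n, 0L)
  expect_true(is.na(s_row$rmsd))
})

test_that("the scatter table feeds per-type statistics and plots", {
  fx <- clean_fixtures()
  mols <- fx$molecules[1:2]
  ref <- charge_set(unclass(fx$ref_charges)[names(mols)])
  eem <- calculate_charges(mols, fx$ground_truth)
  tab <- charge_scatter(mols, ref, eem)
  expect_equal(nrow(tab), sum(vapply(mols, function(m) nrow(m$atoms),
                                     integer(1))))
  q <- eem_quality(mols, ref, eem)
  for (tt in unique(tab$atom_type)) {
    sub <- tab[tab$atom_type == tt, ]
    if (nrow(sub) >= 2 && sd(sub$ref) > 0 && sd(sub$eem) > 0) {
      expect_equal(q$per_type$R[q$per_type$atom_type == tt],
                   cor(sub$ref, sub$eem), tolerance = 1e-12)
    }
  }
  expect_equal(nrow(charge_scatter(list(), charge_set(), charge_set())), 0)
  expect_s3_class(autoplot(q), "ggplot")
})

test_that("misaligned charge vectors are rejected", {
  m <- c1_molecule("m", 3)
  expect_error(eem_quality(list(m = m), as_cs(m = c(0.1, -0.1)),
                           as_cs(m = c(0.1, 0, -0.1))),
               class = "eem_format_error")
})

test_that("coverage reports counts, identities and missing types", {
  # three molecules, one containing a type absent from the set
  m1 <- c1_molecule("m1", 2, "C")
  m2 <- diatomic(c("H", "O"), name = "m2")
  m3 <- assign_atom_types(eem_molecule(
    "m3", tibble::tibble(element = c("C", "S"), x = c(0, 1.8), y = 0, z = 0),
    tibble::tibble(i = 1L, j = 2L, order = 1L)))
  mols <- list(m1 = m1, m2 = m2, m3 = m3)
  set <- parameter_set(0.4, tibble::tibble(
    atom_type = c("C1", "H1", "O1"), A = 1:3, B = c(2, 2, 2)))

  cov <- eem_coverage(mols, set)
  expect_equal(cov$n_total, 3)
  expect_equal(cov$n_covered, 2)
  expect_equal(cov$percent_covered, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(cov$uncovered_ids, "m3")
  expect_equal(cov$missing_types[["m3"]], "S1")
  expect_setequal(cov$covered_ids, c("m1", "m2"))

  # adding entries never decreases coverage
  grown <- parameter_set(0.4, dplyr::bind_rows(
    set$entries[, c("atom_type", "A", "B")],
    tibble::tibble(atom_type = "S1", A = 2, B = 3)))
  expect_gte(eem_coverage(mols, grown)$n_covered, cov$n_covered)
  expect_equal(eem_coverage(mols, grown)$percent_covered, 100)

  # a set with no matching entries covers nothing
  none <- parameter_set(0.4, tibble::tibble(atom_type = "P1", A = 1, B = 1))
  cov0 <- eem_coverage(mols, none)
  expect_equal(cov0$n_covered, 0)
  expect_equal(cov0$percent_covered, 0)
  expect_setequal(cov0$uncovered_ids, names(mols))

  expect_error(eem_coverage(list(), set), class = "eem_usage_error")
})
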
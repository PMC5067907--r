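test_that("the centered design absorbs per-molecule electronegativities", {
  fx <- clean_fixtures()
  mols <- fx$molecules[1:4]
  ref <- charge_set(unclass(fx$ref_charges)[names(mols)])
  d <- electronegativity_design(mols, ref, kappa = 0.4)
  types <- dataset_atom_types(mols)
  expect_equal(ncol(d$X), 2 * length(types))
  expect_equal(nrow(d$X), sum(vapply(mols, function(m) nrow(m$atoms),
                                     integer(1))))
  # centering: every column (and the target) sums to zero per molecule
  for (nm in unique(d$molecule)) {
    rows <- d$molecule == nm
    expect_lt(max(abs(colSums(d$X[rows, , drop = FALSE]))), 1e-10)
    expect_lt(abs(sum(d$y[rows])), 1e-10)
  }
  # kappa = 0 limit: no Coulomb term, targets vanish
  d0 <- electronegativity_design(mols, ref, kappa = 0)
  expect_equal(max(abs(d0$y)), 0)
})

test_that("a type occurring once is an identifiability error", {
  m <- assign_atom_types(eem_molecule(
    "lonely", tibble::tibble(element = c("C", "C", "S"),
                             x = c(0, 1.5, 3), y = 0, z = 0),
    tibble::tibble(i = c(1L, 2L), j = c(2L, 3L), order = 1L)))
  fx <- clean_fixtures()
  mols <- c(fx$molecules[1:3], list(lonely = m))
  ref <- make_reference_charges(
    mols, parameter_set(0.4, tibble::tibble(
      atom_type = c(dataset_atom_types(fx$molecules[1:3]), "S1"),
      A = 0.5, B = 1)))
  expect_error(fit_at_kappa(mols, ref, 0.4), "S1",
               class = "eem_numeric_error")
})

test_that("noiseless data is recovered exactly at the true kappa", {
  fx <- clean_fixtures()
  kap <- fx$ground_truth$kappa
  set <- fit_at_kappa(fx$molecules, fx$ref_charges, kap)
  eem <- calculate_charges(fx$molecules, set)
  q <- eem_quality(fx$molecules, fx$ref_charges, eem)
  expect_lt(q$max_rmsd_a, 1e-6)
  expect_lt(max(abs(unlist(unclass(eem)) -
                      unlist(unclass(fx$ref_charges)))), 1e-6)

  # off-optimum kappa is strictly worse
  off <- fit_at_kappa(fx$molecules, fx$ref_charges, 2 * kap)
  q_off <- eem_quality(fx$molecules, fx$ref_charges,
                       calculate_charges(fx$molecules, off))
  expect_gt(q_off$avg_rmsd_a, q$avg_rmsd_a)
  expect_gt(q_off$avg_rmsd_a, 1e-6)
})

test_that("duplicated training molecules do not change the fit", {
  m <- assign_atom_types(eem_molecule(
    "dup", tibble::tibble(element = c("H", "H", "O", "O"),
                          x = c(0, 1.1, 2.4, 3.2), y = c(0, 0.8, 0, 0.5),
                          z = 0),
    tibble::tibble(i = c(1L, 2L, 3L), j = c(2L, 3L, 4L), order = 1L)))
  truth <- parameter_set(0.3, tibble::tibble(atom_type = c("H1", "O1"),
                                             A = c(0.5, 0.9), B = c(1, 2)))
  ref1 <- make_reference_charges(list(dup = m), truth)
  single <- fit_at_kappa(list(dup = m), ref1, 0.3)

  copies <- list(dup = m, dup2 = m, dup3 = m)
  copies$dup2$name <- "dup2"; copies$dup3$name <- "dup3"
  refk <- charge_set(list(dup = ref1$dup, dup2 = ref1$dup,
                          dup3 = ref1$dup))
  multi <- fit_at_kappa(copies, refk, 0.3)
  expect_equal(multi$entries$A, single$entries$A, tolerance = 1e-9)
  expect_equal(multi$entries$B, single$entries$B, tolerance = 1e-9)
})

test_that("the kappa scan selects the generating kappa on clean data", {
  fx <- clean_fixtures()
  kap <- fx$ground_truth$kappa
  fit <- parameterize_lr(fx$molecules, fx$ref_charges,
                         kappa_min = kap / 2, kappa_max = 2 * kap,
                         kappa_step = kap / 2)
  expect_equal(fit$set$kappa, kap, tolerance = 1e-12)
  expect_gt(fit$quality$summary$R2, 1 - 1e-9)

  # both metrics agree at the exact fit
  fit_r2 <- parameterize_lr(fx$molecules, fx$ref_charges, metric = "r2",
                            kappa_min = kap / 2, kappa_max = 2 * kap,
                            kappa_step = kap / 2)
  expect_equal(fit_r2$set$kappa, fit$set$kappa)

  # the winner is at least as good as every other grid candidate
  ok <- fit$profile[fit$profile$ok, ]
  expect_true(all(min(ok$avg_rmsd_a) >= fit$quality$avg_rmsd_a - 1e-12))

  # LR is deterministic
  fit2 <- parameterize_lr(fx$molecules, fx$ref_charges,
                          kappa_min = kap / 2, kappa_max = 2 * kap,
                          kappa_step = kap / 2)
  expect_identical(fit2$set$entries, fit$set$entries)
  expect_identical(tidy(fit2), tidy(fit))
})

test_that("grid misconfiguration is a usage error", {
  fx <- clean_fixtures()
  expect_error(parameterize_lr(fx$molecules, fx$ref_charges,
                               kappa_min = 0.5, kappa_max = 0.1),
               class = "eem_usage_error")
  expect_error(parameterize_lr(fx$molecules, fx$ref_charges,
                               kappa_min = -0.1),
               class = "eem_usage_error")
  expect_error(parameterize_lr(fx$molecules, fx$ref_charges,
                               kappa_step = 0),
               class = "eem_usage_error")
})

test_that("greedy discard removes a corrupted molecule and improves the metric", {
  fx <- clean_fixtures()
  kap <- fx$ground_truth$kappa
  grid <- list(kappa_min = kap / 2, kappa_max = 2 * kap,
               kappa_step = kap / 4)

  # corrupt one molecule's reference charges with heavy noise
  ref <- unclass(fx$ref_charges)
  victim <- names(ref)[5]
  set.seed(123)
  noise <- rnorm(length(ref[[victim]]), 0, 0.5)
  ref[[victim]] <- ref[[victim]] + noise - mean(noise)
  ref <- charge_set(ref)

  base <- parameterize_lr(fx$molecules, ref, kappa_min = grid$kappa_min,
                          kappa_max = grid$kappa_max,
                          kappa_step = grid$kappa_step)
  searched <- parameterize_lr(fx$molecules, ref, discard = "greedy",
                              kappa_min = grid$kappa_min,
                              kappa_max = grid$kappa_max,
                              kappa_step = grid$kappa_step)
  expect_true(victim %in% searched$discarded)
  expect_lt(searched$quality$avg_rmsd_a, base$quality$avg_rmsd_a)

  # a zero discard budget reproduces the plain scan
  zero <- parameterize_lr(fx$molecules, ref, discard = "greedy",
                          max_discard_fraction = 0,
                          kappa_min = grid$kappa_min,
                          kappa_max = grid$kappa_max,
                          kappa_step = grid$kappa_step)
  expect_identical(zero$set$entries, base$set$entries)
  expect_length(zero$discarded, 0)

  # all-clean data: nothing to discard
  clean <- parameterize_lr(fx$molecules, fx$ref_charges,
                           discard = "greedy",
                           kappa_min = grid$kappa_min,
                           kappa_max = grid$kappa_max,
                           kappa_step = grid$kappa_step)
  expect_length(clean$discarded, 0)
})
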
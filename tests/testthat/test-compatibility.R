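test_that("commutator expectation has the algebraic properties it must", {
  set.seed(8)
  m <- random_rank1_projector(3)
  v <- random_unit(3)
  # an operator commutes with itself
  expect_equal(Mod(commutator_expectation(m, m, v)), 0)
  # real symmetric operators on a real state: antisymmetric commutator has
  # zero diagonal quadratic form
  m1 <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3) + 0i
  m2 <- matrix(c(0.5, 0.5, 0, 0.5, 0.5, 0, 0, 0, 0), 3, 3) + 0i
  expect_equal(Mod(commutator_expectation(m1, m2, c(0.6, 0.8, 0) + 0i)), 0)
  # Hermitian inputs give purely imaginary values
  for (k in 1:20) {
    p1 <- random_rank1_projector(4)
    p2 <- random_rank1_projector(4)
    w <- random_unit(4)
    z <- commutator_expectation(p1, p2, w)
    expect_lt(abs(Re(z)), 1e-12)
    # matches direct dense-matrix arithmetic
    direct <- Conj(w) %*% (p1 %*% p2 - p2 %*% p1) %*% w
    expect_equal(z, direct[1, 1])
  }
  expect_error(commutator_expectation(diag(2) + 0i, diag(3) + 0i, c(1, 0)))
})

test_that("the Machine/Vehicle pair is incompatible in the first sector", {
  d <- read_membership_csv(fixture_csv("machine_vehicle.csv"))
  model <- unify_first_sector(fit_first_sector(d))
  cm <- compatibility_matrix(model)
  pair <- cm[cm$exemplar_1 != cm$exemplar_2, ]
  # at least one commutator expectation is decisively nonzero
  expect_gt(max(pair$mag_a, pair$mag_b, pair$mag_ab), 1e-10)
  expect_false(pair$compatible)
  # diagonal is exactly compatible
  diag_rows <- cm[cm$exemplar_1 == cm$exemplar_2, ]
  expect_true(all(diag_rows$compatible))
  expect_equal(max(diag_rows$mag_a, diag_rows$mag_b, diag_rows$mag_ab), 0)
})

test_that("identical triplets give commuting operators", {
  d <- membership_triplets(c("p1", "p2", "p3"),
    mu_a = rep(0.4, 3), mu_b = rep(0.5, 3), mu_ab = rep(0.55, 3)
  )
  cm <- compatibility_matrix(unify_first_sector(fit_first_sector(d)))
  expect_lt(max(cm$mag_a, cm$mag_b, cm$mag_ab), 1e-10)
  expect_true(all(cm$compatible))
})

test_that("second-sector compatibility vanishes identically for classical data", {
  d <- read_membership_csv(fixture_csv("building_dwelling.csv"))
  cm <- compatibility_matrix(unify_zero_type(d))
  expect_lt(max(cm$mag_a, cm$mag_b, cm$mag_ab), 1e-10)
  expect_true(all(cm$compatible))
  # randomized classical datasets under the all-real construction
  for (k in 1:5) {
    sim <- simulate_triplets(5, "classical", seed = 300 + k)
    cm <- compatibility_matrix(unify_zero_type(sim))
    expect_lt(max(cm$mag_a, cm$mag_b, cm$mag_ab), 1e-10)
  }
})

test_that("magnitudes are symmetric in exemplar order and unitarily invariant", {
  d <- read_membership_csv(fixture_csv("machine_vehicle.csv"))
  model <- unify_first_sector(fit_first_sector(d))
  p12 <- compatibility_pair(model, 1, 2)
  p21 <- compatibility_pair(model, 2, 1)
  expect_equal(p12$mag_a, p21$mag_a)
  expect_equal(p12$mag_ab, p21$mag_ab)

  # applying one further global unitary to the whole model leaves
  # magnitudes unchanged (states and operators transported together)
  set.seed(14)
  u <- build_basis_change(
    complete_orthonormal_basis(random_orthonormal_pair(3), 3),
    fockconj:::canonical_basis(3)
  )
  rotated <- model
  rotated$state_a <- u %*% model$state_a
  rotated$state_b <- u %*% model$state_b
  rotated$operators <- lapply(model$operators, conjugate_operator, u = u)
  p_rot <- compatibility_pair(rotated, 1, 2)
  expect_equal(p_rot$mag_a, p12$mag_a, tolerance = 1e-10)
  expect_equal(p_rot$mag_b, p12$mag_b, tolerance = 1e-10)
  expect_equal(p_rot$mag_ab, p12$mag_ab, tolerance = 1e-10)
})

test_that("pairwise matrix shape and guards", {
  d <- membership_triplets(c("x", "y"), c(0.3, 0.4), c(0.4, 0.5), c(0.45, 0.5))
  model <- unify_first_sector(fit_first_sector(d))
  cm <- compatibility_matrix(model)
  expect_identical(nrow(cm), 3L) # 2 diagonal + 1 off-diagonal
  one <- unify_first_sector(fit_first_sector(d[1, ]))
  expect_error(compatibility_matrix(one), "at least two")
})
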
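test_that("tensor construction reproduces classical triplets exactly", {
  r <- construct_tensor_rep(0.56, 0.8, 0.42)
  expect_equal(
    as.vector(t(r$coefficients)),
    c(sqrt(0.42), sqrt(0.14), sqrt(0.38), sqrt(0.06))
  )
  expect_equal(tensor_expectations(r),
    c(mu_a = 0.56, mu_b = 0.8, mu_ab = 0.42),
    tolerance = 1e-12
  )
  # all construction phases are zero and M is the rank-1 canonical projector
  expect_equal(r$phases, matrix(0, 2, 2))
  expect_equal(r$projector, fockconj:::canonical_projector(2, 1))

  r1 <- construct_tensor_rep(1, 1, 1)
  expect_equal(r1$coefficients[1, 1], 1)
  expect_equal(sum(r1$coefficients^2), 1)

  expect_error(construct_tensor_rep(0.28, 0.84, 0.34),
    "mu_ab <= mu_a",
    class = "fockconj_representability_error"
  )
  expect_error(construct_tensor_rep(0.9, 0.8, 0.4),
    "mu_a \\+ mu_b",
    class = "fockconj_representability_error"
  )
})

test_that("tensor representability is equivalent to classicality (both directions)", {
  set.seed(17)
  # classical triplets always construct, with exact expectations
  sim <- simulate_triplets(100, "classical", seed = 19)
  for (i in seq_len(nrow(sim))) {
    r <- construct_tensor_rep(sim$mu_a[i], sim$mu_b[i], sim$mu_ab[i])
    expect_lt(max(abs(tensor_expectations(r) - r$triplet)), 1e-10)
  }
  # non-classical triplets always rejected
  for (k in 1:100) {
    a <- runif(1)
    b <- runif(1)
    ab <- runif(1)
    if (oracle_classical(a, b, ab)) next
    expect_error(construct_tensor_rep(a, b, ab),
      class = "fockconj_representability_error"
    )
  }
})

test_that("brute-force search over tensor coefficients confirms rejection", {
  # sample many states and rank-1 factor projectors; the reachable triplets
  # form the classical polytope, so clearly non-classical targets are never
  # approached
  set.seed(23)
  samples <- t(replicate(4000, {
    v <- random_unit(4)
    m <- random_rank1_projector(2)
    id <- diag(2) + 0i
    c(
      Re(qip(v, kronecker(m, id) %*% v)),
      Re(qip(v, kronecker(id, m) %*% v)),
      Re(qip(v, kronecker(m, m) %*% v))
    )
  }))
  targets <- rbind(
    c(0.28, 0.84, 0.44), # overextension by 0.1
    c(0.5, 0.5, 0.7), # double overextension
    c(0.95, 0.95, 0.5) # Kolmogorov factor violation by 0.4
  )
  for (i in seq_len(nrow(targets))) {
    expect_false(oracle_classical(targets[i, 1], targets[i, 2], targets[i, 3]))
    dists <- apply(samples, 1, function(s) max(abs(s - targets[i, ])))
    expect_gt(min(dists), 0.03)
  }
})

test_that("zero-type unification shares one state and preserves all data", {
  d <- read_membership_csv(fixture_csv("building_dwelling.csv"))
  model <- unify_zero_type(d)
  expect_equal(model$state, c(1 + 0i, 0, 0, 0)) # |1> (x) |1>
  td <- tidy(model)
  expect_lt(max(td$residual), 1e-10)
  expect_equal(td$mu_ab_hat, c(0.28, 0.45), tolerance = 1e-10)
  # conjugated operators remain projectors; m_and = m_a m_b
  for (trip in model$operators) {
    expect_true(fockconj:::is_projector(trip$m_a))
    expect_true(fockconj:::is_projector(trip$m_b))
    expect_lt(max(Mod(trip$m_a %*% trip$m_b - trip$m_and)), 1e-10)
  }

  # a triplet whose state is already |1>(x)|1> gets the identity unitary
  one <- unify_zero_type(membership_triplets("p", 1, 1, 1))
  expect_lt(max(Mod(one$unitaries[[1]] - diag(4))), 1e-10)
  expect_true(one$first_type[["p"]])

  # random classical datasets: all 3k expectations preserved
  for (k in 1:5) {
    sim <- simulate_triplets(6, "classical", seed = 200 + k)
    expect_lt(max(tidy(unify_zero_type(sim))$residual), 1e-10)
  }

  expect_error(
    unify_zero_type(membership_triplets("bad", 0.28, 0.84, 0.34)),
    class = "fockconj_representability_error"
  )
})

test_that("second-type models exist exactly for independent triplets", {
  sim <- simulate_triplets(8, "independent", seed = 33)
  model <- unify_second_type(sim)
  v <- model$state
  for (i in seq_len(nrow(sim))) {
    trip <- fockconj:::model_operator_triple(model, sim$exemplar[i])
    got <- c(
      Re(qip(v, trip$m_a %*% v)),
      Re(qip(v, trip$m_b %*% v)),
      Re(qip(v, trip$m_and %*% v))
    )
    expect_equal(got, c(sim$mu_a[i], sim$mu_b[i], sim$mu_ab[i]),
      tolerance = 1e-10
    )
  }
  # (1,1,1): both factor operators are the projector onto the full factor...
  all1 <- unify_second_type(membership_triplets("p", 1, 1, 1))
  expect_equal(as.vector(all1$operators$p$m_a %*% c(1, 0)), c(1 + 0i, 0))
  # dependent triplet has no product-state representation
  expect_error(unify_second_type(membership_triplets("dep", 0.56, 0.8, 0.42)),
    class = "fockconj_representability_error"
  )
})

test_that("trivial embedding into three-dimensional factors changes nothing", {
  d <- read_membership_csv(fixture_csv("building_dwelling.csv"))
  m2 <- unify_zero_type(d)
  m3 <- embed_in_C3(m2)
  expect_identical(m3$factor_dim, 3L)
  expect_equal(sum(Mod(m3$state)^2), 1) # zero padding preserves unit norm
  td2 <- tidy(m2)
  td3 <- tidy(m3)
  expect_equal(td3$mu_ab_hat, td2$mu_ab_hat, tolerance = 1e-12)
  expect_lt(max(td3$residual), 1e-10)
  for (trip in m3$operators) {
    for (op in trip) expect_true(fockconj:::is_projector(op))
  }
  # second-type embedding
  s2 <- unify_second_type(simulate_triplets(3, "independent", seed = 9))
  s3 <- embed_in_C3(s2)
  expect_identical(dim(s3$operators[[1]]$m_a), c(3L, 3L))
  expect_identical(s3$factor_dim, 3L)
})
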
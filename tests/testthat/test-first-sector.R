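test_that("feasibility interval matches its closed form", {
  fi <- feasibility_interval(tibble::tibble(mu_a = 0.28, mu_b = 0.84, mu_ab = 0.34))
  expect_equal(fi$ave, 0.56)
  expect_equal(fi$dev, sqrt(0.72 * 0.16))
  expect_equal(fi$fs_lo, 0.56 - sqrt(0.1152))
  expect_equal(fi$fs_hi, 0.56 + sqrt(0.1152))
  expect_true(fi$first_sector_feasible) # 0.34 inside [0.2206, 0.8994]

  # a weight of exactly 1 collapses the interval to a point
  fi2 <- feasibility_interval(tibble::tibble(mu_a = 1, mu_b = 0.49, mu_ab = 0.78))
  expect_equal(fi2$dev, 0)
  expect_equal(fi2$fs_lo, 0.745)
  expect_false(fi2$first_sector_feasible)

  fi3 <- feasibility_interval(tibble::tibble(mu_a = 0, mu_b = 0, mu_ab = 0))
  expect_equal(c(fi3$fs_lo, fi3$fs_hi), c(0, 0))
  expect_true(fi3$first_sector_feasible)
})

test_that("constructive solver hits every branch with tiny residuals", {
  r <- construct_first_sector(0.97, 0.31, 0.53)
  expect_identical(r$branch, "rank2")
  expect_lt(max(verify_first_sector(r)), 1e-10)

  r <- construct_first_sector(0.2, 0.3, 0.15)
  expect_identical(r$branch, "rank1")
  expect_lt(max(verify_first_sector(r)), 1e-10)

  # at mu_a + mu_b = 1 exactly the rank-1 branch is chosen
  r <- construct_first_sector(0.4, 0.6, 0.5)
  expect_identical(r$branch, "rank1")
  expect_lt(max(verify_first_sector(r)), 1e-10)

  # degenerate all-one / all-zero triplets
  r1 <- construct_first_sector(1, 1, 1)
  expect_identical(r1$branch, "rank3")
  expect_equal(r1$projector, diag(3) + 0i)
  expect_equal(max(verify_first_sector(r1)), 0)
  r0 <- construct_first_sector(0, 0, 0)
  expect_identical(r0$branch, "rank0")
  expect_equal(max(verify_first_sector(r0)), 0)

  # infeasible triplet is rejected with the interval in the message
  expect_error(construct_first_sector(1, 0.49, 0.78),
    "0.745",
    class = "fockconj_representability_error"
  )
})

test_that("solver residuals stay below 1e-10 across random feasible triplets", {
  set.seed(21)
  for (k in 1:200) {
    a <- runif(1)
    b <- runif(1)
    fb <- fockconj:::fs_bounds(a, b)
    ab <- runif(1, max(fb$lo, 0), min(fb$hi, 1))
    r <- construct_first_sector(a, b, ab)
    expect_lt(max(verify_first_sector(r)), 1e-10)
    # branch rule: rank 1 iff the weights sum to at most 1
    expect_identical(r$branch, if (a + b <= 1) "rank1" else "rank2")
    # determinism
    r2 <- construct_first_sector(a, b, ab)
    expect_identical(r$state_a, r2$state_a)
  }
})

test_that("verify_first_sector flags hand-built violations", {
  r <- construct_first_sector(0.5, 0.3, 0.35)
  r$state_b <- (r$state_a + r$state_b) / sqrt(2) # break orthogonality
  res <- verify_first_sector(r)
  expect_gt(res[["orthogonality"]], 0.1)
})

test_that("edge weights at 0/1 are handled by the reduced constructions", {
  cases <- list(
    c(1, 0, 0.5), c(0, 1, 0.5), c(1, 0.49, 0.745), c(0, 0.3, 0.15),
    c(0.3, 0, 0.15), c(0.6, 1, 0.8), c(1, 1, 1), c(0, 0, 0)
  )
  for (tc in cases) {
    r <- construct_first_sector(tc[1], tc[2], tc[3])
    expect_lt(max(verify_first_sector(r)), 1e-10)
  }
})

test_that("unification preserves all membership expectations exactly", {
  d <- read_membership_csv(fixture_csv("machine_vehicle.csv"))
  fit <- fit_first_sector(d)
  expect_true(all(fit$data$first_sector_feasible))
  model <- unify_first_sector(fit)
  # canonical single conceptual state pair
  expect_equal(model$state_a, c(1 + 0i, 0, 0))
  expect_equal(model$state_b, c(0, 1 + 0i, 0))
  td <- tidy(model)
  expect_lt(max(td$residual), 1e-10)
  expect_equal(td$mu_ab_hat, c(0.42, 0.34), tolerance = 1e-10)

  # filing cabinet: <A|M|A> recovers 0.97 in the unified basis
  fc <- fit_first_sector(membership_triplets("filing cabinet", 0.97, 0.31, 0.53))
  m1 <- unify_first_sector(fc)$operators[[1]]
  expect_equal(Re(qip(c(1, 0, 0), m1 %*% c(1, 0, 0))), 0.97, tolerance = 1e-10)

  # random datasets: all 3k expectations preserved, operators stay projectors
  set.seed(31)
  for (k in 1:10) {
    sim <- simulate_triplets(5, "overextended_representable", seed = 100 + k)
    um <- unify_first_sector(fit_first_sector(sim))
    expect_lt(max(tidy(um)$residual), 1e-10)
    for (op in um$operators) expect_true(fockconj:::is_projector(op))
  }

  # single rep already canonical: unitary is the identity
  one <- fit_first_sector(membership_triplets("p", 0, 0, 0))
  u <- unify_first_sector(one)$unitaries[[1]]
  expect_lt(max(Mod(u - diag(3))), 1e-10)

  # infeasible member blocks unification
  bad <- fit_first_sector(
    membership_triplets(c("x", "y"), c(0.5, 1), c(0.5, 0.49), c(0.5, 0.78))
  )
  expect_error(unify_first_sector(bad),
    class = "fockconj_representability_error"
  )
})

test_that("unification preserves pairwise inner products among states", {
  set.seed(41)
  sim <- simulate_triplets(4, "overextended_representable", seed = 77)
  fit <- fit_first_sector(sim)
  model <- unify_first_sector(fit)
  for (nm in names(fit$reps)) {
    r <- fit$reps[[nm]]
    u <- model$unitaries[[nm]]
    m <- model$operators[[nm]]
    # <A_i|Mhat|B_i> = <A|M_i|B> after the change of basis
    expect_lt(
      Mod(qip(r$state_a, r$projector %*% r$state_b) -
        qip(model$state_a, m %*% model$state_b)), 1e-12
    )
    expect_lt(Mod(qip(u %*% r$state_a, u %*% r$state_b)), 1e-12)
  }
})
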
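test_that("zero-hyperfine yield has the closed form (1/4) kX/(kX+kS)", {
  for (p in list(c(1, 1), c(2, 0.5), c(0.3, 7))) {
    m <- pair_no_nuclei(k_X = p[1], k_Sigma = p[2])
    expect_equal(scavenging_yield(m, 50), 0.25 * p[1] / (p[1] + p[2]),
                 tolerance = 1e-10)
  }
  # k_X = 0 gives zero yield
  expect_equal(scavenging_yield(pair_no_nuclei(k_X = 0, k_Sigma = 1), 50), 0)
  # k_X = k_Sigma = 0 diverges
  expect_error(scavenging_yield(pair_no_nuclei(k_X = 0, k_Sigma = 0), 50),
               "divergence")
  # vanishing hyperfine coupling approaches the closed form
  m_eps <- pair_one_proton(a_iso = 1e-6, k_X = 1, k_Sigma = 0.5)
  expect_equal(scavenging_yield(m_eps, 0), 0.25 / 1.5, tolerance = 1e-8)
})

test_that("algebraic and ODE routes agree on randomized small models", {
  set.seed(101)
  for (rep in 1:20) {
    m <- random_small_model()
    B <- stats::runif(1, 0, 100)
    fc <- field_condition(B, c(0, 0, 1)) # fixed direction for both routes
    alg <- scavenging_yield(m, fc, method = "algebraic")
    ode <- scavenging_yield(m, fc, method = "ode")
    expect_gte(alg, 0); expect_lte(alg, 1)
    expect_equal(alg, ode, tolerance = 1e-6)
  }
})

test_that("relaxation path (sparse Liouville solve) matches the ODE oracle", {
  m <- pair_one_proton(a_iso = 10, k_X = 1, k_Sigma = 0.1,
                       gamma1 = 0.5, gamma3 = 0.2)
  for (B in c(0, 10, 55.26)) {
    fc <- field_condition(B, c(0, 0, 1))
    expect_equal(scavenging_yield(m, fc, method = "algebraic"),
                 scavenging_yield(m, fc, method = "ode"),
                 tolerance = 1e-6)
  }
  # fast relaxation continuously re-randomizes the pair: the yield
  # approaches (kX/4) / (kX/4 + kSigma)
  m_fast <- pair_one_proton(a_iso = 10, k_X = 1, k_Sigma = 0.01,
                            gamma1 = 100, gamma3 = 100)
  y <- scavenging_yield(m_fast, 0)
  expect_lt(abs(y - 0.25 / 0.26), 0.01)
})

test_that("superoxide yield branching follows Y = (1-phi) PhiX + phi", {
  expect_equal(superoxide_yield(0.5, 0.2), 0.6)
  expect_equal(superoxide_yield(0.37, 0), 0.37)
  expect_equal(superoxide_yield(0.37, 1), 1)
  expect_error(superoxide_yield(1.2, 0), "domain")
  expect_error(superoxide_yield(0.5, -0.1), "domain")
})

test_that("chi is 1 at the reference field and clamps to 1 when phi = 1", {
  m <- pair_one_proton(a_iso = 10, k_X = 1, k_Sigma = 0.5)
  chi <- mfe_ratio(m, GMF_uT, GMF_uT)
  expect_equal(as.numeric(chi), 1, tolerance = 1e-12)
  expect_equal(attr(chi, "effect_pct"), 0, tolerance = 1e-10)
  m1 <- update_rates(m, phi = 1)
  expect_equal(as.numeric(mfe_ratio(m1, 0.29, 55.26)), 1, tolerance = 1e-12)
})

test_that("initial spin correlation labels do not change reduced yields", {
  # the reduced initial state is maximally mixed for triplet-, singlet-
  # and F-pair-born primary pairs alike, so results are bit-identical
  m <- pair_one_proton(a_iso = 10, k_X = 1, k_Sigma = 0.5)
  sp <- m$space
  states <- list(triplet = initial_state(sp), singlet = initial_state(sp),
                 fpair = initial_state(sp))
  expect_identical(states$triplet, states$singlet)
  expect_identical(states$triplet, states$fpair)
})

test_that("orientation averaging reduces to a point for isotropic models", {
  m_iso <- pair_one_proton(a_iso = 10, k_X = 1, k_Sigma = 0.5)
  expect_equal(orientation_average(m_iso, 30),
               scavenging_yield(m_iso, field_condition(30, c(0, 0, 1))),
               tolerance = 1e-10)
  # anisotropic model: average lies within the per-orientation range and
  # is stable under quadrature doubling
  rb <- radical("b", list(nucleus("H", 2,
                                  hyperfine_tensor(diag(c(2, 2, 30))))),
                mobility = "bound")
  mb <- reduced_pair_model(rb, "superoxide", rate_set(k_X = 1, k_Sigma = 0.5))
  dirs <- fibonacci_sphere(24)
  per_or <- vapply(seq_len(nrow(dirs)), function(i) {
    scavenging_yield(mb, field_condition(40, dirs[i, ]))
  }, numeric(1))
  avg <- orientation_average(mb, 40, n_directions = 24)
  expect_gte(avg, min(per_or)); expect_lte(avg, max(per_or))
  avg2 <- orientation_average(mb, 40, n_directions = 48)
  expect_lt(abs(avg2 - avg), 1e-3)
  expect_warning(orientation_average(mb, 40, n_directions = 4), "< 6 nodes")
})

test_that("field sweeps are continuous, consistent and zero-field regular", {
  m <- pair_one_proton(a_iso = 10, k_X = 1, k_Sigma = 0.5)
  Bs <- seq(0, 4, by = 0.5)
  sw <- field_sweep(m, Bs, reference = 2)
  expect_s3_class(sw, "mary_curve")
  expect_equal(nrow(sw), length(Bs))
  # single-point sweep reproduces scavenging_yield exactly
  expect_equal(sw$phi_X[Bs == 1], scavenging_yield(m, 1))
  # continuity in B: refined grid has small adjacent jumps
  fine <- field_sweep(m, seq(0, 4, by = 0.1), reference = 2)
  expect_lt(max(abs(diff(fine$phi_X))), 0.01)
  # zero-field limit is continuous
  expect_equal(scavenging_yield(m, 1e-4), scavenging_yield(m, 0),
               tolerance = 1e-5)
})

test_that("rate maps collapse to mfe_ratio on a 1x1 grid", {
  m <- pair_one_proton(a_iso = 10, k_X = 1, k_Sigma = 0.5)
  map <- rate_map(m, kX_grid = 1, kSigma_grid = 0.5, B = 0.29, B_ref = 55.26)
  expect_equal(nrow(map), 1)
  expect_equal(map$chi, as.numeric(mfe_ratio(m, 0.29, 55.26)),
               tolerance = 1e-10)
  w <- max_mfe(map)
  expect_equal(w$effect_pct, map$effect_pct)
})

test_that("the inverse field problem honors its bracket and tolerance", {
  m <- pair_one_proton(a_iso = 10, k_X = 1, k_Sigma = 0.5)
  expect_identical(field_for_effect(m, 0, B_ref = 3), 3)
  target <- 1
  b <- field_for_effect(m, target, B_ref = 0, bracket = c(0.2, 8))
  eff <- abs(100 * (scavenging_yield(m, b) / scavenging_yield(m, 0) - 1))
  expect_equal(eff, target, tolerance = 0.05)
  # invariant under bracket refinement (1% relative)
  b2 <- field_for_effect(m, target, B_ref = 0,
                         bracket = c(b - 0.5, b + 0.5))
  expect_equal(b2, b, tolerance = 0.02 * b)
  expect_error(field_for_effect(m, 50, B_ref = 0, bracket = c(0.2, 1)),
               "bracket|monotone")
})

test_that("log grids span the requested decades at the requested density", {
  g <- log_grid(1e-2, 1e3)
  expect_equal(length(g), 51)
  expect_equal(g[1], 1e-2); expect_equal(g[51], 1e3)
  expect_equal(length(log_grid(1e-2, 1e2, 5)), 21)
})
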
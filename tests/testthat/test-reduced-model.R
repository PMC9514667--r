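test_that("rate sets compose k_Sigma from components and reject conflicts", {
  r <- rate_set(k_X = 1, k_E = 1, k_Ep = 2, k_F = 4, k_Xp = 8)
  expect_equal(r$k_Sigma, 1 + 2 + 4 / 4 + 8 / 4) # = 6
  expect_silent(rate_set(k_X = 1, k_Sigma = 6, k_E = 1, k_Ep = 2,
                         k_F = 4, k_Xp = 8))
  expect_error(rate_set(k_X = 1, k_Sigma = 5, k_E = 1, k_Ep = 2,
                        k_F = 4, k_Xp = 8), "inconsistent")
  expect_error(rate_set(k_X = -1, k_Sigma = 1), "invalid rate")
  expect_error(rate_set(k_X = 1, k_Sigma = 1, phi = 1.5), "phi")
  expect_error(rate_set(k_X = 1), "k_Sigma")
})

test_that("Zeeman Hamiltonian reproduces the electron Larmor frequency", {
  sp <- spin_space(2, "e")
  r <- radical("e")
  # B = 0 gives the zero matrix
  expect_equal(zeeman_hamiltonian(r, c(0, 0, 0), sp, 1),
               matrix(0i, 2, 2))
  # 50 uT along z: splitting hbar*omega with omega/2pi = 1.4 MHz
  H <- zeeman_hamiltonian(r, c(0, 0, 50), sp, 1)
  expect_hermitian(H)
  ev <- sort(Re(eigen(H, only.values = TRUE)$values))
  expect_equal((ev[2] - ev[1]) / (2 * pi), 1.4, tolerance = 0.01)
  expect_equal(larmor_frequency_MHz(50), 1.4, tolerance = 0.01)
  # linear in |B|
  H2 <- zeeman_hamiltonian(r, c(0, 0, 100), sp, 1)
  expect_lt(max(abs(H2 - 2 * H)), 1e-12)
})

test_that("hyperfine Hamiltonian: doublet algebra and mobility reduction", {
  # no nuclei -> zero
  sp0 <- spin_space(c(2, 2))
  expect_equal(hyperfine_hamiltonian(radical_preset("superoxide"), sp0, 1,
                                     integer(0)),
               matrix(0i, 4, 4))
  # one spin-1/2 nucleus, isotropic a: eigenvalues a/4 (x3), -3a/4
  a <- 10
  r <- radical("t", list(nucleus("H", 2, hyperfine_tensor(a))))
  sp <- spin_space(c(2, 2), c("e", "H"))
  H <- hyperfine_hamiltonian(r, sp, 1, 2L) / MHZ_TO_ANGULAR
  ev <- sort(Re(eigen(H, only.values = TRUE)$values))
  expect_equal(ev, c(-3 * a / 4, rep(a / 4, 3)), tolerance = 1e-10)
  # free == bound when the tensor is already isotropic
  rb <- radical("t", list(nucleus("H", 2, hyperfine_tensor(a))),
                mobility = "bound")
  expect_equal(hyperfine_hamiltonian(rb, sp, 1, 2L), H * MHZ_TO_ANGULAR)
  # free mode keeps only the isotropic part of an anisotropic tensor
  A <- diag(c(1, 2, 6))
  rf <- radical("t", list(nucleus("H", 2, hyperfine_tensor(A))))
  Hf <- hyperfine_hamiltonian(rf, sp, 1, 2L)
  riso <- radical("t", list(nucleus("H", 2, hyperfine_tensor(3))))
  expect_lt(max(abs(Hf - hyperfine_hamiltonian(riso, sp, 1, 2L))), 1e-12)
})

test_that("reduced Hamiltonian is Hermitian and respects symmetries", {
  m <- reduced_pair_model("flavin_3N", "ascorbyl_H4",
                          rate_set(k_X = 1, k_Sigma = 1))
  H <- reduced_hamiltonian(m, field_vector(55.26, 0.7, 1.2))
  expect_equal(dim(H), c(144L, 144L))
  expect_hermitian(H)
  # no nuclei, B = 0 -> zero
  m0 <- pair_no_nuclei()
  expect_equal(reduced_hamiltonian(m0, c(0, 0, 0)), matrix(0i, 4, 4))
  # equal g, no hyperfine: H commutes with the singlet projector
  H0 <- reduced_hamiltonian(m0, c(10, 20, 30))
  P <- singlet_projector(m0$space, 1, 2)
  expect_lt(max(abs(H0 %*% P - P %*% H0)), 1e-10)
})

test_that("Haberkorn superoperator drains trace at the stated rate", {
  m <- pair_no_nuclei(k_X = 1, k_Sigma = 0.5)
  K <- haberkorn_reduced(m)
  sigma0 <- initial_state(m$space)
  ds <- K(sigma0)
  # d Tr/dt = -kX Tr(P sigma) - kSigma Tr(sigma) = -1/4 - 1/2
  expect_equal(Re(sum(diag(ds))), -0.75, tolerance = 1e-12)
  # kX = 0: uniform decay at k_Sigma
  m2 <- pair_no_nuclei(k_X = 0, k_Sigma = 2)
  expect_lt(max(abs(haberkorn_reduced(m2)(sigma0) + 2 * sigma0)), 1e-12)
  # Hermiticity preserved
  set.seed(7)
  X <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  X <- (X + Conj(t(X))) / 2
  expect_hermitian(K(X), 1e-12)
})

test_that("random-field relaxation is trace preserving with T1 = T2 = 1/gamma", {
  sp <- spin_space(c(2, 2))
  # gamma = 0 gives the zero map
  R0 <- random_field_relaxation(0, 0, sp)
  sigma <- initial_state(sp)
  expect_equal(R0(sigma), 0 * sigma)
  gam <- 0.8
  R <- random_field_relaxation(gam, 0, sp)
  # trace preserving on random Hermitian input
  set.seed(11)
  X <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  X <- (X + Conj(t(X))) / 2
  expect_lt(abs(sum(diag(R(X)))), 1e-12)
  # <Sz> and <Sx> of electron 1 decay exponentially at rate gamma:
  # integrate d sigma/dt = R(sigma) and fit the decay
  s1 <- triadspin:::embedded_spin(1, sp)
  sig <- diag(4) / 4 + 0.3 * s1$z + 0.2 * s1$x
  dt <- 0.01
  ts <- seq(0, 2, by = dt)
  obs <- matrix(0, length(ts), 2)
  for (i in seq_along(ts)) {
    obs[i, ] <- c(Re(sum(Conj(t(s1$z)) * sig)), Re(sum(Conj(t(s1$x)) * sig)))
    k1 <- R(sig); k2 <- R(sig + dt / 2 * k1); k3 <- R(sig + dt / 2 * k2)
    k4 <- R(sig + dt * k3)
    sig <- sig + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  fit_z <- stats::lm(log(obs[, 1]) ~ ts)
  fit_x <- stats::lm(log(obs[, 2]) ~ ts)
  expect_equal(unname(stats::coef(fit_z)[2]), -gam, tolerance = 1e-4)
  expect_equal(unname(stats::coef(fit_x)[2]), -gam, tolerance = 1e-4)
})

test_that("the maximally mixed initial state has 1/4 singlet character", {
  for (mult in list(c(2, 2), c(2, 2, 3, 2))) {
    sp <- spin_space(mult)
    s0 <- initial_state(sp)
    expect_equal(Re(sum(diag(s0))), 1)
    expect_equal(max(abs(s0 - diag(sp$dim) / sp$dim)), 0)
    P <- singlet_projector(sp, 1, 2)
    expect_equal(Re(sum(diag(P %*% s0))), 0.25, tolerance = 1e-12)
  }
})

test_that("trajectories stay Hermitian and positive; trace ledger closes", {
  m <- pair_one_proton(a_iso = 8, k_X = 2, k_Sigma = 0.3)
  rhs <- triadspin:::reduced_rhs(m, field_vector(30))
  sig <- initial_state(m$space)
  dt <- 0.002
  for (step in 1:500) {
    k1 <- rhs(sig); k2 <- rhs(sig + dt / 2 * k1); k3 <- rhs(sig + dt / 2 * k2)
    k4 <- rhs(sig + dt * k3)
    sig <- sig + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (step %% 100 == 0) {
      expect_hermitian(sig, 1e-8)
      expect_gt(min(Re(eigen(sig, only.values = TRUE)$values)), -1e-8)
    }
  }
  # exit-probability ledger: phi_X + k_Sigma * int Tr sigma dt = 1
  yc <- yield_components(m, 30)
  expect_equal(yc$exit_total, 1, tolerance = 1e-6)
})

test_that("without mixing the singlet population decays as (1/4) e^-(kX+kS)t", {
  m <- pair_no_nuclei(k_X = 1.3, k_Sigma = 0.4)
  rhs <- triadspin:::reduced_rhs(m, c(0, 0, 20))
  P <- singlet_projector(m$space, 1, 2)
  sig <- initial_state(m$space)
  dt <- 0.005
  for (step in 1:200) {
    k1 <- rhs(sig); k2 <- rhs(sig + dt / 2 * k1); k3 <- rhs(sig + dt / 2 * k2)
    k4 <- rhs(sig + dt * k3)
    sig <- sig + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  t_end <- 200 * dt
  expect_equal(Re(sum(diag(P %*% sig))),
               0.25 * exp(-(1.3 + 0.4) * t_end), tolerance = 1e-8)
})
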
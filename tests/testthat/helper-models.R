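# Toy systems used across the suite. All are built in code; nothing is
# read from disk.

# two electrons, no nuclei: singlet-triplet mixing is absent and the
# scavenging yield has the closed form (1/4) kX / (kX + kSigma)
pair_no_nuclei <- function(k_X = 1, k_Sigma = 1, ...) {
  reduced_pair_model("superoxide", "superoxide",
                     rate_set(k_X = k_X, k_Sigma = k_Sigma), ...)
}

# one isotropic proton on radical 1
pair_one_proton <- function(a_iso = 10, k_X = 1, k_Sigma = 0.1, ...) {
  reduced_pair_model(
    radical("toy", list(nucleus("H", 2L, hyperfine_tensor(a_iso)))),
    "superoxide",
    rate_set(k_X = k_X, k_Sigma = k_Sigma), ...
  )
}

# randomized small model (<= 2 nuclei) for property-style checks
random_small_model <- function(max_nuclei = 2) {
  n1 <- sample(0:max_nuclei, 1)
  nuc <- lapply(seq_len(n1), function(i) {
    mult <- sample(2:3, 1)
    A <- matrix(stats::rnorm(9, sd = 5), 3, 3)
    nucleus(paste0("n", i), mult,
            suppressWarnings(hyperfine_tensor(A)))
  })
  mobility <- sample(c("free", "bound"), 1)
  reduced_pair_model(
    radical("r1", nuc, mobility = mobility),
    "superoxide",
    rate_set(k_X = stats::runif(1, 0.1, 10),
             k_Sigma = stats::runif(1, 0.05, 5))
  )
}

# electrons-only triad with flavin/superoxide and flavin/scavenger
# recombination channels
triad_electrons_only <- function(k_F = 1, k_X = 1, k_Xp = 0, k_E = 0,
                                 k_Ep = 0, gamma2 = 0) {
  triad_system("superoxide", "superoxide", "superoxide",
               k_F = k_F, k_X = k_X, k_Xp = k_Xp, k_E = k_E, k_Ep = k_Ep,
               gamma2 = gamma2)
}

expect_hermitian <- function(M, tol = 1e-10) {
  expect_lt(max(abs(M - Conj(t(M)))), tol)
}
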
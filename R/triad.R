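#' Full three-radical (triad) system
#'
#' Desk-scale reference model of the complete flavin/superoxide/scavenger
#' triad, used to verify that tracing out a fast-relaxing superoxide
#' (radical 2) reproduces the reduced two-radical model with composite
#' rate k_Sigma = k_E + k_Ep + k_F/4 + k_Xp/4. The total Hilbert
#' dimension is capped at 512: this is a verification tool, not the
#' production path.
#'
#' @param radical1,radical2,radical3 [radical()] objects or preset names
#'   (flavin, superoxide, scavenger). Radical 2 has no magnetic nuclei in
#'   the default model.
#' @param k_F,k_X,k_Xp,k_E,k_Ep reaction/escape rate constants in us^-1
#'   (pairwise singlet recombinations of pairs (1,2), (1,3), (2,3) and
#'   escape of the two mobile radicals).
#' @param gamma2 random-field relaxation rate of electron 2 in us^-1.
#' @return object of class `triad_system`; `$space` orders sites as
#'   electrons 1, 2, 3 followed by nuclei of radicals 1, 2, 3.
#' @export
triad_system <- function(radical1, radical2 = "superoxide", radical3,
                         k_F = 0, k_X = 0, k_Xp = 0, k_E = 0, k_Ep = 0,
                         gamma2 = 0) {
  rads <- lapply(list(radical1, radical2, radical3), function(r) {
    if (is.character(r)) radical_preset(r) else r
  })
  rates <- c(k_F = k_F, k_X = k_X, k_Xp = k_Xp, k_E = k_E, k_Ep = k_Ep)
  if (any(rates < 0) || gamma2 < 0) {
    stop("invalid rate: all rates must be >= 0", call. = FALSE)
  }
  mult <- c(2L, 2L, 2L, unlist(lapply(rads, function(r) {
    vapply(r$nuclei, `[[`, integer(1), "multiplicity")
  })))
  if (prod(mult) > 512) {
    stop("size error: triad Hilbert dimension ", prod(mult),
         " exceeds the 512 cap", call. = FALSE)
  }
  labels <- c(paste0("e:", vapply(rads, `[[`, character(1), "label")),
              unlist(lapply(rads, nucleus_labels)))
  nsites <- lapply(rads, function(r) length(r$nuclei))
  offs <- 3L + cumsum(c(0L, unlist(nsites[-3])))
  structure(
    list(radicals = rads, rates = as.list(rates), gamma2 = gamma2,
         space = spin_space(mult, labels),
         electron_sites = 1:3,
         nucleus_sites = list(
           if (nsites[[1]]) offs[1] + seq_len(nsites[[1]]) else integer(0),
           if (nsites[[2]]) offs[2] + seq_len(nsites[[2]]) else integer(0),
           if (nsites[[3]]) offs[3] + seq_len(nsites[[3]]) else integer(0)
         )),
    class = "triad_system"
  )
}

triad_hamiltonian <- function(system, field) {
  sp <- system$space
  H <- matrix(0i, sp$dim, sp$dim)
  for (i in 1:3) {
    H <- H + zeeman_hamiltonian(system$radicals[[i]], field, sp, i) +
      hyperfine_hamiltonian(system$radicals[[i]], sp, i,
                            system$nucleus_sites[[i]])
  }
  H
}

# Haberkorn operator K of the full model:
# K = kF/2 P12 + kX/2 P13 + kXp/2 P23 + (kE/2 + kEp/2) E
triad_K <- function(system) {
  sp <- system$space
  r <- system$rates
  (r$k_F / 2) * singlet_projector(sp, 1L, 2L) +
    (r$k_X / 2) * singlet_projector(sp, 1L, 3L) +
    (r$k_Xp / 2) * singlet_projector(sp, 2L, 3L) +
    ((r$k_E + r$k_Ep) / 2) * diag(sp$dim)
}

#' Generator of the full triad equation of motion
#'
#' Returns the action rho -> -i[H, rho] - \{K, rho\} + R2(rho) as a
#' function, with the Haberkorn operator K combining the three pairwise
#' singlet recombinations and the spin-independent escape channels, and
#' random-field relaxation at rate gamma2 acting on electron 2 only.
#'
#' @param system a [triad_system()].
#' @param field numeric length-3 field vector in uT.
#' @return function mapping a density matrix to its time derivative.
#' @export
full_generator <- function(system, field) {
  H <- triad_hamiltonian(system, field)
  K <- triad_K(system)
  R <- if (system$gamma2 > 0) {
    s2 <- embedded_spin(2L, system$space)
    function(rho) {
      system$gamma2 * (s2$x %*% rho %*% s2$x + s2$y %*% rho %*% s2$y +
                         s2$z %*% rho %*% s2$z - 3 / 4 * rho)
    }
  } else {
    function(rho) 0 * rho
  }
  function(rho) {
    -1i * (H %*% rho - rho %*% H) - (K %*% rho + rho %*% K) + R(rho)
  }
}

#' Initial state of the triad
#'
#' The primary flavin/superoxide pair (1,2) is born as a spin triplet
#' (its generation from triplet molecular oxygen), a singlet, or an
#' F-pair (random encounter, maximally mixed). Electron 3 and all nuclei
#' start maximally mixed in every case. Tracing out radical 2 gives
#' identity/dim on the (1,3) space for all three conditions, which is why
#' the reduced model is insensitive to the initial spin correlation.
#'
#' @param system a [triad_system()].
#' @param condition "triplet12", "singlet12" or "fpair12".
#' @return density matrix (complex, unit trace).
#' @export
initial_triad_state <- function(system,
                                condition = c("triplet12", "singlet12",
                                              "fpair12")) {
  condition <- match.arg(condition)
  sp <- system$space
  if (condition == "fpair12") return(diag(sp$dim) / sp$dim + 0i)
  Ps <- singlet_projector(sp, 1L, 2L)
  Pr <- if (condition == "singlet12") Ps else diag(sp$dim) - Ps
  Pr / Re(sum(diag(Pr)))
}

# dense complex Liouvillian of the full generator (for resolvent solves)
triad_liouvillian <- function(system, field) {
  H <- triad_hamiltonian(system, field)
  K <- triad_K(system)
  d <- nrow(H)
  Id <- diag(d)
  L <- -1i * (Id %x% H - t(H) %x% Id) - (Id %x% K + t(K) %x% Id)
  if (system$gamma2 > 0) {
    s2 <- embedded_spin(2L, system$space)
    for (S in s2) {
      L <- L + system$gamma2 * (t(S) %x% S)
    }
    L <- L - system$gamma2 * 3 / 4 * diag(d * d)
  }
  L
}

#' Scavenging yield of the full triad model
#'
#' Phi_X = k_X * integral of Tr(P_S^(1,3) rho(t)) dt evaluated in the
#' full three-radical space, by adaptive time integration of the full
#' equation of motion (`method = "ode"`) or by a dense Liouville-space
#' resolvent solve (`method = "resolvent"`, the faster default).
#'
#' @param system a [triad_system()].
#' @param field numeric length-3 field vector in uT.
#' @param condition initial condition, see [initial_triad_state()].
#' @param method "resolvent" or "ode".
#' @return Phi_X in \[0, 1\].
#' @export
full_scavenging_yield <- function(system, field,
                                  condition = "triplet12",
                                  method = c("resolvent", "ode")) {
  full_yield_components(system, field, condition, method)$phi_X
}

#' Channel-resolved exit probabilities of the full triad model
#'
#' Integrated probabilities of every exit channel: singlet recombination
#' of pairs (1,2), (1,3), (2,3) and the spin-independent escape channels.
#' They sum to 1 (total exit probability).
#'
#' @inheritParams full_scavenging_yield
#' @return one-row tibble with `phi_F`, `phi_X`, `phi_Xp`, `phi_E`,
#'   `exit_total`.
#' @export
full_yield_components <- function(system, field, condition = "triplet12",
                                  method = c("resolvent", "ode")) {
  method <- match.arg(method)
  r <- system$rates
  exit_rate <- r$k_F + r$k_X + r$k_Xp + r$k_E + r$k_Ep
  if (exit_rate <= 0) {
    stop("divergent integral: no exit channel has positive rate",
         call. = FALSE)
  }
  sp <- system$space
  rho0 <- initial_triad_state(system, condition)
  P12 <- Re(singlet_projector(sp, 1L, 2L))
  P13 <- Re(singlet_projector(sp, 1L, 3L))
  P23 <- Re(singlet_projector(sp, 2L, 3L))
  if (method == "resolvent") {
    # X = -L^+ rho0 in the eigenbasis of the Liouvillian. Stationary modes
    # (|lambda| ~ 0) are trapped subspaces that never react: they carry no
    # flux through any exit channel and are excluded from the integral.
    L <- triad_liouvillian(system, field)
    e <- eigen(L)
    c0 <- solve(e$vectors, as.vector(rho0))
    keep <- abs(e$values) > 1e-10 * max(1, max(abs(e$values)))
    x <- e$vectors[, keep, drop = FALSE] %*%
      (c0[keep] / (-e$values[keep]))
    X <- matrix(x, sp$dim, sp$dim)
    tr <- function(A) Re(sum(A * X))  # A real symmetric: Tr(A X)
    trX <- Re(sum(diag(X)))
    out <- c(phi_F = r$k_F * tr(P12), phi_X = r$k_X * tr(P13),
             phi_Xp = r$k_Xp * tr(P23), phi_E = (r$k_E + r$k_Ep) * trX)
  } else {
    gen <- full_generator(system, field)
    d <- sp$dim
    d2 <- d * d
    deriv <- function(t, y, parms) {
      rho <- matrix(complex(real = y[seq_len(d2)],
                            imaginary = y[d2 + seq_len(d2)]), d, d)
      dr <- gen(rho)
      list(c(Re(as.vector(dr)), Im(as.vector(dr)),
             r$k_F * Re(sum(P12 * rho)), r$k_X * Re(sum(P13 * rho)),
             r$k_Xp * Re(sum(P23 * rho)),
             (r$k_E + r$k_Ep) * Re(sum(diag(rho)))))
    }
    # horizon: 20x the slowest exit timescale (pairwise channels drain at
    # most a quarter of the population per unit rate)
    t_max <- 60 / (r$k_E + r$k_Ep + (r$k_F + r$k_X + r$k_Xp) / 4)
    y0 <- c(Re(as.vector(rho0)), Im(as.vector(rho0)), 0, 0, 0, 0)
    sol <- deSolve::ode(y = y0, times = seq(0, t_max, length.out = 101),
                        func = deriv,
                        parms = NULL, rtol = 1e-10, atol = 1e-12,
                        maxsteps = 5e5)
    yT <- sol[nrow(sol), -1]
    out <- c(phi_F = unname(yT[2 * d2 + 1]), phi_X = unname(yT[2 * d2 + 2]),
             phi_Xp = unname(yT[2 * d2 + 3]), phi_E = unname(yT[2 * d2 + 4]))
  }
  tibble::tibble(phi_F = out[["phi_F"]], phi_X = out[["phi_X"]],
                 phi_Xp = out[["phi_Xp"]], phi_E = out[["phi_E"]],
                 exit_total = sum(out))
}

# reduced counterpart of a triad: same radicals 1 and 3, composite k_Sigma
reduce_triad <- function(system) {
  r <- system$rates
  reduced_pair_model(
    system$radicals[[1]], system$radicals[[3]],
    rate_set(k_X = r$k_X,
             k_F = r$k_F, k_E = r$k_E, k_Ep = r$k_Ep, k_Xp = r$k_Xp)
  )
}

#' Convergence of the full model to the reduced model
#'
#' Computes |Phi_X(full, gamma2) - Phi_X(reduced)| along an increasing
#' ladder of superoxide relaxation rates. As gamma2 grows the full triad
#' loses all memory of the superoxide spin and the discrepancy falls;
#' this is the numerical verification that the k_F/4 and k_Xp/4 terms of
#' the composite rate emerge in the fast-relaxation limit. With gamma2 =
#' 0 the reduction is *not* valid and initial conditions matter (negative
#' control).
#'
#' @param system a [triad_system()] (its `gamma2` is overridden by the
#'   ladder).
#' @param field numeric length-3 field vector in uT.
#' @param gamma2_ladder increasing relaxation rates in us^-1.
#' @param condition initial condition of the full model.
#' @return tibble of class `reduction_report` with columns `gamma2`,
#'   `phi_full`, `phi_reduced`, `discrepancy`, and attribute `converged`
#'   (discrepancy < 1e-2 at the ladder top).
#' @export
reduction_convergence <- function(system, field,
                                  gamma2_ladder = c(10, 100, 1000),
                                  condition = "triplet12") {
  stopifnot(all(diff(gamma2_ladder) > 0))
  reduced <- reduce_triad(system)
  phi_red <- scavenging_yield(reduced, field)
  rows <- purrr::map_dfr(gamma2_ladder, function(g2) {
    sys_g <- system
    sys_g$gamma2 <- g2
    phi_full <- full_scavenging_yield(sys_g, field, condition)
    tibble::tibble(gamma2 = g2, phi_full = phi_full,
                   phi_reduced = phi_red,
                   discrepancy = abs(phi_full - phi_red))
  })
  attr(rows, "converged") <- rows$discrepancy[nrow(rows)] < 1e-2
  class(rows) <- c("reduction_report", class(rows))
  rows
}
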
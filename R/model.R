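#' Reaction rate set of the reduced two-radical model
#'
#' The reduced model has two kinetic parameters: the spin-selective
#' scavenging rate `k_X` (singlet recombination of the flavin/ascorbyl
#' pair) and the spin-independent composite depopulation rate `k_Sigma`,
#' which subsumes every other exit channel of the triad:
#' `k_Sigma = k_E + k_Ep + k_F / 4 + k_Xp / 4`.
#' The factors 1/4 arise because the fast-relaxing superoxide leaves its
#' pairings with the other radicals in effectively random (1/4 singlet)
#' spin states. `phi` is the probability that the processes in `k_Sigma`
#' release superoxide; the default 0 describes efficient oxidation, for
#' which superoxide is only released by productive scavenging of the
#' flavin radical.
#'
#' Supply either `k_Sigma` (aggregate form) or the components `k_F`,
#' `k_E`, `k_Ep`, `k_Xp`. Giving both is accepted only when consistent to
#' 1e-9.
#'
#' @param k_X scavenging (flavin/ascorbyl singlet recombination) rate,
#'   us^-1.
#' @param k_Sigma composite depopulation rate, us^-1.
#' @param k_F flavin/superoxide singlet recombination rate, us^-1.
#' @param k_E,k_Ep escape rates of ascorbyl and superoxide, us^-1.
#' @param k_Xp superoxide/ascorbyl singlet recombination rate, us^-1.
#' @param phi probability in \[0, 1\] that k_Sigma processes release
#'   superoxide.
#' @return object of class `rate_set` with fields `k_X`, `k_Sigma`, `phi`
#'   and, when given, the components.
#' @examples
#' rate_set(k_X = 1, k_F = 4, k_E = 1, k_Ep = 2, k_Xp = 8) # k_Sigma = 6
#' @export
rate_set <- function(k_X, k_Sigma = NULL, k_F = NULL, k_E = NULL,
                     k_Ep = NULL, k_Xp = NULL, phi = 0) {
  comp <- list(k_F = k_F, k_E = k_E, k_Ep = k_Ep, k_Xp = k_Xp)
  have_comp <- !all(vapply(comp, is.null, logical(1)))
  if (have_comp) comp <- lapply(comp, function(x) x %||% 0)
  rates <- c(list(k_X = k_X), if (have_comp) comp,
             if (!is.null(k_Sigma)) list(k_Sigma = k_Sigma))
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("invalid rate: ", nm, " must be a finite number >= 0",
           call. = FALSE)
    }
  }
  if (!is.numeric(phi) || phi < 0 || phi > 1) {
    stop("phi must lie in [0, 1]", call. = FALSE)
  }
  if (have_comp) {
    k_Sigma_comp <- comp$k_E + comp$k_Ep + comp$k_F / 4 + comp$k_Xp / 4
    if (!is.null(k_Sigma) && abs(k_Sigma - k_Sigma_comp) > 1e-9) {
      stop("inconsistent rates: k_Sigma disagrees with its components",
           call. = FALSE)
    }
    k_Sigma <- k_Sigma_comp
  }
  if (is.null(k_Sigma)) {
    stop("supply k_Sigma or its components", call. = FALSE)
  }
  structure(c(list(k_X = k_X, k_Sigma = k_Sigma, phi = phi),
              if (have_comp) comp),
            class = "rate_set")
}

#' Reduced two-radical pair model
#'
#' The working model of the package: the flavin semiquinone (radical 1)
#' and the scavenger radical (radical 3, ascorbyl by default) evolving
#' under their Zeeman and hyperfine interactions, with Haberkorn
#' scavenging at `k_X` through the singlet projector of the pair and
#' uniform depopulation at `k_Sigma`. The fast-relaxing superoxide
#' (radical 2) has been traced out; its only traces are the 1/4 factors
#' inside `k_Sigma` and the maximally mixed initial state.
#'
#' @param radical1 flavin-side [radical()] or preset name.
#' @param radical3 scavenger [radical()] or preset name.
#' @param rates a [rate_set()].
#' @param gamma1,gamma3 optional random-field relaxation rates (us^-1) of
#'   electrons 1 and 3.
#' @return object of class `reduced_pair_model`. The composite
#'   [spin_space()] (electron 1, electron 3, nuclei of radical 1, nuclei
#'   of radical 3) is in `$space`; electron sites are 1 and 2.
#' @examples
#' m <- reduced_pair_model("flavin_3N", "ascorbyl_H4",
#'                         rate_set(k_X = 1, k_Sigma = 0.1))
#' m$space$dim # 144
#' @export
reduced_pair_model <- function(radical1, radical3, rates,
                               gamma1 = 0, gamma3 = 0) {
  if (is.character(radical1)) radical1 <- radical_preset(radical1)
  if (is.character(radical3)) radical3 <- radical_preset(radical3)
  stopifnot(inherits(radical1, "radical"), inherits(radical3, "radical"),
            inherits(rates, "rate_set"))
  if (gamma1 < 0 || gamma3 < 0) {
    stop("relaxation rates must be >= 0", call. = FALSE)
  }
  mult <- c(2L, 2L,
            vapply(radical1$nuclei, `[[`, integer(1), "multiplicity"),
            vapply(radical3$nuclei, `[[`, integer(1), "multiplicity"))
  labels <- c(paste0("e:", radical1$label), paste0("e:", radical3$label),
              nucleus_labels(radical1), nucleus_labels(radical3))
  space <- spin_space(mult, labels)
  structure(
    list(radical1 = radical1, radical3 = radical3, rates = rates,
         gamma1 = gamma1, gamma3 = gamma3, space = space,
         electron_sites = c(1L, 2L),
         nucleus_sites = list(
           radical1 = if (length(radical1$nuclei)) 2L + seq_along(radical1$nuclei) else integer(0),
           radical3 = if (length(radical3$nuclei)) 2L + length(radical1$nuclei) + seq_along(radical3$nuclei) else integer(0)
         )),
    class = "reduced_pair_model"
  )
}

#' @export
print.reduced_pair_model <- function(x, ...) {
  cat("<reduced_pair_model> dim", x$space$dim, "\n")
  cat(sprintf("  k_X = %g, k_Sigma = %g us^-1, phi = %g\n",
              x$rates$k_X, x$rates$k_Sigma, x$rates$phi))
  if (x$gamma1 > 0 || x$gamma3 > 0) {
    cat(sprintf("  relaxation gamma1 = %g, gamma3 = %g us^-1\n",
                x$gamma1, x$gamma3))
  }
  print(x$radical1); print(x$radical3)
  invisible(x)
}

#' Zeeman Hamiltonian of one radical's electron
#'
#' omega . S with omega = g mu_B B / hbar, embedded at `site` in `space`.
#' Returned in rad/us.
#'
#' @param radical a [radical()] (supplies the g-factor).
#' @param field numeric length-3 field vector in uT.
#' @param space composite [spin_space()].
#' @param site electron site index.
#' @return Hermitian complex matrix, rad/us.
#' @export
zeeman_hamiltonian <- function(radical, field, space, site) {
  stopifnot(length(field) == 3, all(is.finite(field)))
  omega <- gyromagnetic_ratio(radical$g_factor) * field
  s <- embedded_spin(site, space)
  omega[1] * s$x + omega[2] * s$y + omega[3] * s$z
}

#' Hyperfine Hamiltonian of one radical
#'
#' Sum over the radical's nuclei of S . A_j . I_j in rad/us, with the
#' electron at `electron_site` and nucleus j at `nucleus_sites[j]`. For a
#' `free` radical each tensor is replaced by its isotropic part
#' (rotational averaging); a `bound` radical keeps the full tensor.
#'
#' @param radical a [radical()].
#' @param space composite [spin_space()].
#' @param electron_site electron site index.
#' @param nucleus_sites integer vector of the radical's nucleus sites, in
#'   the order of `radical$nuclei`.
#' @return Hermitian complex matrix, rad/us.
#' @export
hyperfine_hamiltonian <- function(radical, space, electron_site,
                                  nucleus_sites) {
  d <- space$dim
  H <- matrix(0i, d, d)
  if (length(radical$nuclei) == 0) return(H)
  stopifnot(length(nucleus_sites) == length(radical$nuclei))
  s <- embedded_spin(electron_site, space)
  s <- list(s$x, s$y, s$z)
  for (j in seq_along(radical$nuclei)) {
    nuc <- radical$nuclei[[j]]
    A <- nuc$tensor$matrix
    if (radical$mobility == "free") A <- diag(3) * isotropic_part(nuc$tensor)
    A <- A * MHZ_TO_ANGULAR
    iops <- embedded_spin(nucleus_sites[j], space)
    iops <- list(iops$x, iops$y, iops$z)
    for (a in 1:3) for (b in 1:3) {
      if (A[a, b] != 0) H <- H + A[a, b] * (s[[a]] %*% iops[[b]])
    }
  }
  H
}

#' Coherent Hamiltonian of the reduced model
#'
#' H' = H_1 + H_3: Zeeman plus hyperfine terms of radicals 1 and 3 on the
#' composite space, in rad/us.
#'
#' @param model a [reduced_pair_model()].
#' @param field numeric length-3 field vector in uT.
#' @return Hermitian complex matrix of dimension `model$space$dim`.
#' @export
reduced_hamiltonian <- function(model, field) {
  sp <- model$space
  zeeman_hamiltonian(model$radical1, field, sp, 1L) +
    zeeman_hamiltonian(model$radical3, field, sp, 2L) +
    hyperfine_hamiltonian(model$radical1, sp, 1L,
                          model$nucleus_sites$radical1) +
    hyperfine_hamiltonian(model$radical3, sp, 2L,
                          model$nucleus_sites$radical3)
}

#' Reduced Haberkorn reaction superoperator
#'
#' Returns the action sigma -> -(k_X/2) \{P_S, sigma\} - k_Sigma sigma as
#' a function of a density matrix. The anticommutator term removes
#' singlet population of the (1,3) pair at `k_X`; the scalar term removes
#' population uniformly at `k_Sigma`. Consequently
#' d Tr(sigma)/dt = -k_X Tr(P_S sigma) - k_Sigma Tr(sigma).
#'
#' @param model a [reduced_pair_model()].
#' @return function taking and returning a complex matrix.
#' @export
haberkorn_reduced <- function(model) {
  P <- singlet_projector(model$space, 1L, 2L)
  kX <- model$rates$k_X
  kS <- model$rates$k_Sigma
  function(sigma) {
    -(kX / 2) * (P %*% sigma + sigma %*% P) - kS * sigma
  }
}

#' Random-field electron spin relaxation superoperator
#'
#' Isotropic single-electron depolarization implemented as a Lindblad
#' dissipator with jump operators sqrt(gamma) * S_x, S_y, S_z, applied to
#' electron spins only. The normalization makes the longitudinal and
#' transverse relaxation rates both equal to gamma (T1 = T2 = 1/gamma);
#' the map is trace preserving and drives each electron toward its
#' maximally mixed state.
#'
#' @param gamma1,gamma3 relaxation rates (us^-1) of electrons 1 and 3.
#' @param space composite [spin_space()].
#' @param electron_sites indices of the two electron sites (default 1:2).
#' @return function taking and returning a complex matrix; the zero map
#'   when both rates are 0.
#' @export
random_field_relaxation <- function(gamma1, gamma3, space,
                                    electron_sites = c(1L, 2L)) {
  if (gamma1 < 0 || gamma3 < 0) {
    stop("relaxation rates must be >= 0", call. = FALSE)
  }
  gammas <- c(gamma1, gamma3)
  ops <- list()
  for (k in 1:2) {
    if (gammas[k] > 0) {
      s <- embedded_spin(electron_sites[k], space)
      ops <- c(ops, lapply(s, function(S) list(g = gammas[k], S = S)))
    }
  }
  if (length(ops) == 0) {
    return(function(sigma) 0 * sigma)
  }
  function(sigma) {
    out <- 0 * sigma
    for (o in ops) {
      # D(sigma) = g (S sigma S - 1/2 {S^2, sigma}); S^2 = 1/4 identity
      out <- out + o$g * (o$S %*% sigma %*% o$S - sigma / 4)
    }
    out
  }
}

#' Maximally mixed initial state
#'
#' identity/dim: the initial condition of the reduced model, obtained by
#' tracing the fast-relaxing superoxide out of the triad. It takes the
#' same form whether the primary flavin/superoxide pair was born as
#' triplet, singlet or F-pair, so reduced-model yields are independent of
#' the initial spin correlation of that pair. Its singlet population is
#' Tr(P_S sigma(0)) = 1/4.
#'
#' @param space a [spin_space()].
#' @return complex matrix identity/dim with unit trace.
#' @export
initial_state <- function(space) {
  diag(space$dim) / space$dim + 0i
}

# Right-hand side of the reduced master equation as a closure:
# dsigma/dt = -i[H, sigma] + K'(sigma) + R'(sigma)
reduced_rhs <- function(model, field) {
  H <- reduced_hamiltonian(model, field)
  K <- haberkorn_reduced(model)
  R <- random_field_relaxation(model$gamma1, model$gamma3, model$space)
  function(sigma) {
    -1i * (H %*% sigma - sigma %*% H) + K(sigma) + R(sigma)
  }
}
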
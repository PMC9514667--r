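#' Field condition: magnitude plus direction or averaging policy
#'
#' @param magnitude field strength in uT (>= 0).
#' @param direction unit 3-vector, or `"average"` for orientation
#'   averaging over the unit sphere, or `"auto"` (default): average when
#'   the model contains a bound radical, +z otherwise.
#' @return object of class `field_condition`.
#' @export
field_condition <- function(magnitude, direction = "auto") {
  if (!is.finite(magnitude) || magnitude < 0) {
    stop("invalid field: magnitude must be finite and >= 0", call. = FALSE)
  }
  if (is.numeric(direction)) {
    stopifnot(length(direction) == 3)
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) stop("direction must be a nonzero vector", call. = FALSE)
    direction <- direction / nrm
  } else {
    direction <- match.arg(direction, c("auto", "average"))
  }
  structure(list(magnitude = magnitude, direction = direction),
            class = "field_condition")
}

as_field_condition <- function(field) {
  if (inherits(field, "field_condition")) return(field)
  if (is.numeric(field) && length(field) == 1) return(field_condition(field))
  if (is.numeric(field) && length(field) == 3) {
    mag <- sqrt(sum(field^2))
    if (mag == 0) return(field_condition(0))
    return(field_condition(mag, field / mag))
  }
  stop("field must be a magnitude, a 3-vector or a field_condition",
       call. = FALSE)
}

model_is_anisotropic <- function(model) {
  any(vapply(list(model$radical1, model$radical3), function(r) {
    r$mobility == "bound" && length(r$nuclei) > 0
  }, logical(1)))
}

# Resolve a field condition into a list of field vectors (uT) to average
# over, given the model's anisotropy and the quadrature size.
field_vectors_for <- function(model, field, n_directions) {
  fc <- as_field_condition(field)
  dirn <- fc$direction
  if (identical(dirn, "auto")) {
    dirn <- if (model_is_anisotropic(model)) "average" else c(0, 0, 1)
  }
  if (identical(dirn, "average")) {
    if (!model_is_anisotropic(model)) {
      # isotropic model: any single orientation equals the average
      return(list(policy = "single", vecs = list(fc$magnitude * c(0, 0, 1))))
    }
    if (n_directions < 6) {
      warning("orientation quadrature with < 6 nodes is unreliable",
              call. = FALSE)
    }
    dirs <- fibonacci_sphere(n_directions)
    return(list(policy = "average",
                vecs = lapply(seq_len(nrow(dirs)),
                              function(i) fc$magnitude * dirs[i, ])))
  }
  list(policy = "single", vecs = list(fc$magnitude * dirn))
}

# --- algebraic (resolvent) path, gamma = 0 -------------------------------
#
# With A = H - i (k_X/2) P_S, sigma(t) = exp(-k_Sigma t) exp(-iAt) sigma0
# exp(iA^H t). Eigendecomposing A = V Lambda V^-1 turns the yield integral
# into a double sum with denominators k_Sigma + i(lambda_j - conj(lambda_k)),
# so k_Sigma enters only as a uniform shift and the eigendecomposition is
# reused across a whole k_Sigma grid axis.
yield_kernel <- function(H, P, k_X) {
  d <- nrow(H)
  A <- H - (1i * k_X / 2) * P
  e <- eigen(A)
  V <- e$vectors
  lam <- e$values
  Vh <- Conj(t(V))
  M <- solve(Vh %*% V) / d      # V^-1 sigma0 V^-H with sigma0 = I/d
  WN <- M * t(Vh %*% P %*% V)   # (j,k) term of the singlet-trace sum
  WT <- M * t(Vh %*% V)         # (j,k) term of the total-trace sum
  G <- 1i * outer(lam, Conj(lam), `-`)
  safe_sum <- function(W, D) {
    r <- W / D
    r[abs(W) < 1e-30] <- 0  # decoupled modes: numerator vanishes first
    sum(r)
  }
  function(k_Sigma) {
    D <- k_Sigma + G
    c(phi_X = Re(k_X * safe_sum(WN, D)),
      trace_integral = Re(safe_sum(WT, D)))
  }
}

# --- algebraic path, gamma > 0: Liouville-space linear solve -------------

# Sparse real-block Liouvillian for d sigma/dt = L sigma (column-major vec).
liouvillian_sparse <- function(H, P, k_X, k_Sigma, relax) {
  d <- nrow(H)
  Id <- Matrix::Diagonal(d)
  Hr <- Matrix::Matrix(Re(H), sparse = TRUE)
  Hi <- Matrix::Matrix(Im(H), sparse = TRUE)
  Ps <- Matrix::Matrix(Re(P), sparse = TRUE)
  # -i[H, .]: C = I x H - t(H) x I (complex); contributes Im(C) to the real
  # part and -Re(C) to the imaginary part of L
  C_re <- Matrix::kronecker(Id, Hr) - Matrix::kronecker(Matrix::t(Hr), Id)
  C_im <- Matrix::kronecker(Id, Hi) + Matrix::kronecker(Hi, Id)
  L_re <- C_im -
    (k_X / 2) * (Matrix::kronecker(Id, Ps) + Matrix::kronecker(Ps, Id)) -
    k_Sigma * Matrix::Diagonal(d * d)
  L_im <- -C_re
  for (rl in relax) { # rl: list(g, S = embedded spin ops)
    for (S in rl$S) {
      St <- t(S)
      term_re <- Matrix::kronecker(Matrix::Matrix(Re(St), sparse = TRUE),
                                   Matrix::Matrix(Re(S), sparse = TRUE)) -
        Matrix::kronecker(Matrix::Matrix(Im(St), sparse = TRUE),
                          Matrix::Matrix(Im(S), sparse = TRUE))
      term_im <- Matrix::kronecker(Matrix::Matrix(Re(St), sparse = TRUE),
                                   Matrix::Matrix(Im(S), sparse = TRUE)) +
        Matrix::kronecker(Matrix::Matrix(Im(St), sparse = TRUE),
                          Matrix::Matrix(Re(S), sparse = TRUE))
      L_re <- L_re + rl$g * (term_re - Matrix::Diagonal(d * d) / 4)
      L_im <- L_im + rl$g * term_im
    }
  }
  list(re = L_re, im = L_im)
}

# Solve L vec(X) = -vec(sigma0) for X = int_0^inf sigma dt.
yield_linsolve <- function(H, P, k_X, k_Sigma, relax, sigma0) {
  d <- nrow(H)
  L <- liouvillian_sparse(H, P, k_X, k_Sigma, relax)
  A <- rbind(cbind(L$re, -L$im), cbind(L$im, L$re))
  b <- c(-Re(as.vector(sigma0)), -Im(as.vector(sigma0)))
  x <- Matrix::solve(A, b)
  X <- matrix(complex(real = x[seq_len(d * d)],
                      imaginary = x[d * d + seq_len(d * d)]), d, d)
  c(phi_X = Re(k_X * sum(Re(P) * X)),
    trace_integral = Re(sum(diag(X))))
}

relax_ops <- function(model) {
  relax <- list()
  gam <- c(model$gamma1, model$gamma3)
  for (k in 1:2) {
    if (gam[k] > 0) {
      relax[[length(relax) + 1]] <-
        list(g = gam[k], S = embedded_spin(model$electron_sites[k],
                                           model$space))
    }
  }
  relax
}

# --- ODE oracle ----------------------------------------------------------

# Time integration of the reduced master equation with accumulated yield
# integrals as auxiliary states. Horizon 20 / (k_X/4 + k_Sigma), extended
# (up to 3 doublings) until the residual trace falls below `tail_tol`.
ode_yield <- function(model, field_vec, rtol = 1e-10, atol = 1e-12,
                      tail_tol = 1e-7, horizon_factor = 20) {
  kX <- model$rates$k_X
  kS <- model$rates$k_Sigma
  if (kX + kS <= 0) {
    stop("divergence: k_X + k_Sigma must be > 0", call. = FALSE)
  }
  d <- model$space$dim
  d2 <- d * d
  rhs <- reduced_rhs(model, field_vec)
  P <- Re(singlet_projector(model$space, 1L, 2L))
  sigma0 <- initial_state(model$space)
  y0 <- c(Re(as.vector(sigma0)), Im(as.vector(sigma0)), 0, 0)
  deriv <- function(t, y, parms) {
    sig <- matrix(complex(real = y[seq_len(d2)],
                          imaginary = y[d2 + seq_len(d2)]), d, d)
    ds <- rhs(sig)
    list(c(Re(as.vector(ds)), Im(as.vector(ds)),
           kX * Re(sum(P * sig)), Re(sum(diag(sig)))))
  }
  # the uniform k_Sigma channel drains the trace at least at rate k_Sigma,
  # while singlet-only decay can be mixing-limited; take the shorter of the
  # two horizon estimates, then extend until the residual trace (an upper
  # bound on the truncated yield contribution) is negligible
  t_max <- horizon_factor / (kX / 4 + kS)
  if (kS > 0) t_max <- max(t_max, -log(tail_tol / 10) / kS / 32)
  for (attempt in 0:5) {
    sol <- deSolve::ode(y = y0,
                        times = seq(0, t_max * 2^attempt, length.out = 101),
                        func = deriv, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 5e5)
    yT <- sol[nrow(sol), -1]
    tail_mass <- sum(Re(yT[seq_len(d2)][seq(1, d2, by = d + 1)]))
    if (tail_mass < tail_tol) {
      return(c(phi_X = unname(yT[2 * d2 + 1]),
               trace_integral = unname(yT[2 * d2 + 2]),
               tail_mass = tail_mass))
    }
  }
  stop("horizon error: residual trace ", signif(tail_mass, 3),
       " after t = ", signif(t_max * 32, 3), " us", call. = FALSE)
}

# --- user-facing yield functions ----------------------------------------

#' Singlet scavenging quantum yield Phi_X
#'
#' Phi_X = k_X * integral of Tr(P_S sigma(t)) dt over the reaction: the
#' probability that the flavin semiquinone recombines with the scavenger
#' radical through their singlet channel. `method = "algebraic"` solves
#' the stationary linear problem (eigendecomposition of the effective
#' non-Hermitian generator when no relaxation is present, a sparse
#' Liouville-space linear solve otherwise); `method = "ode"` integrates
#' the master equation in time and serves as an independent oracle.
#'
#' For a model containing a bound (anisotropic) radical and a field
#' condition with direction `"auto"` or `"average"`, the yield is
#' averaged over `n_directions` field orientations.
#'
#' @param model a [reduced_pair_model()].
#' @param field magnitude in uT, a 3-vector in uT, or a
#'   [field_condition()].
#' @param method "algebraic" or "ode".
#' @param n_directions orientation quadrature size (default 72).
#' @return Phi_X in \[0, 1\].
#' @examples
#' m <- reduced_pair_model("superoxide", "superoxide",
#'                         rate_set(k_X = 1, k_Sigma = 1))
#' scavenging_yield(m, 50) # closed form: 1/4 * 1 / 2 = 0.125
#' @export
scavenging_yield <- function(model, field, method = c("algebraic", "ode"),
                             n_directions = 72) {
  unname(yield_components(model, field, method, n_directions)$phi_X)
}

#' Yield components: Phi_X and the total-trace integral
#'
#' Returns both Phi_X and `trace_integral` = integral of Tr(sigma) dt,
#' whose combination obeys the exit-probability ledger
#' `phi_X + k_Sigma * trace_integral = 1` (every trajectory eventually
#' leaves through the singlet channel or a k_Sigma channel).
#'
#' @inheritParams scavenging_yield
#' @return one-row tibble with `phi_X`, `trace_integral`, `exit_total`.
#' @export
yield_components <- function(model, field, method = c("algebraic", "ode"),
                             n_directions = 72) {
  method <- match.arg(method)
  kX <- model$rates$k_X
  kS <- model$rates$k_Sigma
  if (kX + kS <= 0) {
    stop("divergence: k_X + k_Sigma must be > 0", call. = FALSE)
  }
  fv <- field_vectors_for(model, field, n_directions)
  P <- singlet_projector(model$space, 1L, 2L)
  has_relax <- model$gamma1 > 0 || model$gamma3 > 0
  acc <- c(phi_X = 0, trace_integral = 0)
  for (vec in fv$vecs) {
    if (method == "ode") {
      r <- ode_yield(model, vec)[c("phi_X", "trace_integral")]
    } else if (!has_relax) {
      H <- reduced_hamiltonian(model, vec)
      r <- yield_kernel(H, P, kX)(kS)
    } else {
      H <- reduced_hamiltonian(model, vec)
      r <- yield_linsolve(H, P, kX, kS, relax_ops(model),
                          initial_state(model$space))
    }
    acc <- acc + r
  }
  acc <- acc / length(fv$vecs)
  tibble::tibble(phi_X = acc[["phi_X"]],
                 trace_integral = acc[["trace_integral"]],
                 exit_total = acc[["phi_X"]] + kS * acc[["trace_integral"]])
}

#' Superoxide escape quantum yield
#'
#' Y = (1 - phi) * Phi_X + phi, where phi is the probability that the
#' k_Sigma processes release superoxide. With phi = 0, Y equals the
#' scavenging yield Phi_X.
#'
#' @param phi_X singlet scavenging yield in \[0, 1\].
#' @param phi branching probability in \[0, 1\].
#' @return Y in \[0, 1\].
#' @export
superoxide_yield <- function(phi_X, phi = 0) {
  if (any(phi_X < -1e-12 | phi_X > 1 + 1e-12) || phi < 0 || phi > 1) {
    stop("domain error: phi_X and phi must lie in [0, 1]", call. = FALSE)
  }
  (1 - phi) * phi_X + phi
}

#' Magnetic field effect ratio chi(B)
#'
#' chi(B) = Y(B) / Y(B_ref): the superoxide yield at field B relative to
#' the reference condition (the geomagnetic field, by default). The
#' signed percentage effect 100 * (chi - 1) is attached as attribute
#' `effect_pct`.
#'
#' @param model a [reduced_pair_model()].
#' @param B field (magnitude, 3-vector or [field_condition()]).
#' @param B_ref reference field; default `GMF_uT`.
#' @param ... passed to [scavenging_yield()].
#' @return chi as a numeric scalar with attribute `effect_pct`.
#' @export
mfe_ratio <- function(model, B, B_ref = GMF_uT, ...) {
  phi <- model$rates$phi
  Y <- superoxide_yield(scavenging_yield(model, B, ...), phi)
  Y_ref <- superoxide_yield(scavenging_yield(model, B_ref, ...), phi)
  if (Y_ref <= 0) {
    stop("division error: reference yield is zero", call. = FALSE)
  }
  chi <- Y / Y_ref
  attr(chi, "effect_pct") <- 100 * (chi - 1)
  chi
}

#' Orientation-averaged scavenging yield
#'
#' Mean of Phi_X over near-uniform field directions on the unit sphere
#' (Fibonacci point set), for models whose bound radical makes the spin
#' dynamics orientation dependent. For a fully isotropic model the
#' average equals any single orientation and one evaluation is performed.
#'
#' @param model a [reduced_pair_model()].
#' @param magnitude field strength in uT.
#' @param n_directions quadrature size (default 72; < 6 warns).
#' @param method passed to [scavenging_yield()].
#' @return averaged Phi_X.
#' @export
orientation_average <- function(model, magnitude, n_directions = 72,
                                method = "algebraic") {
  scavenging_yield(model, field_condition(magnitude, "average"),
                   method = method, n_directions = n_directions)
}

#' Magnetically affected reaction yield (MARY) curve
#'
#' Phi_X, Y and chi as a function of applied field strength, relative to
#' a reference field.
#'
#' @param model a [reduced_pair_model()].
#' @param B_values numeric vector of field magnitudes in uT.
#' @param reference reference magnitude in uT (default `GMF_uT`).
#' @param n_directions orientation quadrature size for bound radicals.
#' @param method passed to [scavenging_yield()].
#' @return tibble of class `mary_curve` with columns `B_uT`, `phi_X`,
#'   `Y`, `chi`, `effect_pct`, `orientation_policy`.
#' @export
field_sweep <- function(model, B_values, reference = GMF_uT,
                        n_directions = 72, method = "algebraic") {
  stopifnot(all(B_values >= 0))
  phi <- model$rates$phi
  policy <- if (model_is_anisotropic(model)) "average" else "single"
  phiX <- vapply(B_values, function(B) {
    scavenging_yield(model, B, method = method, n_directions = n_directions)
  }, numeric(1))
  phiX_ref <- scavenging_yield(model, reference, method = method,
                               n_directions = n_directions)
  Y <- superoxide_yield(phiX, phi)
  Y_ref <- superoxide_yield(phiX_ref, phi)
  out <- tibble::tibble(
    B_uT = B_values, phi_X = phiX, Y = Y, chi = Y / Y_ref,
    effect_pct = 100 * (Y / Y_ref - 1), orientation_policy = policy
  )
  attr(out, "reference_uT") <- reference
  attr(out, "phi_X_ref") <- phiX_ref
  class(out) <- c("mary_curve", class(out))
  out
}

#' Rate map: chi and Phi_X over a (k_X, k_Sigma) grid
#'
#' Evaluates the hypomagnetic-versus-geomagnetic yield ratio over grids
#' of the scavenging rate constant k_X and the composite depopulation
#' rate k_Sigma. For relaxation-free models the eigendecomposition of the
#' effective generator is reused across the whole k_Sigma axis.
#'
#' @param model a [reduced_pair_model()] (its k_X/k_Sigma are overridden
#'   by the grids; phi and relaxation rates are respected).
#' @param kX_grid,kSigma_grid positive rate grids in us^-1.
#' @param B probe field magnitude in uT (default `HMF_uT`).
#' @param B_ref reference field magnitude in uT (default `GMF_uT`).
#' @param n_directions orientation quadrature size for bound radicals.
#' @return tibble of class `rate_map` with columns `k_X`, `k_Sigma`,
#'   `phi_X`, `phi_X_ref`, `Y`, `Y_ref`, `chi`, `effect_pct`.
#' @export
rate_map <- function(model, kX_grid = log_grid(1e-2, 1e3),
                     kSigma_grid = log_grid(1e-2, 1e2),
                     B = HMF_uT, B_ref = GMF_uT, n_directions = 72) {
  stopifnot(all(kX_grid > 0), all(kSigma_grid > 0))
  phi <- model$rates$phi
  has_relax <- model$gamma1 > 0 || model$gamma3 > 0
  P <- singlet_projector(model$space, 1L, 2L)
  fv_B <- field_vectors_for(model, B, n_directions)
  fv_ref <- field_vectors_for(model, B_ref, n_directions)
  phiX_for <- function(fv) {
    acc <- matrix(0, length(kX_grid), length(kSigma_grid))
    for (vec in fv$vecs) {
      H <- reduced_hamiltonian(model, vec)
      for (i in seq_along(kX_grid)) {
        if (!has_relax) {
          kern <- yield_kernel(H, P, kX_grid[i])
          for (j in seq_along(kSigma_grid)) {
            acc[i, j] <- acc[i, j] + kern(kSigma_grid[j])[["phi_X"]]
          }
        } else {
          for (j in seq_along(kSigma_grid)) {
            acc[i, j] <- acc[i, j] +
              yield_linsolve(H, P, kX_grid[i], kSigma_grid[j],
                             relax_ops(model),
                             initial_state(model$space))[["phi_X"]]
          }
        }
      }
    }
    acc / length(fv$vecs)
  }
  phiX <- phiX_for(fv_B)
  phiX_ref <- phiX_for(fv_ref)
  Y <- superoxide_yield(pmin(pmax(phiX, 0), 1), phi)
  Y_ref <- superoxide_yield(pmin(pmax(phiX_ref, 0), 1), phi)
  out <- tibble::tibble(
    k_X = rep(kX_grid, times = length(kSigma_grid)),
    k_Sigma = rep(kSigma_grid, each = length(kX_grid)),
    phi_X = as.vector(phiX), phi_X_ref = as.vector(phiX_ref),
    Y = as.vector(Y), Y_ref = as.vector(Y_ref),
    chi = as.vector(Y / Y_ref),
    effect_pct = 100 * (as.vector(Y / Y_ref) - 1)
  )
  attr(out, "B_uT") <- as_field_condition(B)$magnitude
  attr(out, "B_ref_uT") <- as_field_condition(B_ref)$magnitude
  attr(out, "orientation_policy") <- fv_B$policy
  class(out) <- c("rate_map", class(out))
  out
}

#' Logarithmically spaced grid
#'
#' @param from,to positive endpoints.
#' @param points_per_decade grid density (default 10).
#' @return numeric vector including both endpoints' decades.
#' @export
log_grid <- function(from, to, points_per_decade = 10) {
  stopifnot(from > 0, to > from)
  n <- round(log10(to / from) * points_per_decade)
  10^seq(log10(from), log10(to), length.out = n + 1)
}

#' Most negative magnetic field effect of a rate map
#'
#' Returns the row of the map with the most negative signed effect
#' (ties broken by the lexicographically smallest (k_X, k_Sigma)).
#'
#' @param map a [rate_map()] result.
#' @return one-row tibble.
#' @export
max_mfe <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  ord <- order(map$effect_pct, map$k_X, map$k_Sigma)
  map[ord[1], ]
}

#' Field strength producing a target yield change
#'
#' Inverse problem on the MARY curve: finds B such that
#' |100 * (Phi_X(B) / Phi_X(B_ref) - 1)| equals `target_effect`, by
#' bracketed root finding to about 1 percent relative tolerance. The
#' magnitude of the effect must be monotone across the bracket, which is
#' validated by sampling.
#'
#' @param model a [reduced_pair_model()].
#' @param target_effect target absolute effect in percent (>= 0).
#' @param B_ref reference magnitude in uT.
#' @param bracket length-2 numeric search interval in uT.
#' @param n_directions orientation quadrature size.
#' @return field magnitude in uT.
#' @export
field_for_effect <- function(model, target_effect, B_ref = 0,
                             bracket = c(0.5, 50), n_directions = 72) {
  stopifnot(target_effect >= 0, length(bracket) == 2, bracket[1] < bracket[2])
  if (target_effect == 0) return(B_ref)
  phiX_ref <- scavenging_yield(model, B_ref, n_directions = n_directions)
  eff <- function(B) {
    abs(100 * (scavenging_yield(model, B, n_directions = n_directions) /
                 phiX_ref - 1))
  }
  probe <- seq(bracket[1], bracket[2], length.out = 7)
  ev <- vapply(probe, eff, numeric(1))
  mono_up <- all(diff(ev) >= -1e-6 * max(ev))
  mono_dn <- all(diff(ev) <= 1e-6 * max(ev))
  if (!mono_up && !mono_dn) {
    stop("effect magnitude is not monotone across the bracket", call. = FALSE)
  }
  f <- function(B) eff(B) - target_effect
  if (f(bracket[1]) * f(bracket[2]) > 0) {
    stop("bracketing error: no sign change across the bracket",
         call. = FALSE)
  }
  stats::uniroot(f, interval = bracket,
                 tol = 0.005 * bracket[2])$root
}

#' Replace the rates of a model
#'
#' Convenience for scanning rate constants: returns the model with a new
#' [rate_set()] (or new k_X / k_Sigma values), everything else unchanged.
#'
#' @param model a [reduced_pair_model()].
#' @param k_X,k_Sigma,phi replacement values (NULL keeps the current one).
#' @return modified model.
#' @export
update_rates <- function(model, k_X = NULL, k_Sigma = NULL, phi = NULL) {
  r <- model$rates
  model$rates <- rate_set(k_X = k_X %||% r$k_X,
                          k_Sigma = k_Sigma %||% r$k_Sigma,
                          phi = phi %||% r$phi)
  model
}
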
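#' Cartesian angular-momentum operators for a spin of given multiplicity
#'
#' Returns the three Cartesian spin matrices Jx, Jy, Jz in the standard
#' Zeeman basis (descending magnetic quantum number). They satisfy the
#' cyclic commutation relations \[Jx, Jy\] = i Jz and the Casimir identity
#' Jx^2 + Jy^2 + Jz^2 = I(I+1) * identity with I = (multiplicity - 1) / 2.
#'
#' @param multiplicity integer 2I+1 >= 2 (2 for protons and electrons,
#'   3 for 14N).
#' @return list with complex matrices `x`, `y`, `z`.
#' @examples
#' spin_operators(2)$z # diag(1/2, -1/2)
#' @export
spin_operators <- function(multiplicity) {
  if (length(multiplicity) != 1 || multiplicity != round(multiplicity) ||
      multiplicity < 2) {
    stop("invalid spin: multiplicity must be an integer >= 2", call. = FALSE)
  }
  m <- as.integer(multiplicity)
  I <- (m - 1) / 2
  mz <- seq(I, -I, by = -1)
  jz <- diag(mz) + 0i
  # ladder operator J+ : <m+1|J+|m> = sqrt(I(I+1) - m(m+1))
  jp <- matrix(0i, m, m)
  for (k in seq_len(m - 1)) {
    jp[k, k + 1] <- sqrt(I * (I + 1) - mz[k + 1] * (mz[k + 1] + 1))
  }
  jm <- Conj(t(jp))
  list(x = (jp + jm) / 2, y = (jp - jm) / (2i), z = jz)
}

#' Composite spin space
#'
#' Describes the tensor-product structure of a multi-spin Hilbert space as
#' an ordered list of site multiplicities. The package convention orders
#' electrons first, then the nuclei of each radical in configuration
#' order; all operators are constructed against this ordering.
#'
#' @param multiplicities integer vector of site multiplicities (>= 2 each).
#' @param labels optional character vector naming each site.
#' @return object of class `spin_space` with elements `multiplicities`,
#'   `labels`, `dim`.
#' @export
spin_space <- function(multiplicities, labels = NULL) {
  multiplicities <- as.integer(multiplicities)
  if (any(multiplicities < 2)) {
    stop("invalid spin: all multiplicities must be >= 2", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("site", seq_along(multiplicities))
  stopifnot(length(labels) == length(multiplicities))
  structure(
    list(multiplicities = multiplicities, labels = labels,
         dim = prod(multiplicities)),
    class = "spin_space"
  )
}

#' @export
print.spin_space <- function(x, ...) {
  cat("<spin_space> dim", x$dim, "=",
      paste(x$multiplicities, collapse = " x "), "\n")
  cat("  sites:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Embed a single-site operator in a composite spin space
#'
#' Kronecker embedding: identity on every site except `site`, where `op`
#' acts. Operators embedded at different sites commute; embedding
#' preserves Hermiticity and spectra.
#'
#' @param op square matrix matching the multiplicity of `site`.
#' @param site site index into `space`.
#' @param space a [spin_space()].
#' @return complex matrix of dimension `space$dim`.
#' @export
embed_operator <- function(op, site, space) {
  m <- space$multiplicities
  if (site < 1 || site > length(m)) {
    stop("invalid site index", call. = FALSE)
  }
  if (!is.matrix(op) || nrow(op) != m[site] || ncol(op) != m[site]) {
    stop("shape error: operator dimension does not match site multiplicity",
         call. = FALSE)
  }
  d_before <- if (site > 1) prod(m[seq_len(site - 1)]) else 1L
  d_after <- if (site < length(m)) prod(m[(site + 1):length(m)]) else 1L
  out <- op + 0i
  if (d_before > 1) out <- diag(d_before) %x% out
  if (d_after > 1) out <- out %x% diag(d_after)
  out
}

# All three Cartesian spin operators of `site`, embedded in `space`.
embedded_spin <- function(site, space) {
  ops <- spin_operators(space$multiplicities[site])
  lapply(ops, embed_operator, site = site, space = space)
}

#' Singlet projection operator of an electron pair
#'
#' P = 1/4 * identity - S_e1 . S_e2 on the composite space. Idempotent and
#' Hermitian with trace dim/4; the triplet projector is its complement.
#' Spin-selective (Haberkorn) recombination of a radical pair proceeds
#' through this projector.
#'
#' @param space a [spin_space()].
#' @param e1,e2 distinct indices of electron (multiplicity 2) sites.
#' @return complex matrix of dimension `space$dim`.
#' @export
singlet_projector <- function(space, e1, e2) {
  if (e1 == e2) stop("invalid site: electron sites must differ", call. = FALSE)
  for (s in c(e1, e2)) {
    if (s < 1 || s > length(space$multiplicities) ||
        space$multiplicities[s] != 2) {
      stop("invalid site: singlet projector requires multiplicity-2 sites",
           call. = FALSE)
    }
  }
  s1 <- embedded_spin(e1, space)
  s2 <- embedded_spin(e2, space)
  diag(space$dim) / 4 -
    (s1$x %*% s2$x + s1$y %*% s2$y + s1$z %*% s2$z)
}

#' Magnetic field vector from spherical angles
#'
#' Cartesian field vector with the polar angle measured from the molecular
#' z-axis. Hyperfine tensors are held fixed in the molecular frame and the
#' field is rotated instead; only the relative orientation matters, so the
#' axis convention is arbitrary (and stated here).
#'
#' @param magnitude field strength in uT (>= 0).
#' @param polar polar angle in radians (from +z).
#' @param azimuth azimuthal angle in radians (from +x, in the xy plane).
#' @return numeric length-3 vector in uT.
#' @examples
#' field_vector(50, 0, 0) # (0, 0, 50)
#' @export
field_vector <- function(magnitude, polar = 0, azimuth = 0) {
  if (!is.finite(magnitude) || magnitude < 0) {
    stop("invalid field: magnitude must be finite and >= 0", call. = FALSE)
  }
  magnitude * c(sin(polar) * cos(azimuth),
                sin(polar) * sin(azimuth),
                cos(polar))
}

#' Deterministic near-uniform directions on the unit sphere
#'
#' Fibonacci (golden-angle) spiral point set used for orientation
#' averaging of anisotropic hyperfine interactions. Deterministic: the
#' same `n` always yields the same points.
#'
#' @param n number of directions (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
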
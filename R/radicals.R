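#' Hyperfine interaction tensor
#'
#' A 3x3 real symmetric tensor in MHz (linear frequency) expressed in a
#' common molecular frame. A scalar input `a_iso` expands to
#' `a_iso * identity`. Non-symmetric input is symmetrized
#' (A <- (A + t(A)) / 2) with a warning: antisymmetric hyperfine
#' components are outside the model.
#'
#' @param matrix 3x3 numeric matrix (MHz), or a single number taken as an
#'   isotropic coupling.
#' @param frame_label text identifier of the molecular frame.
#' @return object of class `hyperfine_tensor`.
#' @examples
#' hyperfine_tensor(4.94)            # isotropic ascorbyl H4 coupling
#' isotropic_part(hyperfine_tensor(diag(c(1, 2, 3))))
#' @export
hyperfine_tensor <- function(matrix, frame_label = "molecular") {
  if (length(matrix) == 1 && is.numeric(matrix)) {
    matrix <- diag(3) * as.numeric(matrix)
  }
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(3, 3)) || !all(is.finite(matrix))) {
    stop("hyperfine tensor must be a finite 3x3 matrix or a scalar a_iso",
         call. = FALSE)
  }
  if (max(abs(matrix - t(matrix))) > 1e-12 * max(1, max(abs(matrix)))) {
    warning("non-symmetric hyperfine tensor symmetrized", call. = FALSE)
  }
  structure(
    list(matrix = (matrix + t(matrix)) / 2, frame_label = frame_label),
    class = "hyperfine_tensor"
  )
}

#' Isotropic (rank-0) part of a hyperfine tensor
#'
#' @param tensor a [hyperfine_tensor()].
#' @return trace/3, in MHz.
#' @export
isotropic_part <- function(tensor) {
  stopifnot(inherits(tensor, "hyperfine_tensor"))
  sum(diag(tensor$matrix)) / 3
}

#' Magnetic nucleus of a radical
#'
#' @param label text label (e.g. "N5").
#' @param multiplicity 2I+1 (2 for 1H, 3 for 14N).
#' @param tensor a [hyperfine_tensor()] (or scalar/matrix coerced to one).
#' @return object of class `nucleus`.
#' @export
nucleus <- function(label, multiplicity, tensor) {
  if (!inherits(tensor, "hyperfine_tensor")) tensor <- hyperfine_tensor(tensor)
  multiplicity <- as.integer(multiplicity)
  if (multiplicity < 2) {
    stop("invalid spin: nuclear multiplicity must be >= 2", call. = FALSE)
  }
  structure(list(label = label, multiplicity = multiplicity, tensor = tensor),
            class = "nucleus")
}

#' Paramagnetic radical
#'
#' A radical carries one unpaired electron, an ordered list of magnetic
#' nuclei with hyperfine tensors, and a mobility flag. For a `free`
#' (rotationally averaged) radical only the isotropic tensor parts enter
#' the Hamiltonian; a `bound` (immobilized) radical retains the full
#' anisotropic tensors, making its spin dynamics orientation dependent.
#'
#' @param label text label.
#' @param nuclei list of [nucleus()] objects (possibly empty).
#' @param g_factor electron g-factor (> 0).
#' @param mobility "free" or "bound".
#' @return object of class `radical`.
#' @export
radical <- function(label, nuclei = list(), g_factor = G_ELECTRON,
                    mobility = c("free", "bound")) {
  mobility <- match.arg(mobility)
  if (!is.numeric(g_factor) || g_factor <= 0) {
    stop("g_factor must be > 0", call. = FALSE)
  }
  stopifnot(all(vapply(nuclei, inherits, logical(1), "nucleus")))
  structure(
    list(label = label, g_factor = g_factor, nuclei = nuclei,
         mobility = mobility),
    class = "radical"
  )
}

#' @export
print.radical <- function(x, ...) {
  cat("<radical>", x$label, sprintf("(g = %.4f, %s)", x$g_factor, x$mobility),
      "\n")
  for (n in x$nuclei) {
    cat(sprintf("  %-4s mult %d  a_iso %7.3f MHz\n", n$label, n$multiplicity,
                isotropic_part(n$tensor)))
  }
  invisible(x)
}

# Hyperfine tensors of the flavin semiquinone (MHz, principal-axis
# representation in the molecular frame, z perpendicular to the isoalloxazine
# plane), as used in radical-scavenging triad models of flavin
# magnetosensitivity. N5/N10 are the strongly axial nitrogen couplings that
# dominate singlet-triplet mixing; H5 is the alpha proton at N5.
.flavin_tensors <- list(
  N5  = list(mult = 3L, A = diag(c(-2.84, -2.84, 49.94))),
  N10 = list(mult = 3L, A = diag(c(-0.91, -0.23, 28.89))),
  H5  = list(mult = 2L, A = diag(c(-26.34, -16.65, -0.62))),
  H6  = list(mult = 2L, A = diag(c(-13.92, -3.90, -1.43))),
  Hb1 = list(mult = 2L, A = diag(c(11.41, 11.41, 11.41)))
)

.make_flavin <- function(which, mobility) {
  nuc <- lapply(which, function(nm) {
    t <- .flavin_tensors[[nm]]
    nucleus(nm, t$mult, hyperfine_tensor(t$A, frame_label = "flavin"))
  })
  radical("FH", nuclei = nuc, mobility = mobility)
}

#' Built-in radical presets
#'
#' \describe{
#'   \item{`flavin_3N`}{flavin semiquinone FH with its three dominant
#'     hyperfine couplings N5, N10 and H5.}
#'   \item{`flavin_5N`}{adds the next two couplings, H6 and Hb1.}
#'   \item{`ascorbyl_H4`}{ascorbyl radical A with the single significant
#'     isotropic proton coupling a_iso = 4.94 MHz; always rotationally
#'     averaged (free).}
#'   \item{`superoxide`}{superoxide O2- with no magnetic nuclei (16O).}
#' }
#'
#' @param name preset name.
#' @param mobility mobility of the flavin presets ("free" or "bound");
#'   ignored for ascorbyl and superoxide, which are mobile species.
#' @return a [radical()].
#' @examples
#' radical_preset("ascorbyl_H4")
#' @export
radical_preset <- function(name, mobility = c("free", "bound")) {
  mobility <- match.arg(mobility)
  switch(
    name,
    flavin_3N = .make_flavin(c("N5", "N10", "H5"), mobility),
    flavin_5N = .make_flavin(c("N5", "N10", "H5", "H6", "Hb1"), mobility),
    ascorbyl_H4 = radical(
      "A",
      nuclei = list(nucleus("H4", 2L, hyperfine_tensor(4.94))),
      mobility = "free"
    ),
    superoxide = radical("O2", nuclei = list(), mobility = "free"),
    stop("unknown preset: ", name, call. = FALSE)
  )
}

# "label:nucleus" site labels; character(0) for a nuclei-free radical
nucleus_labels <- function(r) {
  nl <- vapply(r$nuclei, `[[`, character(1), "label")
  if (length(nl)) paste0(r$label, ":", nl) else character(0)
}

# serialize a radical to a plain list (for YAML/JSON round-tripping)
radical_to_list <- function(r) {
  list(
    label = r$label,
    g_factor = r$g_factor,
    mobility = r$mobility,
    nuclei = lapply(r$nuclei, function(n) {
      list(label = n$label, multiplicity = n$multiplicity,
           tensor = apply(n$tensor$matrix, 1, as.numeric, simplify = FALSE))
    })
  )
}

# build a radical from a plain list or preset name
radical_from_spec <- function(spec, mobility = "free") {
  if (is.character(spec) && length(spec) == 1) {
    return(radical_preset(spec, mobility = mobility))
  }
  stopifnot(is.list(spec))
  nuclei <- lapply(spec$nuclei, function(n) {
    tn <- n$tensor
    if (!is.null(n$a_iso)) tn <- n$a_iso
    if (is.list(tn)) tn <- do.call(rbind, tn)
    nucleus(n$label, n$multiplicity, hyperfine_tensor(tn))
  })
  radical(
    label = spec$label %||% "radical",
    nuclei = nuclei,
    g_factor = spec$g_factor %||% G_ELECTRON,
    mobility = spec$mobility %||% mobility
  )
}
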
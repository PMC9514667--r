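#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a rate map
#'
#' Already long-format; returned with the field conditions as columns so
#' the provenance survives row binding.
#'
#' @param x a `rate_map`.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.rate_map <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                B_uT = attr(x, "B_uT"), B_ref_uT = attr(x, "B_ref_uT"),
                orientation_policy = attr(x, "orientation_policy"))
}

#' @rdname tidy.rate_map
#' @export
glance.rate_map <- function(x, ...) {
  worst <- max_mfe(x)
  tibble::tibble(
    n = nrow(x),
    B_uT = attr(x, "B_uT"), B_ref_uT = attr(x, "B_ref_uT"),
    min_effect_pct = worst$effect_pct,
    k_X_at_min = worst$k_X, k_Sigma_at_min = worst$k_Sigma,
    max_chi = max(x$chi)
  )
}

#' Tidy a MARY curve
#'
#' @param x a `mary_curve`.
#' @param ... unused.
#' @return tibble with the reference field as a column.
#' @export
tidy.mary_curve <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                reference_uT = attr(x, "reference_uT"))
}

#' @rdname tidy.mary_curve
#' @export
glance.mary_curve <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    reference_uT = attr(x, "reference_uT"),
    min_effect_pct = min(x$effect_pct),
    max_effect_pct = max(x$effect_pct)
  )
}

#' Tidy / summarize a reduction-convergence report
#'
#' @param x a `reduction_report`.
#' @param ... unused.
#' @return `tidy`: the table itself; `glance`: one row with the top-of-
#'   ladder discrepancy and the convergence flag.
#' @export
tidy.reduction_report <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.reduction_report
#' @export
glance.reduction_report <- function(x, ...) {
  tibble::tibble(
    gamma2_top = x$gamma2[nrow(x)],
    discrepancy_top = x$discrepancy[nrow(x)],
    monotone = all(diff(x$discrepancy) < 0),
    converged = isTRUE(attr(x, "converged"))
  )
}
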
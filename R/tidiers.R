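# broom-style tidiers for the package's result objects.

#' Tidy a binding result
#'
#' `tidy()` returns the per-frame component table; `glance()` a one-row
#' summary with the mean estimate, its standard error and component means.
#'
#' @param x A `binding_result` from [mmgbsa_binding()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy binding_result
#' @export
tidy.binding_result <- function(x, ...) {
  x$frames
}

#' @rdname tidy.binding_result
#' @method glance binding_result
#' @export
glance.binding_result <- function(x, ...) {
  tibble::tibble(
    dg_mean = x$mean, sem = x$sem, n_frames = nrow(x$frames),
    e_coul = unname(x$components["e_coul"]),
    e_lj = unname(x$components["e_lj"]),
    g_gb = unname(x$components["g_gb"]),
    g_sa = unname(x$components["g_sa"])
  )
}

#' Tidy a thermodynamic-integration result
#'
#' `tidy()` returns the per-stage free-energy table; `glance()` a one-row
#' summary with the total, its standard error and the replicate count when
#' pooled.
#'
#' @param x A `ti_result` from [trapezoid_integrate()] or
#'   [pool_replicates()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ti_result
#' @export
tidy.ti_result <- function(x, ...) {
  x$stages
}

#' @rdname tidy.ti_result
#' @method glance ti_result
#' @export
glance.ti_result <- function(x, ...) {
  tibble::tibble(
    dg_total = x$total, se = x$se,
    n_replicates = if (is.null(x$replicates)) NA_integer_ else length(x$replicates)
  )
}

#' Tidy a conformational tendency report
#'
#' `tidy()` returns the per-distribution medians and ranks; `glance()` the
#' verdict with the decision margin.
#'
#' @param x A `tendency_report` from [classify_tendency()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tendency_report
#' @export
tidy.tendency_report <- function(x, ...) {
  x$medians
}

#' @rdname tidy.tendency_report
#' @method glance tendency_report
#' @export
glance.tendency_report <- function(x, ...) {
  tibble::tibble(verdict = x$verdict, margin = x$margin)
}

#' Tidy a pose contact report
#'
#' `tidy()` returns the per-residue minimum distances and interaction
#' flags; `glance()` the pose label and cutoff.
#'
#' @param x A `contact_report` from [pose_contacts()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy contact_report
#' @export
tidy.contact_report <- function(x, ...) {
  x$contacts
}

#' @rdname tidy.contact_report
#' @method glance contact_report
#' @export
glance.contact_report <- function(x, ...) {
  tibble::tibble(label = x$label, cutoff = x$cutoff)
}

#' Tidy an RMSD density estimate
#'
#' `tidy()` returns the density grid; `glance()` the bandwidth, sample size
#' and summary quantiles.
#'
#' @param x An `rmsd_density` from [density_estimate()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rmsd_density
#' @export
tidy.rmsd_density <- function(x, ...) {
  x$grid
}

#' @rdname tidy.rmsd_density
#' @method glance rmsd_density
#' @export
glance.rmsd_density <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = length(x$values), bandwidth = x$bandwidth),
    x$summary
  )
}
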
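#' Parameters for resistant-clone size back-calculation
#'
#' Study conventions: net exponential growth between 0.65% and 2.8% per day
#' (median to upper-95% growth rates reported for HER2-positive breast
#' tumors), a +/-25% uncertainty on each volumetric measurement, a resistant
#' clone making up 90-100% of the residual tumor, and 1e9 cells per cm^3.
#'
#' @param growth_rate_range net per-day growth rate range of the resistant
#'   clone.
#' @param volume_uncertainty fractional measurement uncertainty applied to
#'   each volume.
#' @param resistant_share_range fraction of the residual tumor made up by
#'   the resistant clone.
#' @param cells_per_cm3 conversion between volume and cell count.
#' @param correlated_volumes when `TRUE` the same volume scaling is applied
#'   to the pre and post measurement; default applies them independently.
#' @return a list of class `clone_size_params`.
#' @export
clone_size_params <- function(growth_rate_range = c(0.0065, 0.028),
                              volume_uncertainty = 0.25,
                              resistant_share_range = c(0.90, 1.00),
                              cells_per_cm3 = 1e9,
                              correlated_volumes = FALSE) {
  stopifnot(growth_rate_range[1] <= growth_rate_range[2],
            growth_rate_range[1] > 0, volume_uncertainty >= 0,
            resistant_share_range[1] <= resistant_share_range[2])
  structure(list(growth_rate_range = growth_rate_range,
                 volume_uncertainty = volume_uncertainty,
                 resistant_share_range = resistant_share_range,
                 cells_per_cm3 = cells_per_cm3,
                 correlated_volumes = correlated_volumes),
            class = "clone_size_params")
}

#' Feasible pre-treatment resistant-clone fraction
#'
#' Back-calculates, under exponential growth of the resistant clone at net
#' rate `g` through treatment, the fraction of the pre-treatment tumor the
#' clone must have occupied: resistant cells at surgery are
#' `w * post_volume * cells_per_cm3` (share `w` of the residual), so the
#' clone held `R_T * exp(-g * days)` cells at the start of treatment, and
#' the fraction is that count over the pre-treatment cell number. The
#' fraction is monotone in every input, so the feasible interval is attained
#' on the corner grid of (growth rate, volume scalings, share); corners are
#' enumerated and the min/max reported, clipped to `[0, 1]`.
#'
#' @param pre_volume_cm3,post_volume_cm3 measured tumor volumes.
#' @param treatment_days treatment duration in days.
#' @param params a [clone_size_params()] object.
#' @return a list of class `clone_size_estimate`: `f_low`, `f_high`, and
#'   `corners` (data.frame of all corner combinations with their fractions).
#'   Warns when every corner exceeds 1 (inconsistent with exponential
#'   growth).
#' @export
resistant_fraction_interval <- function(pre_volume_cm3, post_volume_cm3,
                                        treatment_days,
                                        params = clone_size_params()) {
  stopifnot(pre_volume_cm3 > 0, post_volume_cm3 > 0, treatment_days > 0)
  u <- params$volume_uncertainty
  vscale <- c(1 - u, 1 + u)
  corners <- if (params$correlated_volumes)
    expand.grid(g = params$growth_rate_range, v = vscale,
                w = params$resistant_share_range)
  else
    expand.grid(g = params$growth_rate_range, v_pre = vscale,
                v_post = vscale, w = params$resistant_share_range)
  if (params$correlated_volumes) {
    corners$v_pre <- corners$v
    corners$v_post <- corners$v
    corners$v <- NULL
  }
  cells <- params$cells_per_cm3
  r_t <- corners$w * post_volume_cm3 * corners$v_post * cells
  r_0 <- r_t * exp(-corners$g * treatment_days)
  frac_raw <- r_0 / (pre_volume_cm3 * corners$v_pre * cells)
  if (all(frac_raw > 1))
    warning("inconsistent with exponential-growth assumption: ",
            "fraction > 1 at every corner")
  corners$fraction <- pmin(pmax(frac_raw, 0), 1)
  structure(list(f_low = min(corners$fraction),
                 f_high = max(corners$fraction),
                 corners = corners), class = "clone_size_estimate")
}

#' @export
print.clone_size_estimate <- function(x, ...) {
  cat(sprintf(
    "pre-treatment resistant fraction in [%.4g, %.4g] (corner grid, n=%d)\n",
    x$f_low, x$f_high, nrow(x$corners)))
  invisible(x)
}
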
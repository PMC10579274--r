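#' Buoyant-density calibration for \eqn{^{13}}C-qSIP
#'
#' Physical constants linking GC content, DNA buoyant density, nucleotide
#' molecular weight, and the maximal mass shift attainable under full
#' \eqn{^{13}}C labeling. The defaults follow the standard qSIP calibration
#' for CsCl/CsTFA gradients:
#' \itemize{
#'   \item unlabeled density: \eqn{W_{light} = 0.083506\,GC + 1.646057} g/mL
#'   \item mean nucleotide weight: \eqn{M_{light} = 0.496\,GC + 307.691} g/mol
#'   \item maximal heavy shift: \eqn{\Delta M_{max} = 9.974564 - 0.4987282\,GC} g/mol
#'   \item natural \eqn{^{13}}C abundance: 0.01111233
#' }
#'
#' The constants are overridable as a unit (pass a full replacement object to
#' downstream functions); they are validated once at construction and never
#' mutated mid-run.
#'
#' @param density_slope,density_intercept linear map GC -> buoyant density (g/mL).
#' @param mw_slope,mw_intercept linear map GC -> mean nucleotide molecular
#'   weight (g/mol).
#' @param heavymax_slope,heavymax_intercept linear map GC -> maximal molecular
#'   weight gain under 100 atom% \eqn{^{13}}C (g/mol); the slope is negative
#'   because high-GC DNA has fewer carbon atoms per average nucleotide.
#' @param nat_abund_13C natural abundance of \eqn{^{13}}C (unitless fraction).
#' @return An object of class `gradient_calibration` (a validated list).
#' @examples
#' calib <- gradient_calibration()
#' taxon_mean_density(gc = 0.5, afe = 0, calib)  # 1.687810 g/mL
#' @export
gradient_calibration <- function(density_slope = 0.083506,
                                 density_intercept = 1.646057,
                                 mw_slope = 0.496,
                                 mw_intercept = 307.691,
                                 heavymax_slope = -0.4987282,
                                 heavymax_intercept = 9.974564,
                                 nat_abund_13C = 0.01111233) {
  stopifnot(
    is.numeric(density_slope), density_slope > 0,
    is.numeric(density_intercept), density_intercept > 0,
    is.numeric(mw_slope), mw_slope > 0,
    is.numeric(mw_intercept), mw_intercept > 0,
    is.numeric(heavymax_slope), heavymax_slope < 0,
    is.numeric(heavymax_intercept), heavymax_intercept > 0,
    is.numeric(nat_abund_13C), nat_abund_13C > 0, nat_abund_13C < 1
  )
  structure(
    list(
      density_slope = density_slope,
      density_intercept = density_intercept,
      mw_slope = mw_slope,
      mw_intercept = mw_intercept,
      heavymax_slope = heavymax_slope,
      heavymax_intercept = heavymax_intercept,
      nat_abund_13C = nat_abund_13C
    ),
    class = "gradient_calibration"
  )
}

#' @export
print.gradient_calibration <- function(x, ...) {
  cat("qSIP gradient calibration (13C)\n")
  cat(sprintf("  W_light  = %.6f * GC + %.6f  [g/mL]\n",
              x$density_slope, x$density_intercept))
  cat(sprintf("  M_light  = %.3f * GC + %.3f  [g/mol]\n",
              x$mw_slope, x$mw_intercept))
  cat(sprintf("  dM_max   = %.7f * GC + %.6f  [g/mol]\n",
              x$heavymax_slope, x$heavymax_intercept))
  cat(sprintf("  natural 13C abundance = %.8f\n", x$nat_abund_13C))
  invisible(x)
}

.as_calibration <- function(calib) {
  if (inherits(calib, "gradient_calibration")) return(calib)
  stop("`calibration` must be a gradient_calibration object")
}

#' Expected buoyant density of a taxon's DNA
#'
#' Forward model: the equilibrium density of a taxon's DNA in an isopycnic
#' gradient, given its genomic GC content and its \eqn{^{13}}C atom fraction
#' excess (AFE). Labeling scales density through the molecular-weight ratio:
#' \deqn{W_{lab} = W_{light} \cdot M_{lab} / M_{light}}
#' with \eqn{M_{lab} = M_{light} + \frac{afe}{1 - a_{13C}} \Delta M_{max}}.
#' Strictly increasing in both `gc` and `afe`. This is the exact inverse of
#' [compute_afe()].
#'
#' @param gc genomic GC content, fraction in (0, 1). Vectorized.
#' @param afe atom fraction excess of \eqn{^{13}}C, in `[0, 1 - nat_abund_13C]`.
#' @param calibration a [gradient_calibration()] object.
#' @return buoyant density in g/mL.
#' @export
taxon_mean_density <- function(gc, afe, calibration = gradient_calibration()) {
  cal <- .as_calibration(calibration)
  if (any(!is.finite(gc)) || any(gc <= 0) || any(gc >= 1))
    stop("`gc` must lie strictly inside (0, 1)")
  afe_max <- 1 - cal$nat_abund_13C
  if (any(!is.finite(afe)) || any(afe < 0) || any(afe > afe_max))
    stop(sprintf("`afe` must lie in [0, %.8f] (full-labeling bound)", afe_max))
  w_light <- cal$density_slope * gc + cal$density_intercept
  m_light <- cal$mw_slope * gc + cal$mw_intercept
  dm_max <- cal$heavymax_intercept + cal$heavymax_slope * gc
  m_lab <- m_light + (afe / afe_max) * dm_max
  w_light * (m_lab / m_light)
}

# Internal GC-from-density: clamps to [0, 1] without the user-facing range
# checks; used inside estimators where extreme resampled densities must not
# abort a run.
.gc_from_density <- function(w_light, cal) {
  pmin(pmax((w_light - cal$density_intercept) / cal$density_slope, 0), 1)
}

#' Estimate GC content from unlabeled buoyant density
#'
#' Inverts the linear density calibration:
#' \eqn{GC = (W_{light} - intercept)/slope}. Values marginally outside `[0, 1]`
#' (within `[-0.05, 1.05]`) are clamped with a warning; values further out
#' indicate a density outside the calibrated range and raise an error.
#'
#' @param w_light weighted average density of the taxon in unlabeled tubes (g/mL).
#' @inheritParams taxon_mean_density
#' @param warn emit a warning when clamping occurs.
#' @return GC content as a fraction in `[0, 1]`.
#' @export
estimate_gc <- function(w_light, calibration = gradient_calibration(),
                        warn = TRUE) {
  cal <- .as_calibration(calibration)
  gc_raw <- (w_light - cal$density_intercept) / cal$density_slope
  if (any(!is.finite(gc_raw)) || any(gc_raw < -0.05) || any(gc_raw > 1.05))
    stop("density outside the calibrated range (implied GC beyond [-0.05, 1.05])")
  if (warn && any(gc_raw < 0 | gc_raw > 1))
    warning("implied GC clamped to [0, 1]")
  pmin(pmax(gc_raw, 0), 1)
}

#' Atom fraction excess from a taxon's density shift
#'
#' Converts the shift between unlabeled and labeled weighted average densities
#' into the \eqn{^{13}}C atom fraction excess:
#' \deqn{AFE = \frac{M_{lab} - M_{light}}{\Delta M_{max}} (1 - a_{13C})}
#' with \eqn{M_{lab} = (W_{lab}/W_{light}) M_{light}} and GC estimated from
#' `w_light`. Negative values are returned as-is and read as "no enrichment";
#' the function is the exact inverse of [taxon_mean_density()].
#'
#' @param w_light,w_lab weighted average densities in unlabeled and labeled
#'   tubes (g/mL). Vectorized.
#' @inheritParams estimate_gc
#' @return atom fraction excess (fraction; may be negative).
#' @export
compute_afe <- function(w_light, w_lab, calibration = gradient_calibration(),
                        warn = TRUE) {
  cal <- .as_calibration(calibration)
  gc <- estimate_gc(w_light, cal, warn = warn)
  .afe_from_densities(w_light, w_lab, gc, cal)
}

# Core AFE arithmetic shared by the exported op and the bootstrap loop.
.afe_from_densities <- function(w_light, w_lab, gc, cal) {
  m_light <- cal$mw_slope * gc + cal$mw_intercept
  dm_max <- cal$heavymax_intercept + cal$heavymax_slope * gc
  if (any(dm_max <= 0))
    stop("calibration error: non-positive maximal heavy mass shift")
  m_lab <- (w_lab / w_light) * m_light
  ((m_lab - m_light) / dm_max) * (1 - cal$nat_abund_13C)
}
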
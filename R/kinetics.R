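#' Parametric tissue time-activity model
#'
#' A minimal uptake model used to paint phantom tissues. Activity (in SUV)
#' follows
#' \deqn{S(t) = S_{eq} g(t) + m \max(0, t - t_d),}
#' where \eqn{g(t)} is the response of a first-order uptake compartment
#' (rate `uptake_rate` per minute) to a constant-rate infusion of duration
#' `infusion_min`:
#' \deqn{g(t) = \frac{1}{T_{inf}} \int_0^{\min(t, T_{inf})}
#'       \left(1 - e^{-k (t - u)}\right) du,}
#' with the bolus limit \eqn{g(t) = 1 - e^{-kt}} when `infusion_min = 0`.
#' \eqn{g} rises monotonically from 0 to 1, so `plateau_suv` is the
#' asymptotic (equilibrium) SUV; the optional linear drift term
#' (`drift_slope` SUV/min after `drift_onset_min`) models departures from
#' equilibrium.
#'
#' The default 4-minute infusion mirrors a slow pump administration chosen
#' to broaden the input function in dynamic brain studies. The model is an
#' emulation of the empirical TAC shape (rise then plateau from roughly
#' 30 min), not a pharmacokinetic claim; images are assumed
#' decay-corrected, so no decay term appears.
#'
#' @param plateau_suv Asymptotic SUV level (>= 0).
#' @param uptake_rate Uptake rate constant k, per minute (> 0).
#' @param infusion_min Infusion duration, minutes (>= 0; 0 = bolus).
#' @param drift_slope Linear drift, SUV per minute, applied after
#'   `drift_onset_min` (default 0: true equilibrium).
#' @param drift_onset_min Drift onset time, minutes.
#' @return An object of class `tissue_kinetics`.
#' @examples
#' kin <- tissue_kinetics(plateau_suv = 4.5, uptake_rate = 0.18)
#' tissue_tac(kin, c(0, 5, 30, 60))
#' @export
tissue_kinetics <- function(plateau_suv, uptake_rate, infusion_min = 4,
                            drift_slope = 0, drift_onset_min = 30) {
  if (!is.finite(plateau_suv) || plateau_suv < 0)
    stop_("'plateau_suv' must be finite and >= 0")
  if (!is.finite(uptake_rate) || uptake_rate <= 0)
    stop_("'uptake_rate' must be finite and > 0")
  if (!is.finite(infusion_min) || infusion_min < 0)
    stop_("'infusion_min' must be finite and >= 0")
  if (!is.finite(drift_slope) || !is.finite(drift_onset_min) || drift_onset_min < 0)
    stop_("drift parameters must be finite (onset >= 0)")
  structure(
    list(plateau_suv = plateau_suv, uptake_rate = uptake_rate,
         infusion_min = infusion_min, drift_slope = drift_slope,
         drift_onset_min = drift_onset_min),
    class = "tissue_kinetics")
}

# Closed-form uptake fraction g(t) in [0, 1].
# For T_inf > 0:  g(t) = (tau - (exp(-k (t - tau)) - exp(-k t)) / k) / T_inf,
# tau = min(t, T_inf) -- the overflow-safe rearrangement of the infusion
# integral. Bolus limit (T_inf = 0): g(t) = 1 - exp(-k t).
uptake_fraction_ <- function(t, k, t_inf) {
  if (t_inf == 0) return(-expm1(-k * t))
  tau <- pmin(t, t_inf)
  (tau - (exp(-k * (t - tau)) - exp(-k * t)) / k) / t_inf
}

#' Evaluate a tissue time-activity curve
#'
#' Closed-form evaluation of the `tissue_kinetics` model at time(s) `t_min`
#' minutes post-injection (no numeric quadrature).
#'
#' @param kin A [tissue_kinetics()] object.
#' @param t_min Time(s) in minutes, all >= 0.
#' @return SUV value(s), same length as `t_min`.
#' @export
tissue_tac <- function(kin, t_min) {
  stopifnot(inherits(kin, "tissue_kinetics"))
  if (any(!is.finite(t_min)) || any(t_min < 0))
    stop_("'t_min' must be finite and >= 0")
  g <- uptake_fraction_(t_min, kin$uptake_rate, kin$infusion_min)
  kin$plateau_suv * g + kin$drift_slope * pmax(0, t_min - kin$drift_onset_min)
}

# Time-average of the TAC over [a, b] minutes by Gauss-Legendre quadrature,
# split at the model's kink points (end of infusion, drift onset) so each
# panel integrates a smooth function; 8 nodes per panel is ample for these
# exponentials.
tac_frame_average_ <- function(kin, a, b, nodes = 8L) {
  stopifnot(b > a, a >= 0)
  cuts <- sort(unique(c(a, b,
                        kin$infusion_min[kin$infusion_min > a & kin$infusion_min < b],
                        kin$drift_onset_min[kin$drift_onset_min > a & kin$drift_onset_min < b])))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    gl <- pracma::gaussLegendre(nodes, cuts[i], cuts[i + 1L])
    total <- total + sum(gl$w * tissue_tac(kin, gl$x))
  }
  total / (b - a)
}

#' Frame-averaged tissue activity over a schedule
#'
#' The value recorded for a frame in histogrammed list-mode data is the
#' time-average of the tissue TAC over that frame's interval, not a
#' midpoint sample; this function computes those averages.
#'
#' @param kin A [tissue_kinetics()] object.
#' @param schedule A [make_frame_schedule()] object.
#' @return Numeric vector, one frame-averaged SUV per frame.
#' @export
tissue_frame_averages <- function(kin, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  vapply(seq_len(n_frames(schedule)), function(i) {
    tac_frame_average_(kin,
                       schedule$start_s[i] / 60,
                       (schedule$start_s[i] + schedule$duration_s[i]) / 60)
  }, numeric(1))
}

#' @export
print.tissue_kinetics <- function(x, ...) {
  cat(sprintf("Tissue kinetics: plateau %.3g SUV, k = %.3g /min, infusion %.3g min",
              x$plateau_suv, x$uptake_rate, x$infusion_min))
  if (x$drift_slope != 0)
    cat(sprintf(", drift %.3g SUV/min after %.3g min", x$drift_slope, x$drift_onset_min))
  cat("\n")
  invisible(x)
}
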
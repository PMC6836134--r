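#' Signed wrapped orientation error
#'
#' Computes the signed difference between the actual and reported
#' orientation of a bar stimulus. Orientation is periodic with period
#' 180 degrees, so the raw difference `actual - reported` is wrapped
#' into the half-open interval \[-90, 90). The boundary convention is
#' half-open: a raw difference of +90 maps to -90, while -90 maps to
#' itself.
#'
#' @param actual_deg actual (presented) orientation in degrees.
#' @param reported_deg reported orientation in degrees.
#' @return Signed error in degrees, in \[-90, 90). Vectorised.
#' @examples
#' wrap_orientation_error(10, 170)  # 20
#' wrap_orientation_error(0, 89)    # -89
#' @export
wrap_orientation_error <- function(actual_deg, reported_deg) {
  if (!is.numeric(actual_deg) || !is.numeric(reported_deg))
    stop("orientations must be numeric")
  if (any(!is.finite(actual_deg)) || any(!is.finite(reported_deg)))
    stop("orientations must be finite")
  d <- (actual_deg - reported_deg) %% 180
  ifelse(d >= 90, d - 180, d)
}

#' Wrap an angle into the signed error range
#'
#' Maps any angular difference (period 180) into \[-90, 90).
#' @param x angle(s) in degrees.
#' @return wrapped value(s) in \[-90, 90).
#' @export
wrap_half <- function(x) {
  d <- x %% 180
  ifelse(d >= 90, d - 180, d)
}

#' Transformed performance
#'
#' Linear rescaling of the absolute report error to a probability-like
#' score: `1 - |error| / 90`. A score of 1 is a perfect report; the
#' expected score under uniform random guessing is 0.5, which is the
#' chance level used throughout the criterion tests.
#'
#' @param error_deg signed wrapped error(s) in degrees, |error| <= 90.
#' @return score(s) in \[0, 1\].
#' @export
transformed_performance <- function(error_deg) {
  if (any(!is.finite(error_deg))) stop("error_deg must be finite")
  if (any(abs(error_deg) > 90))
    stop("|error_deg| > 90; wrap with wrap_orientation_error() first")
  1 - abs(error_deg) / 90
}

#' Weber contrast
#'
#' Stimulus contrast relative to the background: `(L - Lb) / Lb`.
#' Used only as stimulus metadata (luminances of targets, masks and
#' cues); no luminance-dependent modelling is done.
#'
#' @param luminance stimulus luminance (cd/m^2).
#' @param background background luminance (cd/m^2), default 60.
#' @return Weber contrast (dimensionless).
#' @export
weber_contrast <- function(luminance, background = 60) {
  if (any(background <= 0)) stop("background luminance must be positive")
  (luminance - background) / background
}
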
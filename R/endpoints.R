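# Endpoint dispersion: generalized variance of 3D reach endpoints.

#' Generalized variance of reach endpoints
#'
#' Determinant of the 3x3 sample covariance matrix (n - 1 denominator) of
#' per-trial 3D endpoints, a single scalar measure of dispersion in mm^6.
#'
#' @param endpoints n x 3 matrix of endpoints (mm), one row per trial.
#' @return Determinant in mm^6; `NA` (with a warning) for fewer than 4
#'   endpoints, where the determinant is degenerate.
#' @export
endpoint_generalized_variance <- function(endpoints) {
  endpoints <- as.matrix(endpoints)
  endpoints <- endpoints[complete.cases(endpoints), , drop = FALSE]
  if (nrow(endpoints) < 4) {
    warning("generalized variance undefined for fewer than 4 endpoints")
    return(NA_real_)
  }
  max(det(cov(endpoints)), 0)
}

#' Hand-subtracted digit endpoints
#'
#' Per-trial digit endpoint minus the matched hand endpoint, isolating
#' digit placement relative to the hand from transport variability.
#'
#' @param digit_endpoints,hand_endpoints n x 3 matrices with matching trial
#'   order.
#' @return n x 3 matrix of differences (mm).
#' @export
hand_subtracted_endpoints <- function(digit_endpoints, hand_endpoints) {
  digit_endpoints <- as.matrix(digit_endpoints)
  hand_endpoints <- as.matrix(hand_endpoints)
  if (!identical(dim(digit_endpoints), dim(hand_endpoints)))
    stop("digit and hand endpoint sets must have matching trials")
  digit_endpoints - hand_endpoints
}
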
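# Circular consistency of angular hand-shape measures.

#' Mean resultant length and circular mean of a set of angles
#'
#' MRL is the magnitude of the mean unit vector of the angles: 1 when all
#' angles coincide (perfect consistency), 0 for angles spread uniformly
#' around the circle. Used here as a consistency measure of hand
#' orientation and digit flexion at reach end (higher = less variable).
#'
#' @param angles Angles in degrees.
#' @return List: `MRL` in \[0, 1\], `mean_deg` (circular mean, degrees in
#'   \[0, 360)), `n`.
#' @export
mean_resultant_length <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("no angles supplied")
  th <- angles * pi / 180
  c_ <- mean(cos(th)); s_ <- mean(sin(th))
  list(MRL = sqrt(c_^2 + s_^2),
       mean_deg = (atan2(s_, c_) * 180 / pi) %% 360,
       n = length(angles))
}
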
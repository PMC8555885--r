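#' Pinhole camera model
#'
#' Constructs the shared intrinsic model for the real camera and the virtual
#' camera behind the mirror (same physical lens, so one intrinsic matrix).
#' No lens distortion terms are modelled.
#'
#' @param fx,fy Focal lengths in pixels (must be positive).
#' @param cx,cy Principal point in pixels.
#' @param image_width,image_height Sensor size in pixels.
#' @return An object of class `camera_model` with the upper-triangular
#'   3x3 intrinsic matrix `K`.
#' @export
camera_model <- function(fx, fy, cx, cy, image_width = 2400, image_height = 1024) {
  stopifnot(fx > 0, fy > 0, image_width > 0, image_height > 0)
  K <- matrix(c(fx, 0, cx,
                0, fy, cy,
                0,  0,  1), nrow = 3, byrow = TRUE)
  structure(list(K = K, fx = fx, fy = fy, cx = cx, cy = cy,
                 image_width = image_width, image_height = image_height),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: fx=%.1f fy=%.1f cx=%.1f cy=%.1f (%d x %d px)\n",
              x$fx, x$fy, x$cx, x$cy, x$image_width, x$image_height))
  invisible(x)
}

#' Read / write camera intrinsics as JSON
#'
#' @param path File path.
#' @return `read_intrinsics_json` returns a [camera_model()].
#' @export
read_intrinsics_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_model(j$fx, j$fy, j$cx, j$cy, j$image_width, j$image_height)
}

#' @param camera A [camera_model()].
#' @rdname read_intrinsics_json
#' @export
write_intrinsics_json <- function(camera, path) {
  jsonlite::write_json(
    list(fx = camera$fx, fy = camera$fy, cx = camera$cx, cy = camera$cy,
         image_width = camera$image_width, image_height = camera$image_height),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# pixel -> normalized camera coordinates, n x 2 in, n x 2 out
px_to_norm <- function(xy, camera) {
  cbind((xy[, 1] - camera$cx) / camera$fx,
        (xy[, 2] - camera$cy) / camera$fy)
}

# normalized -> pixel
norm_to_px <- function(xy, camera) {
  cbind(xy[, 1] * camera$fx + camera$cx,
        xy[, 2] * camera$fy + camera$cy)
}
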
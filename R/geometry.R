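#' Cone-beam acquisition geometry
#'
#' Distances and detector grid of the kV imaging chain. Room coordinates are
#' in mm with the isocenter at the origin: x lateral (patient left positive),
#' y longitudinal (superior positive), z vertical (anterior positive).
#' Gantry angles follow IEC 61217: 0 degrees puts the source above the
#' isocenter and the angle increases toward patient left.
#'
#' @param sad source-to-isocenter distance, mm.
#' @param sid source-to-detector distance, mm; must exceed `sad`.
#' @param detector_size detector physical size, mm (u, v).
#' @param detector_pixels detector pixel counts (u, v), at least 16 per axis.
#' @return An object of class `acquisition_geometry`.
#' @seealso [geometry_preset()] for named presets.
#' @export
acquisition_geometry <- function(sad = 1000, sid = 1500,
                                 detector_size = c(300, 300),
                                 detector_pixels = c(300, 300)) {
  stopifnot(is.numeric(sad), is.numeric(sid), length(sad) == 1, length(sid) == 1)
  if (!(sad > 0 && sad < sid))
    stop("acquisition geometry requires 0 < sad < sid")
  detector_pixels <- as.integer(detector_pixels)
  if (any(detector_pixels < 16))
    stop("detector needs at least 16 pixels per axis")
  if (any(detector_size <= 0)) stop("detector_size must be positive")
  structure(list(sad = sad, sid = sid,
                 detector_size = as.numeric(detector_size),
                 detector_pixels = detector_pixels,
                 pixel_mm = as.numeric(detector_size) / detector_pixels),
            class = "acquisition_geometry")
}

#' Named geometry presets
#'
#' `"obi"` is the standard clinical on-board kV imager geometry (sad 1000 mm,
#' sid 1500 mm) and is the package default. `"fig1"` is the alternative
#' short geometry sometimes quoted for kV imaging arms (imager 500 mm from
#' the isocenter, source 1000 mm from the imager), giving magnification 2.
#'
#' @param name one of `"obi"`, `"fig1"`.
#' @param ... overrides passed to [acquisition_geometry()].
#' @return An `acquisition_geometry` object.
#' @export
geometry_preset <- function(name = c("obi", "fig1"), ...) {
  name <- match.arg(name)
  base <- switch(name,
                 obi = list(sad = 1000, sid = 1500),
                 fig1 = list(sad = 500, sid = 1000))
  do.call(acquisition_geometry, modifyList(base, list(...)))
}

#' Short imaging arc specification
#'
#' @param theta_c middle arc angle, degrees (gantry angle at the arc center).
#' @param arc_length total arc length, degrees; the arc spans
#'   `theta_c - arc_length/2` to `theta_c + arc_length/2`.
#' @param angular_step angular spacing between projections, degrees.
#' @return An object of class `arc_spec`.
#' @export
arc_spec <- function(theta_c, arc_length, angular_step = 0.5) {
  stopifnot(is.numeric(theta_c), is.numeric(arc_length), is.numeric(angular_step))
  if (arc_length <= 0) stop("arc_length must be > 0")
  if (angular_step <= 0) stop("angular_step must be > 0")
  if (angular_step > arc_length) stop("angular_step must not exceed arc_length")
  structure(list(theta_c = as.numeric(theta_c),
                 arc_length = as.numeric(arc_length),
                 angular_step = as.numeric(angular_step)),
            class = "arc_spec")
}

#' Gantry angles of an arc
#'
#' Evenly spaced angles from `theta_c - arc_length/2` to
#' `theta_c + arc_length/2` inclusive; the count is
#' `floor(arc_length/angular_step) + 1`. Returned values are reduced modulo
#' 360 degrees; the monotone (unwrapped) sequence is available with
#' `unwrapped = TRUE`.
#'
#' @param arc an [arc_spec()].
#' @param unwrapped return the strictly increasing unreduced sequence.
#' @return Numeric vector of gantry angles in degrees.
#' @export
arc_angles <- function(arc, unwrapped = FALSE) {
  stopifnot(inherits(arc, "arc_spec"))
  n <- floor(arc$arc_length / arc$angular_step + 1e-9) + 1
  a <- arc$theta_c - arc$arc_length / 2 + (seq_len(n) - 1) * arc$angular_step
  if (unwrapped) a else a %% 360
}

#' Beam frame of a gantry angle
#'
#' Orthonormal triad attached to the central beam of an arc: `w` points from
#' the source toward the isocenter, `v` is the longitudinal room axis, and
#' `u = w x v` completes the in-plane detector row direction. DTS volumes
#' are sliced along `w` with slices in the (u, v) plane.
#'
#' @param theta_c gantry angle, degrees.
#' @return A 3x3 matrix with columns `u`, `v`, `w` (class `beam_frame`).
#' @export
beam_frame <- function(theta_c) {
  t <- theta_c * pi / 180
  w <- c(-sin(t), 0, -cos(t))
  v <- c(0, 1, 0)
  u <- c(w[2] * v[3] - w[3] * v[2],
         w[3] * v[1] - w[1] * v[3],
         w[1] * v[2] - w[2] * v[1])
  f <- cbind(u = u, v = v, w = w)
  rownames(f) <- c("x", "y", "z")
  class(f) <- c("beam_frame", class(f))
  f
}

#' Source position for a gantry angle
#'
#' @param theta gantry angle, degrees.
#' @param sad source-to-isocenter distance, mm.
#' @return Room coordinates of the kV source, mm.
#' @export
source_position <- function(theta, sad) {
  t <- theta * pi / 180
  sad * c(sin(t), 0, cos(t))
}

# Detector center, axes and source for one projection angle, room coords.
projection_frame <- function(theta, geom) {
  f <- beam_frame(theta)
  S <- source_position(theta, geom$sad)
  list(src = S,
       det_center = (geom$sid - geom$sad) * f[, "w"],
       e1 = f[, "u"], e2 = f[, "v"], w = f[, "w"])
}

#' Project a room point onto the detector
#'
#' Pinhole (perspective) projection of a 3D point through the kV source onto
#' the detector plane, with detector coordinates centered on the central ray.
#'
#' @param p 3-vector, room coordinates mm.
#' @param gantry_angle gantry angle, degrees.
#' @param geom an [acquisition_geometry()].
#' @return 2-vector of detector coordinates (u, v) in mm.
#' @export
project_point <- function(p, gantry_angle, geom) {
  stopifnot(length(p) == 3, inherits(geom, "acquisition_geometry"))
  pf <- projection_frame(gantry_angle, geom)
  dp <- as.numeric(p) - pf$src
  denom <- sum(dp * pf$w)
  if (denom <= 0) stop("point lies at or behind the source plane")
  X <- pf$src + (geom$sid / denom) * dp
  q <- X - pf$det_center
  c(u = sum(q * pf$e1), v = sum(q * pf$e2))
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("Cone-beam geometry: sad %.0f mm, sid %.0f mm (magnification %.2f)\n",
              x$sad, x$sid, x$sid / x$sad))
  cat(sprintf("Detector: %.0f x %.0f mm, %d x %d pixels (%.2f mm pitch)\n",
              x$detector_size[1], x$detector_size[2],
              x$detector_pixels[1], x$detector_pixels[2], x$pixel_mm[1]))
  invisible(x)
}

#' @export
print.arc_spec <- function(x, ...) {
  cat(sprintf("DTS arc: theta_c %.1f deg, arc length %.1f deg, step %.2f deg (%d projections)\n",
              x$theta_c %% 360, x$arc_length, x$angular_step,
              length(arc_angles(x))))
  invisible(x)
}
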
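#' Hounsfield to linear attenuation
#'
#' Linear rescaling of the CT number to an attenuation coefficient,
#' `mu = mu_water * (1 + hu/1000)`, clamped at zero (air maps to zero).
#'
#' @param hu Hounsfield values (>= -1000).
#' @param mu_water attenuation of water, mm^-1.
#' @return Attenuation coefficients, mm^-1.
#' @export
hu_to_mu <- function(hu, mu_water = 0.02) {
  if (any(hu < -1000)) stop("hu values below -1000 are not physical")
  pmax(0, mu_water * (1 + hu / 1000))
}

# Source/detector description for projecting `vol`: if the volume carries a
# beam frame (resliced CT), room-frame positions are rotated into it.
vol_projection_frame <- function(vol, theta, geom) {
  pf <- projection_frame(theta, geom)
  fr <- attr(vol, "frame")
  if (is.null(fr)) return(pf)
  R <- unclass(fr)  # columns u, v, w: room <- beam
  list(src = drop(crossprod(R, pf$src)),
       det_center = drop(crossprod(R, pf$det_center)),
       e1 = drop(crossprod(R, pf$e1)),
       e2 = drop(crossprod(R, pf$e2)),
       w = drop(crossprod(R, pf$w)))
}

#' Simulate one cone-beam projection
#'
#' Computes the line integral of the attenuation volume (`hu_to_mu` of the
#' CT) from the source to each detector pixel, sampling trilinearly along
#' each ray at steps of at most half the smallest voxel size. Rays are
#' clipped to the volume bounding box; rays that miss the volume integrate
#' to zero.
#'
#' @param vol a [ct_volume()] (optionally beam-frame resliced).
#' @param angle gantry angle, degrees.
#' @param geom an [acquisition_geometry()].
#' @param step integration step, mm; default half the smallest voxel size.
#' @param mu_water attenuation of water, mm^-1.
#' @return A matrix of line integrals (class `dts_projection`) with the
#'   gantry angle and geometry attached as attributes.
#' @export
forward_project <- function(vol, angle, geom, step = NULL, mu_water = 0.02) {
  stopifnot(inherits(vol, "ct_volume"), inherits(geom, "acquisition_geometry"))
  if (is.null(step)) step <- min(vol$spacing) / 2
  pf <- vol_projection_frame(vol, angle, geom)
  # the whole volume must sit in front of the source plane
  n <- dim(vol$voxels)
  corners <- as.matrix(expand.grid(c(0, n[1] - 1), c(0, n[2] - 1), c(0, n[3] - 1)))
  corners <- sweep(sweep(corners, 2, vol$spacing, "*"), 2, vol$origin, "+")
  depth <- sweep(corners, 2, pf$src) %*% pf$w
  if (any(depth <= 0))
    stop(sprintf("volume extends behind the source at gantry angle %.1f", angle))
  mu <- hu_to_mu(vol$voxels, mu_water)
  dim(mu) <- n
  px <- cpp_drr(mu, vol$spacing, vol$origin, pf$src, pf$det_center,
                pf$e1, pf$e2, geom$detector_pixels, geom$pixel_mm, step)
  structure(px, gantry_angle = angle %% 360, geom = geom,
            class = c("dts_projection", class(px)))
}

#' Acquire a projection set over a short arc
#'
#' One projection per [arc_angles()] entry, with optional i.i.d. additive
#' Gaussian noise on the line integrals. With a seed the result is
#' reproducible; the caller's RNG state is left untouched.
#'
#' @param vol a [ct_volume()].
#' @param arc an [arc_spec()].
#' @param geom an [acquisition_geometry()].
#' @param noise_sigma standard deviation of the additive noise on the line
#'   integrals (dimensionless); 0 disables noise.
#' @param seed integer seed for the noise, or NULL.
#' @param step ray integration step, mm (see [forward_project()]).
#' @return An object of class `projection_set`: pixel array
#'   (nu x nv x n_projections), per-projection angles, arc, geometry.
#' @export
acquire_arc <- function(vol, arc, geom, noise_sigma = 0.01, seed = NULL,
                        step = NULL) {
  stopifnot(inherits(arc, "arc_spec"))
  ang <- arc_angles(arc, unwrapped = TRUE)
  pix <- array(0, dim = c(geom$detector_pixels, length(ang)))
  for (k in seq_along(ang)) {
    p <- tryCatch(forward_project(vol, ang[k], geom, step = step),
                  error = function(e)
                    stop(sprintf("projection at gantry angle %.1f failed: %s",
                                 ang[k] %% 360, conditionMessage(e))))
    pix[, , k] <- p
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) {
      rng <- get_rng_state()
      on.exit(set_rng_state(rng), add = TRUE)
      set.seed(as.integer(seed))
    }
    pix <- pix + rnorm(length(pix), sd = noise_sigma)
  }
  structure(list(pixels = pix, angles = ang %% 360, angles_unwrapped = ang,
                 arc = arc, geom = geom, noise_sigma = noise_sigma,
                 seed = seed),
            class = "projection_set")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("Projection set: %d projections, theta_c %.1f deg, arc %.1f deg, noise sigma %g\n",
              length(x$angles), x$arc$theta_c %% 360, x$arc$arc_length,
              x$noise_sigma))
  invisible(x)
}
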
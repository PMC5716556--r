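#' DTS reconstruction configuration
#'
#' @param initial_depth depth extent of the initial back-projected stack, mm.
#'   The extra depth provides out-of-plane slices for the deblurring step.
#' @param final_volume final reconstructed extent (u, v, depth), mm.
#'   Treatment volumes default to 60 x 60 x 75 mm; reference volumes use
#'   60 x 60 x 33 mm (see [reference_config()]).
#' @param slice_spacing spacing between reconstructed slices along the beam
#'   depth, mm.
#' @param deblur_fraction fraction (0, 1] of the initial stack used as the
#'   deblurring window.
#' @param in_plane_pixel in-plane pixel size of the reconstructed slices, mm.
#' @param in_plane_margin extra in-plane margin reconstructed around the
#'   final volume and cropped after deblurring, mm. It absorbs warp edge
#'   effects of the deblurring step.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(initial_depth = 150, final_volume = c(60, 60, 75),
                         slice_spacing = 3, deblur_fraction = 1,
                         in_plane_pixel = 1, in_plane_margin = 12) {
  stopifnot(length(final_volume) == 3)
  if (slice_spacing <= 0) stop("slice_spacing must be > 0")
  if (deblur_fraction <= 0 || deblur_fraction > 1)
    stop("deblur_fraction must lie in (0, 1]")
  if (final_volume[3] > initial_depth)
    stop("final depth must not exceed initial_depth")
  structure(list(initial_depth = initial_depth,
                 final_volume = as.numeric(final_volume),
                 slice_spacing = slice_spacing,
                 deblur_fraction = deblur_fraction,
                 in_plane_pixel = in_plane_pixel,
                 in_plane_margin = in_plane_margin),
            class = "recon_config")
}

#' Reference-volume variant of a reconstruction configuration
#'
#' Copies a treatment [recon_config()] with the final depth replaced by the
#' reference default (33 mm), so a reference DTS shares slice spacing, pixel
#' size and deblurring with the treatment DTS it is matched against.
#'
#' @param cfg a [recon_config()].
#' @param final_depth final reference depth, mm.
#' @return A `recon_config`.
#' @export
reference_config <- function(cfg = recon_config(), final_depth = 33) {
  cfg$final_volume[3] <- min(final_depth, cfg$initial_depth)
  cfg
}

# Odd voxel count covering `extent` at pitch `h` (isocenter-centered grid).
odd_count <- function(extent, h) {
  n <- as.integer(ceiling(extent / h - 1e-9))
  n + (1L - n %% 2L)
}

centered_coords <- function(n, h) (seq_len(n) - (n + 1) / 2) * h

# Coherent fraction of a point structure at depth offset `dd`: the share of
# the arc's back-projected copies that still fall within one in-plane pixel
# of the true position. f(0) = 1; f decays as the offset grows, faster for
# longer arcs. Governs both the deblurring guard band (offsets with f >= 1/2
# carry mostly-focused duplicates of the in-focus content) and the
# redundancy normalizer (sum of f over the stack: how many times a point is
# counted across the raw slices).
coherent_fraction <- function(dd, phis, pixel) {
  vapply(abs(dd), function(d)
    mean(abs(d * tan(phis)) <= pixel / 2), numeric(1))
}

#' Shift-and-add back-projection
#'
#' Back-projects a projection set onto a stack of beam-aligned depth planes
#' spanning `initial_depth`, centered on the isocenter. Each voxel value is
#' the mean over projections of the projection image sampled (bilinearly)
#' where the source-to-voxel ray meets the detector; voxels that project off
#' the detector in some projections average over the remaining ones, and a
#' coverage count is kept. Structures lying in a given plane are in focus in
#' that plane; structures elsewhere smear along the arc direction.
#'
#' @param ps a [projection_set()][acquire_arc].
#' @param cfg a [recon_config()].
#' @return An object of class `dts_raw_stack` (in-plane grid includes the
#'   deblurring margin; depth grid spans the initial depth).
#' @export
backproject <- function(ps, cfg = recon_config()) {
  stopifnot(inherits(ps, "projection_set"), inherits(cfg, "recon_config"))
  ang <- ps$angles_unwrapped
  if (length(ang) < 2) stop("back-projection needs at least 2 projections")
  geom <- ps$geom
  theta_c <- ps$arc$theta_c
  fr <- beam_frame(theta_c)
  nu <- odd_count(cfg$final_volume[1] + 2 * cfg$in_plane_margin, cfg$in_plane_pixel)
  nv <- odd_count(cfg$final_volume[2] + 2 * cfg$in_plane_margin, cfg$in_plane_pixel)
  nd <- odd_count(cfg$initial_depth, cfg$slice_spacing)
  ucoord <- centered_coords(nu, cfg$in_plane_pixel)
  vcoord <- centered_coords(nv, cfg$in_plane_pixel)
  depth <- centered_coords(nd, cfg$slice_spacing)
  pf <- lapply(ang, projection_frame, geom = geom)
  srcs <- t(vapply(pf, `[[`, numeric(3), "src"))
  dcs <- t(vapply(pf, `[[`, numeric(3), "det_center"))
  e1s <- t(vapply(pf, `[[`, numeric(3), "e1"))
  e2s <- t(vapply(pf, `[[`, numeric(3), "e2"))
  bp <- cpp_backproject(ps$pixels, srcs, dcs, e1s, e2s, geom$pixel_mm,
                        ucoord, vcoord, depth,
                        fr[, "u"], fr[, "v"], fr[, "w"])
  structure(list(stack = bp$stack, coverage = bp$coverage,
                 ucoord = ucoord, vcoord = vcoord, depth = depth,
                 frame = fr, theta_c = theta_c, arc = ps$arc, geom = geom,
                 cfg = cfg, phis = (ang - theta_c) * pi / 180),
            class = "dts_raw_stack")
}

#' Selective-plane deblurring of a back-projected stack
#'
#' For each output slice an out-of-plane estimate is built from the other
#' slices of the initial stack: every slice inside the deblurring window
#' (a centered window covering `deblur_fraction` of the initial depth) but
#' outside the in-focus guard band is warped to the output slice's geometry
#' along the exact back-projection rays, summed, normalized by the focus
#' redundancy of the stack, and subtracted. The guard band is the set of
#' depth offsets whose angular spread is below one in-plane pixel: those
#' slices carry near-duplicates of the in-focus content and are excluded so
#' the subtraction removes out-of-plane structure, not the in-focus signal;
#' their count is the redundancy normalizer. The result is cropped to the
#' final volume. A window that holds no slice beyond the guard band leaves
#' the stack unchanged (identity).
#'
#' @param raw a `dts_raw_stack` from [backproject()].
#' @param cfg a [recon_config()]; defaults to the stack's own.
#' @param kind `"treatment"` or `"reference"` label for the result.
#' @return An object of class `dts_volume`.
#' @export
deblur <- function(raw, cfg = raw$cfg, kind = "treatment") {
  stopifnot(inherits(raw, "dts_raw_stack"))
  nd <- length(raw$depth)
  ndf <- odd_count(cfg$final_volume[3], cfg$slice_spacing)
  ndf <- min(ndf, nd)
  out_idx <- (nd + 1) / 2 + seq(-(ndf - 1) / 2, (ndf - 1) / 2)
  dd <- abs(raw$depth - raw$depth[(nd + 1) / 2])
  f <- coherent_fraction(dd, raw$phis, cfg$in_plane_pixel)
  guard <- max(0, dd[f >= 0.5])
  win_half <- cfg$deblur_fraction * cfg$initial_depth / 2
  st <- cpp_deblur(raw$stack, raw$ucoord, raw$vcoord, raw$depth,
                   raw$phis, raw$geom$sad, win_half, guard,
                   as.integer(out_idx))
  # crop the in-plane margin
  nuf <- odd_count(cfg$final_volume[1], cfg$in_plane_pixel)
  nvf <- odd_count(cfg$final_volume[2], cfg$in_plane_pixel)
  iu <- (length(raw$ucoord) + 1) / 2 + seq(-(nuf - 1) / 2, (nuf - 1) / 2)
  iv <- (length(raw$vcoord) + 1) / 2 + seq(-(nvf - 1) / 2, (nvf - 1) / 2)
  structure(list(slices = st[iu, iv, , drop = FALSE],
                 ucoord = raw$ucoord[iu], vcoord = raw$vcoord[iv],
                 depth = raw$depth[out_idx],
                 slice_spacing = cfg$slice_spacing,
                 in_plane_pixel = cfg$in_plane_pixel,
                 frame = raw$frame, theta_c = raw$theta_c, arc = raw$arc,
                 kind = kind, deblur_fraction = cfg$deblur_fraction,
                 cfg = cfg),
            class = "dts_volume")
}

#' Reconstruct a treatment DTS volume
#'
#' Shift-and-add back-projection of an acquired arc followed by
#' selective-plane deblurring, cropped to the final treatment volume.
#'
#' @inheritParams backproject
#' @return A `dts_volume` with `kind = "treatment"`.
#' @export
reconstruct_treatment_dts <- function(ps, cfg = recon_config()) {
  deblur(backproject(ps, cfg), cfg, kind = "treatment")
}

#' Reslice a CT volume into a beam-aligned grid
#'
#' Trilinear resampling of the CT onto a grid aligned with the beam frame
#' (axes u, v, w), centered on the isocenter, covering the reconstruction
#' in-plane extent (plus margin) and the initial back-projection depth.
#' Samples outside the CT grid are air; the reconstruction core (the final
#' in-plane plane at the isocenter depth and the central beam segment over
#' the final depth) must be covered by the CT, otherwise an error names the
#' uncovered points.
#'
#' @param vol a [ct_volume()] in room coordinates.
#' @param frame a [beam_frame()].
#' @param cfg a [recon_config()].
#' @param depth_pitch sampling pitch along the beam depth, mm; defaults to
#'   the smallest CT voxel size.
#' @return A [ct_volume()] whose coordinates live in the beam frame (the
#'   frame is attached as attribute `frame`).
#' @export
reslice_ct <- function(vol, frame, cfg = recon_config(), depth_pitch = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(frame, "beam_frame"))
  if (is.null(depth_pitch)) depth_pitch <- min(vol$spacing)
  nu <- odd_count(cfg$final_volume[1] + 2 * cfg$in_plane_margin, cfg$in_plane_pixel)
  nv <- odd_count(cfg$final_volume[2] + 2 * cfg$in_plane_margin, cfg$in_plane_pixel)
  nw <- odd_count(cfg$initial_depth, depth_pitch)
  ucoord <- centered_coords(nu, cfg$in_plane_pixel)
  vcoord <- centered_coords(nv, cfg$in_plane_pixel)
  wcoord <- centered_coords(nw, depth_pitch)
  R <- unclass(frame)
  # coverage check on the reconstruction core
  hf <- cfg$final_volume / 2
  core <- rbind(cbind(c(-hf[1], hf[1], -hf[1], hf[1], 0, 0),
                      c(-hf[2], -hf[2], hf[2], hf[2], 0, 0),
                      c(0, 0, 0, 0, -hf[3], hf[3])))
  core_room <- core %*% t(R)
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (dim(vol$voxels) - 0.5) * vol$spacing
  bad <- which(apply(core_room, 1, function(p) any(p < lo | p > hi)))
  if (length(bad))
    stop(sprintf(
      "reconstruction volume exits the CT: uncovered beam-frame points %s",
      paste(apply(core[bad, , drop = FALSE], 1,
                  function(p) sprintf("(%g, %g, %g)", p[1], p[2], p[3])),
            collapse = ", ")))
  g <- as.matrix(expand.grid(u = ucoord, v = vcoord, w = wcoord))
  pts <- g %*% t(R)
  vals <- cpp_resample_trilinear(vol$voxels, vol$spacing, vol$origin, pts, -1000)
  out <- ct_volume(array(vals, dim = c(nu, nv, nw)),
                   spacing = c(cfg$in_plane_pixel, cfg$in_plane_pixel, depth_pitch),
                   origin = c(ucoord[1], vcoord[1], wcoord[1]))
  attr(out, "frame") <- frame
  out
}

#' Reconstruct a reference DTS volume from a planning CT
#'
#' Runs the reference synthesis path: reslice the planning CT into the beam
#' frame, reproject the resliced volume into noise-free virtual projections
#' (DRRs) at the arc's gantry angles, then back-project and deblur exactly
#' as for a treatment DTS. Matching a treatment DTS against a reference
#' built this way compares volumes of near-identical image character.
#'
#' @param vol the planning [ct_volume()].
#' @param arc an [arc_spec()].
#' @param geom an [acquisition_geometry()].
#' @param cfg a [recon_config()]; the final depth defaults to the reference
#'   value of 33 mm via [reference_config()].
#' @return A `dts_volume` with `kind = "reference"`.
#' @export
reconstruct_reference_dts <- function(vol, arc, geom,
                                      cfg = reference_config()) {
  stopifnot(inherits(arc, "arc_spec"))
  fr <- beam_frame(arc$theta_c)
  rs <- reslice_ct(vol, fr, cfg)
  ang <- arc_angles(arc, unwrapped = TRUE)
  pix <- array(0, dim = c(geom$detector_pixels, length(ang)))
  for (k in seq_along(ang))
    pix[, , k] <- forward_project(rs, ang[k], geom)
  ps <- structure(list(pixels = pix, angles = ang %% 360,
                       angles_unwrapped = ang, arc = arc, geom = geom,
                       noise_sigma = 0, seed = NULL),
                  class = "projection_set")
  deblur(backproject(ps, cfg), cfg, kind = "reference")
}

#' Number of slices in which a clip is observed
#'
#' Counts the reconstructed slices whose maximum value inside the clip's
#' in-plane neighborhood exceeds the local background by more than half of
#' the peak excess over the whole stack. This is the depth extent over
#' which a clip visibly smears in a limited-angle reconstruction (the
#' "effective slice thickness" behavior).
#'
#' @param dts a `dts_volume`.
#' @param center_uv in-plane beam-frame coordinates of the clip, mm.
#' @param radius in-plane neighborhood radius, mm.
#' @return Integer count of slices; the per-slice excess profile is
#'   attached as attribute `profile`.
#' @export
clip_slice_span <- function(dts, center_uv = c(0, 0), radius = 6) {
  stopifnot(inherits(dts, "dts_volume"))
  iu <- which(abs(dts$ucoord - center_uv[1]) <= radius)
  iv <- which(abs(dts$vcoord - center_uv[2]) <= radius)
  ex <- vapply(seq_len(dim(dts$slices)[3]), function(k) {
    sl <- dts$slices[, , k]
    max(sl[iu, iv]) - median(sl)
  }, numeric(1))
  structure(sum(ex > 0.5 * max(ex)), profile = ex)
}

#' @export
print.dts_volume <- function(x, ...) {
  n <- dim(x$slices)
  cat(sprintf(
    "%s DTS volume: %d x %d pixels x %d slices (%.0f x %.0f x %.0f mm)\n",
    x$kind, n[1], n[2], n[3],
    diff(range(x$ucoord)) + x$in_plane_pixel,
    diff(range(x$vcoord)) + x$in_plane_pixel,
    diff(range(x$depth)) + x$slice_spacing))
  cat(sprintf(
    "  theta_c %.1f deg, arc %.1f deg, slice spacing %g mm, deblur fraction %g\n",
    x$theta_c %% 360, x$arc$arc_length, x$slice_spacing, x$deblur_fraction))
  invisible(x)
}
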
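#' Surgical clip specification
#'
#' A clip is modeled as a finite cylinder of uniform Hounsfield value.
#'
#' @param center 3-vector, clip center in room coordinates, mm.
#' @param axis 3-vector, long-axis direction (normalized internally).
#' @param length cylinder length, mm.
#' @param diameter cylinder diameter, mm.
#' @param hu clip Hounsfield value, within [-1000, 4000].
#' @return An object of class `clip_spec`.
#' @export
clip_spec <- function(center, axis = c(0, 1, 0), length = 4, diameter = 1,
                      hu = 1200) {
  stopifnot(base::length(center) == 3, base::length(axis) == 3)
  if (length <= 0 || diameter <= 0) stop("clip length and diameter must be > 0")
  if (hu < -1000 || hu > 4000) stop("clip hu must lie in [-1000, 4000]")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("clip axis must be non-zero")
  structure(list(center = as.numeric(center), axis = as.numeric(axis) / nrm,
                 length = as.numeric(length), diameter = as.numeric(diameter),
                 hu = as.numeric(hu)),
            class = "clip_spec")
}

#' Digital phantom specification
#'
#' A water-equivalent body (box or hemiellipsoid) centered on the isocenter
#' with embedded surgical clips. For `shape = "box"` the body occupies
#' `[-body_size/2, body_size/2]` per axis. For `shape = "hemiellipsoid"`
#' `body_size` is the bounding box of a dome with its flat base facing down
#' (base plane at `z = -body_size[3]/2`, apex at `z = +body_size[3]/2`).
#'
#' @param body_size 3-vector of body extents, mm.
#' @param body_hu Hounsfield value of the body fill (water-equivalent: 0).
#' @param clips list of [clip_spec()] objects; may be empty.
#' @param shape `"box"` or `"hemiellipsoid"`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_size, body_hu = 0, clips = list(),
                         shape = c("box", "hemiellipsoid")) {
  shape <- match.arg(shape)
  stopifnot(length(body_size) == 3, all(body_size > 0))
  if (!is.list(clips)) clips <- list(clips)
  spec <- structure(list(body_size = as.numeric(body_size),
                         body_hu = as.numeric(body_hu),
                         clips = clips, shape = shape),
                    class = "phantom_spec")
  for (i in seq_along(clips)) {
    cl <- clips[[i]]
    if (!inherits(cl, "clip_spec")) stop("clips must be clip_spec objects")
    if (!clip_inside_body(cl, spec))
      stop(sprintf("clip %d (center %s) is not strictly inside the phantom body",
                   i, paste(round(cl$center, 1), collapse = ", ")))
  }
  spec
}

# TRUE when the whole cylinder (endpoints inflated by its radius) lies
# strictly inside the body.
clip_inside_body <- function(clip, spec) {
  r <- clip$diameter / 2
  ends <- rbind(clip$center + clip$axis * clip$length / 2,
                clip$center - clip$axis * clip$length / 2)
  if (spec$shape == "box") {
    half <- spec$body_size / 2
    all(abs(ends) + r < rep(half, each = 2))
  } else {
    a <- spec$body_size[1] / 2 - r
    b <- spec$body_size[2] / 2 - r
    c2 <- spec$body_size[3] - r      # vertical semi-axis from the base
    z0 <- -spec$body_size[3] / 2     # base plane
    ok <- ends[, 3] > z0 + r
    q <- (ends[, 1] / a)^2 + (ends[, 2] / b)^2 + ((ends[, 3] - z0) / c2)^2
    all(ok & q < 1)
  }
}

#' Phantom presets
#'
#' `"rectangular"`: 120 x 200 x 40 mm water-equivalent box with five
#' 1 x 4 mm surgical clips spread around the isocenter.
#' `"breast"`: hemiellipsoidal breast mold stand-in (100 x 100 x 60 mm
#' bounding box) with the same five clips. Clip HU defaults to 1200 and can
#' be overridden per clip with `clip_hu` (recycled across the five clips).
#'
#' @param name `"rectangular"` or `"breast"`.
#' @param clip_hu clip Hounsfield value(s), recycled over the five clips.
#' @return A [phantom_spec()].
#' @export
preset_phantom <- function(name, clip_hu = 1200) {
  if (!is.character(name) || !(name %in% c("rectangular", "breast")))
    stop("unknown phantom preset; valid presets: \"rectangular\", \"breast\"")
  centers <- list(c(0, 0, 0), c(9, 8, 5), c(-8, 6, -6),
                  c(7, -9, 6), c(-8, -8, -7))
  axes <- list(c(0, 1, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 0), c(1, -1, 1))
  hu <- rep_len(clip_hu, 5)
  clips <- lapply(seq_len(5), function(i)
    clip_spec(centers[[i]], axes[[i]], length = 4, diameter = 1, hu = hu[i]))
  if (name == "rectangular")
    phantom_spec(c(120, 200, 40), body_hu = 0, clips = clips, shape = "box")
  else
    phantom_spec(c(100, 100, 60), body_hu = 0, clips = clips,
                 shape = "hemiellipsoid")
}

#' Construct a CT volume container
#'
#' @param voxels 3D array of Hounsfield values.
#' @param spacing 3-vector, mm per voxel.
#' @param origin 3-vector, room coordinates of the center of voxel (1,1,1), mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin) {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

# Voxel-center coordinates along one axis.
vol_axis <- function(vol, a) vol$origin[a] + (seq_len(dim(vol$voxels)[a]) - 1) * vol$spacing[a]

#' Voxelize a phantom specification
#'
#' Renders the body and clips onto a regular HU grid centered on the
#' isocenter. The grid covers the body plus an air margin on every side.
#' Clip cylinders are rendered with partial-volume anti-aliasing: each voxel
#' value is a volume-fraction-weighted blend of clip HU and the local
#' background, the fraction estimated on a regular sub-voxel supersampling
#' lattice. Rendering is deterministic.
#'
#' @param spec a [phantom_spec()].
#' @param voxel_spacing 3-vector, mm per voxel.
#' @param air_margin air margin added around the body, mm.
#' @return A [ct_volume()] carrying the spec and margin as attributes.
#' @export
build_phantom <- function(spec, voxel_spacing = c(1, 1, 1), air_margin = 10) {
  stopifnot(inherits(spec, "phantom_spec"), all(voxel_spacing > 0))
  voxel_spacing <- rep_len(as.numeric(voxel_spacing), 3)
  extent <- spec$body_size + 2 * air_margin
  n <- pmax(1L, as.integer(ceiling(extent / voxel_spacing)))
  n <- n + (1L - n %% 2L)  # odd: a voxel center sits exactly on the isocenter
  origin <- -(n - 1) / 2 * voxel_spacing
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(n[a]) - 1) * voxel_spacing[a])

  # body rendered with anti-aliased faces: boundary voxels blend body and
  # air by their coverage, so line integrals through the body match its
  # physical extent
  if (spec$shape == "box") {
    half <- spec$body_size / 2
    cov <- lapply(1:3, function(a)
      pmin(1, pmax(0, (half[a] - abs(ax[[a]])) / voxel_spacing[a] + 0.5)))
    frac <- outer(outer(cov[[1]], cov[[2]]), cov[[3]])
  } else {
    a <- spec$body_size[1] / 2; b <- spec$body_size[2] / 2
    cc <- spec$body_size[3]; z0 <- -spec$body_size[3] / 2
    q <- outer((ax[[1]] / a)^2, (ax[[2]] / b)^2, "+")
    q <- sqrt(outer(q, ((ax[[3]] - z0) / cc)^2, "+"))
    # approximate signed distance to the dome surface, ramped over a voxel
    h <- mean(voxel_spacing)
    d <- (q - 1) * min(a, b, cc)
    frac <- pmin(1, pmax(0, 0.5 - d / h))
    base <- pmin(1, pmax(0, (ax[[3]] - z0) / mean(voxel_spacing[3]) + 0.5))
    frac <- frac * rep(base, each = n[1] * n[2])
    dim(frac) <- n
  }
  vox <- -1000 * (1 - frac) + spec$body_hu * frac

  # Partial-volume rendering: the volume fraction of each voxel inside the
  # clip cylinder, estimated on an s^3 supersampling lattice per voxel.
  s <- 8L
  oo <- (seq_len(s) - (s + 1) / 2) / s  # sub-voxel offsets, voxel units
  sub_off <- as.matrix(expand.grid(x = oo, y = oo, z = oo))
  for (cl in spec$clips) {
    r <- cl$diameter / 2
    pad <- cl$length / 2 + r + max(voxel_spacing)
    idx <- lapply(1:3, function(a) which(abs(ax[[a]] - cl$center[a]) <= pad))
    if (any(lengths(idx) == 0)) next
    g <- as.matrix(expand.grid(x = ax[[1]][idx[[1]]], y = ax[[2]][idx[[2]]],
                               z = ax[[3]][idx[[3]]]))
    # each sample contributes a coverage ramped over the sub-sample pitch,
    # which suppresses lattice aliasing on thin cylinders
    hsub <- mean(voxel_spacing) / s
    cnt <- numeric(nrow(g))
    for (k in seq_len(nrow(sub_off))) {
      p <- sweep(g, 2, cl$center - sub_off[k, ] * voxel_spacing)
      t_ax <- drop(p %*% cl$axis)
      dr <- sqrt(pmax(0, rowSums(p^2) - t_ax^2)) - r
      dt <- abs(t_ax) - cl$length / 2
      d <- ifelse(dr > 0 | dt > 0,
                  sqrt(pmax(dr, 0)^2 + pmax(dt, 0)^2),
                  pmax(dr, dt))
      cnt <- cnt + pmin(1, pmax(0, 0.5 - d / hsub))
    }
    frac <- cnt / nrow(sub_off)
    sub <- vox[idx[[1]], idx[[2]], idx[[3]]]
    vox[idx[[1]], idx[[2]], idx[[3]]] <- sub * (1 - frac) + cl$hu * frac
  }
  out <- ct_volume(vox, voxel_spacing, origin)
  attr(out, "phantom_spec") <- spec
  attr(out, "air_margin") <- air_margin
  out
}

#' Rigidly shift a CT volume
#'
#' Returns the volume displaced by `+shift` (the "treatment-day" anatomy):
#' the output at room position x equals the input sampled at x - shift, via
#' trilinear interpolation on the same grid. A registration of the result
#' against the original must therefore report a couch correction equal to
#' `shift`.
#'
#' @param vol a [ct_volume()].
#' @param shift 3-vector (x, y, z), mm.
#' @return A [ct_volume()] of identical shape and spacing.
#' @export
apply_shift <- function(vol, shift) {
  stopifnot(inherits(vol, "ct_volume"), length(shift) == 3, all(is.finite(shift)))
  shift <- as.numeric(shift)
  spec <- attr(vol, "phantom_spec")
  if (!is.null(spec) && length(spec$clips)) {
    lo <- vol$origin
    hi <- vol$origin + (dim(vol$voxels) - 1) * vol$spacing
    for (cl in spec$clips) {
      ends <- rbind(cl$center + cl$axis * cl$length / 2,
                    cl$center - cl$axis * cl$length / 2)
      ends <- sweep(ends, 2, shift, "+")
      if (any(sweep(ends, 2, lo) < 0) || any(sweep(ends, 2, hi) > 0))
        stop("shift would move a clip outside the volume grid")
    }
  }
  if (all(shift == 0)) return(vol)
  n <- dim(vol$voxels)
  ax <- lapply(1:3, function(a) vol_axis(vol, a) - shift[a])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- cpp_resample_trilinear(vol$voxels, vol$spacing, vol$origin, pts, -1000)
  out <- ct_volume(array(vals, dim = n), vol$spacing, vol$origin)
  if (!is.null(spec)) {
    spec$clips <- lapply(spec$clips, function(cl) { cl$center <- cl$center + shift; cl })
    attr(out, "phantom_spec") <- spec
    attr(out, "air_margin") <- attr(vol, "air_margin")
  }
  out
}

#' @export
print.ct_volume <- function(x, ...) {
  n <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              n[1], n[2], n[3], paste(round(x$spacing, 2), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom: %s body %s mm, fill %g HU, %d clip(s)\n",
              x$shape, paste(x$body_size, collapse = " x "), x$body_hu,
              length(x$clips)))
  for (cl in x$clips)
    cat(sprintf("  clip at (%s) mm: %g x %g mm, %g HU\n",
                paste(round(cl$center, 1), collapse = ", "),
                cl$diameter, cl$length, cl$hu))
  invisible(x)
}
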
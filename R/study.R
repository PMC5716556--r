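#' Per-axis registration accuracy
#'
#' @param found recovered shift, 3-vector mm.
#' @param applied known applied shift, 3-vector mm.
#' @return Named vector: absolute per-axis differences (x, y, z) and the 3D
#'   Euclidean magnitude, mm.
#' @export
evaluate_error <- function(found, applied) {
  stopifnot(length(found) == 3, length(applied) == 3,
            all(is.finite(found)), all(is.finite(applied)))
  d <- abs(as.numeric(found) - as.numeric(applied))
  c(x = d[1], y = d[2], z = d[3], magnitude = sqrt(sum(d^2)))
}

#' Parameter sweep configuration
#'
#' Defines a factorial accuracy study: for every combination of arc length,
#' arc separation and slice spacing, and for every applied shift, the full
#' pipeline (shift phantom, acquire arcs, reconstruct, match, triangulate)
#' is run and the per-axis error against the known shift recorded.
#'
#' @param phantom a [phantom_spec()] or a [preset_phantom()] name.
#' @param arc_lengths arc lengths to sweep, degrees.
#' @param separations arc separations to sweep, degrees.
#' @param slice_spacings reconstruction slice spacings, mm.
#' @param shifts list of applied shifts (3-vectors, mm), or NULL to draw
#'   `n_shifts` random shifts uniform in [-max_shift, max_shift] per axis.
#' @param n_shifts number of random shifts when `shifts` is NULL.
#' @param max_shift random-shift amplitude per axis, mm (kept inside the
#'   search half-width).
#' @param seed integer seed for shift generation and projection noise.
#' @param noise_sigma projection noise level (see [acquire_arc()]).
#' @param base_theta_c middle arc angle of the first arc, degrees; further
#'   arcs sit at `base_theta_c + k * separation`.
#' @param n_arcs number of arcs triangulated per registration.
#' @param deblur_fraction deblurring window fraction.
#' @param geom an [acquisition_geometry()].
#' @param voxel_spacing phantom voxelization pitch, mm.
#' @param angular_step projection spacing along each arc, degrees.
#' @param recon named list of [recon_config()] overrides (e.g.
#'   `initial_depth`, `final_volume`, `in_plane_pixel`) applied to every
#'   cell; `slice_spacing` and `deblur_fraction` come from the sweep axes.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(phantom = "rectangular", arc_lengths = c(5, 10, 20),
                         separations = seq(10, 90, by = 10),
                         slice_spacings = 3, shifts = NULL, n_shifts = 5,
                         max_shift = 5, seed = 1, noise_sigma = 0.01,
                         base_theta_c = 305, n_arcs = 2, deblur_fraction = 1,
                         geom = acquisition_geometry(),
                         voxel_spacing = c(1, 1, 1), angular_step = 0.5,
                         recon = list()) {
  if (is.character(phantom)) phantom <- preset_phantom(phantom)
  stopifnot(inherits(phantom, "phantom_spec"),
            length(arc_lengths) >= 1, length(separations) >= 1,
            length(slice_spacings) >= 1, n_arcs >= 1)
  if (!is.null(shifts)) {
    if (!is.list(shifts)) shifts <- list(shifts)
    stopifnot(all(vapply(shifts, length, integer(1)) == 3))
  }
  structure(list(phantom = phantom, arc_lengths = arc_lengths,
                 separations = separations, slice_spacings = slice_spacings,
                 shifts = shifts, n_shifts = n_shifts, max_shift = max_shift,
                 seed = as.integer(seed), noise_sigma = noise_sigma,
                 base_theta_c = base_theta_c, n_arcs = n_arcs,
                 deblur_fraction = deblur_fraction, geom = geom,
                 voxel_spacing = voxel_spacing, angular_step = angular_step,
                 recon = recon),
            class = "sweep_config")
}

#' Run an accuracy parameter sweep
#'
#' Full factorial over arc length x separation x slice spacing x applied
#' shift. Reference DTS volumes are reconstructed once per (arc orientation,
#' arc length, slice spacing) and reused across shifts. Per-cell failures
#' (e.g. a failed cross-correlation match) are recorded as failed rows with
#' the reason and never abort the sweep. The same configuration and seed
#' reproduce the same result.
#'
#' @param cfg a [sweep_config()].
#' @param mcfg a [match_config()].
#' @param verbose print per-cell progress.
#' @return A data frame of class `sweep_result`, one row per parameter
#'   combination x shift, with applied/found shifts, per-axis errors,
#'   correlation scores, validity and triangulation conditioning.
#' @export
run_sweep <- function(cfg = sweep_config(), mcfg = match_config(),
                      verbose = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  planning <- build_phantom(cfg$phantom, cfg$voxel_spacing)
  shifts <- cfg$shifts
  if (is.null(shifts)) {
    rng <- get_rng_state()
    set.seed(cfg$seed)
    shifts <- lapply(seq_len(cfg$n_shifts), function(i)
      runif(3, -cfg$max_shift, cfg$max_shift))
    set_rng_state(rng)
  }
  ref_cache <- new.env(parent = emptyenv())
  rows <- list()
  noise_counter <- 0L
  for (sp in cfg$slice_spacings) for (L in cfg$arc_lengths)
    for (S in cfg$separations) {
      rcfg <- do.call(recon_config,
                      modifyList(list(slice_spacing = sp,
                                      deblur_fraction = cfg$deblur_fraction),
                                 cfg$recon))
      arcs <- lapply(seq_len(cfg$n_arcs) - 1, function(k)
        arc_spec(cfg$base_theta_c + k * S, L, cfg$angular_step))
      refs <- lapply(arcs, function(a) {
        key <- sprintf("%.3f_%g_%g", a$theta_c %% 360, L, sp)
        if (is.null(ref_cache[[key]]))
          ref_cache[[key]] <- reconstruct_reference_dts(
            planning, a, cfg$geom, reference_config(rcfg))
        ref_cache[[key]]
      })
      frefs <- lapply(refs, prefilter, sigma = mcfg$gaussian_sigma)
      for (si in seq_along(shifts)) {
        s <- shifts[[si]]
        noise_counter <- noise_counter + 1L
        row <- data.frame(arc_length = L, separation = S, slice_spacing = sp,
                          shift_id = si, applied_x = s[1], applied_y = s[2],
                          applied_z = s[3], found_x = NA_real_,
                          found_y = NA_real_, found_z = NA_real_,
                          err_x = NA_real_, err_y = NA_real_, err_z = NA_real_,
                          err_3d = NA_real_, min_ncc = NA_real_,
                          n_valid = 0L, condition = NA_real_,
                          failed = TRUE, reason = "")
        res <- tryCatch({
          tvol <- apply_shift(planning, s)
          matches <- vector("list", length(arcs))
          for (ai in seq_along(arcs)) {
            ps <- acquire_arc(tvol, arcs[[ai]], cfg$geom,
                              noise_sigma = cfg$noise_sigma,
                              seed = cfg$seed + 1000L * noise_counter + ai)
            trt <- prefilter(reconstruct_treatment_dts(ps, rcfg),
                             mcfg$gaussian_sigma)
            amcfg <- mcfg
            if (is.null(amcfg$template_center)) {
              amcfg$template_center <-
                clips_centroid_beam(planning, frefs[[ai]]$frame)
              amcfg$.clamp <- TRUE
            }
            matches[[ai]] <- match_template(frefs[[ai]], trt, amcfg)
          }
          triangulate(matches)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          row$reason <- conditionMessage(res)
        } else {
          err <- evaluate_error(res$shift, s)
          row[c("found_x", "found_y", "found_z")] <- as.list(res$shift)
          row[c("err_x", "err_y", "err_z", "err_3d")] <- as.list(err)
          row$min_ncc <- min(vapply(res$matches, `[[`, numeric(1), "ncc"))
          row$n_valid <- sum(vapply(res$matches, `[[`, logical(1), "valid"))
          row$condition <- res$condition
          row$failed <- FALSE
        }
        rows[[length(rows) + 1L]] <- row
        if (verbose)
          message(sprintf(
            "arc %g deg, sep %g deg, spacing %g mm, shift %d: %s", L, S, sp,
            si, if (row$failed) row$reason else sprintf("err %.2f mm", row$err_3d)))
      }
    }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  attr(out, "config") <- cfg
  out
}

#' Mean per-axis error grid of a sweep
#'
#' Summarizes a sweep into the separation x arc-length x axis grid of mean
#' absolute errors (failed rows excluded).
#'
#' @param x a [run_sweep()] result.
#' @return A 3D array (separations x arc lengths x axes x/y/z), mm.
#' @export
sweep_grid <- function(x) {
  stopifnot(inherits(x, "sweep_result"))
  seps <- sort(unique(x$separation), decreasing = TRUE)
  lens <- sort(unique(x$arc_length), decreasing = TRUE)
  g <- array(NA_real_, dim = c(length(seps), length(lens), 3),
             dimnames = list(separation = seps, arc_length = lens,
                             axis = c("x", "y", "z")))
  ok <- !x$failed
  for (i in seq_along(seps)) for (j in seq_along(lens)) {
    sel <- ok & x$separation == seps[i] & x$arc_length == lens[j]
    if (any(sel)) {
      g[i, j, 1] <- mean(x$err_x[sel])
      g[i, j, 2] <- mean(x$err_y[sel])
      g[i, j, 3] <- mean(x$err_z[sel])
    }
  }
  g
}

#' @export
summary.sweep_result <- function(object, ...) {
  ok <- !object$failed
  agg <- aggregate(cbind(err_x, err_y, err_z, err_3d) ~
                     arc_length + separation + slice_spacing,
                   data = object[ok, , drop = FALSE], FUN = mean)
  attr(agg, "n_failed") <- sum(!ok)
  agg
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("DTS accuracy sweep: %d runs (%d failed)\n",
              nrow(x), sum(x$failed)))
  cat(sprintf("  arc lengths %s deg; separations %s deg; slice spacings %s mm\n",
              paste(sort(unique(x$arc_length)), collapse = "/"),
              paste(sort(unique(x$separation)), collapse = "/"),
              paste(sort(unique(x$slice_spacing)), collapse = "/")))
  ok <- !x$failed
  if (any(ok))
    cat(sprintf("  mean 3D error %.2f mm (range %.2f-%.2f)\n",
                mean(x$err_3d[ok]), min(x$err_3d[ok]), max(x$err_3d[ok])))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  ok <- !x$failed
  agg <- aggregate(err_3d ~ arc_length + separation,
                   data = x[ok, , drop = FALSE], FUN = mean)
  lens <- sort(unique(agg$arc_length))
  seps <- sort(unique(agg$separation))
  m <- sapply(lens, function(L)
    sapply(seps, function(S) {
      v <- agg$err_3d[agg$arc_length == L & agg$separation == S]
      if (length(v)) v else NA_real_
    }))
  matplot(seps, m, type = "b", pch = 19, lty = 1,
          xlab = "arc separation (deg)", ylab = "mean 3D error (mm)",
          main = "Registration accuracy vs arc separation", ...)
  legend("topright", legend = sprintf("arc %g deg", lens), col = seq_along(lens),
         lty = 1, pch = 19, bty = "n")
  invisible(x)
}
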
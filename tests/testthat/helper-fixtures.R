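# Shared fixtures, built once per test run and cached across test files.
# Unit tests use a compact geometry (small detector, 2 mm reconstruction
# pixels, short stacks) so each reconstruction takes a second or two; the
# acceptance tests use the full study conditions.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- expr
  .fixtures[[name]]
}

# 81x81 detector, 1 mm pitch: odd pixel count puts a pixel center on the
# central ray, which the slab oracles rely on.
small_geom <- function() acquisition_geometry(detector_size = c(81, 81),
                                              detector_pixels = c(81, 81))

# wider small detector for reconstruction tests at 2 mm pixels
recon_geom <- function() acquisition_geometry(detector_size = c(162, 162),
                                              detector_pixels = c(81, 81))

small_recon_cfg <- function(...) {
  do.call(recon_config,
          modifyList(list(initial_depth = 60, final_volume = c(40, 40, 40),
                          slice_spacing = 2, in_plane_pixel = 2,
                          in_plane_margin = 8),
                     list(...)))
}

# water cube with one bright clip at the isocenter
one_clip_phantom <- function() {
  fixture("one_clip_phantom", {
    spec <- phantom_spec(c(70, 70, 70), body_hu = 0,
                         clips = list(clip_spec(c(0, 0, 0), c(0, 1, 0),
                                                length = 2, diameter = 2,
                                                hu = 2000)))
    build_phantom(spec, c(1, 1, 1))
  })
}

# reference + treatment DTS pair of the one-clip phantom, 10 degree arc at
# theta_c 0, noise-free
small_pair <- function() {
  fixture("small_pair", {
    vol <- one_clip_phantom()
    arc <- arc_spec(0, 10)
    cfg <- small_recon_cfg()
    ref <- reconstruct_reference_dts(vol, arc, recon_geom(),
                                     reference_config(cfg, final_depth = 28))
    ps <- acquire_arc(vol, arc, recon_geom(), noise_sigma = 0, seed = 1)
    trt <- reconstruct_treatment_dts(ps, cfg)
    list(ref = ref, trt = trt, vol = vol, arc = arc, cfg = cfg)
  })
}

# in-plane integer translation of a DTS volume (voxels shifted within the
# grid, zero-filled at the edges) for known-translation oracles
translate_dts <- function(v, du = 0, dv = 0, dw = 0) {
  s <- array(0, dim = dim(v$slices))
  n <- dim(v$slices)
  src <- list(seq_len(n[1]) - du, seq_len(n[2]) - dv, seq_len(n[3]) - dw)
  ok <- lapply(seq_len(3), function(a) src[[a]] >= 1 & src[[a]] <= n[a])
  s[ok[[1]], ok[[2]], ok[[3]]] <-
    v$slices[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  v$slices <- s
  v
}

# compact sweep shared by the study and io tests: one small phantom, short
# arcs, modest detector and stack
tiny_sweep_cfg <- function(...) {
  ph <- phantom_spec(c(70, 70, 70), body_hu = 0, clips = list(
    clip_spec(c(0, 0, 0), c(0, 1, 0), 2, 2, 2000),
    clip_spec(c(8, 6, 4), c(1, 0, 0), 2, 2, 2000),
    clip_spec(c(-7, -6, -5), c(0, 1, 1), 2, 2, 2000)))
  sweep_config(phantom = ph, arc_lengths = 10, separations = c(10, 20),
               slice_spacings = 2, shifts = list(c(2, -1, 1.5)),
               noise_sigma = 0, base_theta_c = 0, geom = recon_geom(),
               recon = list(initial_depth = 60, final_volume = c(40, 40, 40),
                            in_plane_pixel = 2, in_plane_margin = 8), ...)
}

run_tiny_sweep <- function() {
  fixture("tiny_sweep", run_sweep(tiny_sweep_cfg()))
}

# center of mass of the clip signal, room mm: thresholded mask when `thr`
# is given, excess-weighted otherwise (more stable under sub-voxel shifts)
clip_centroid_mm <- function(vol, thr = NULL) {
  if (is.null(thr)) {
    w <- pmax(vol$voxels, 0)
  } else {
    w <- (vol$voxels > thr) * 1
  }
  idx <- which(w > 0, arr.ind = TRUE)
  stopifnot(nrow(idx) > 0)
  wt <- w[w > 0]
  pos <- sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  unname(colSums(pos * wt) / sum(wt))
}
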
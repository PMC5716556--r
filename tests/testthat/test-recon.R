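test_that("recon_config validates its fields", {
  expect_error(recon_config(slice_spacing = 0), "slice_spacing")
  expect_error(recon_config(deblur_fraction = 0), "deblur_fraction")
  expect_error(recon_config(deblur_fraction = 1.2), "deblur_fraction")
  expect_error(recon_config(initial_depth = 50, final_volume = c(60, 60, 75)),
               "initial_depth")
  ref <- reference_config(recon_config(slice_spacing = 5))
  expect_equal(ref$final_volume[3], 33)
  expect_equal(ref$slice_spacing, 5)
})

test_that("back-projecting zero projections yields a zero stack", {
  g <- recon_geom()
  ps <- structure(list(pixels = array(0, c(g$detector_pixels, 5)),
                       angles = seq(358, 2) %% 360,
                       angles_unwrapped = 358:362,
                       arc = arc_spec(0, 4, 1), geom = g, noise_sigma = 0,
                       seed = NULL),
                  class = "projection_set")
  raw <- backproject(ps, small_recon_cfg())
  expect_true(all(raw$stack == 0))
  expect_true(all(raw$coverage > 0))
})

test_that("back-projection is linear in the projections", {
  vol <- one_clip_phantom()
  g <- recon_geom()
  arc <- arc_spec(0, 6, 1)
  cfg <- small_recon_cfg()
  ps1 <- acquire_arc(vol, arc, g, noise_sigma = 0)
  ps2 <- ps1
  set.seed(5)
  ps2$pixels <- array(runif(length(ps1$pixels)), dim = dim(ps1$pixels))
  mix <- ps1
  a <- 2.5; b <- -0.75
  mix$pixels <- a * ps1$pixels + b * ps2$pixels
  s_mix <- backproject(mix, cfg)$stack
  s_lin <- a * backproject(ps1, cfg)$stack + b * backproject(ps2, cfg)$stack
  expect_equal(s_mix, s_lin, tolerance = 1e-6)
})

test_that("a point clip back-projects into focus at the stack center", {
  pr <- small_pair()
  raw <- backproject(acquire_arc(pr$vol, pr$arc, recon_geom(), 0, seed = 1),
                     pr$cfg)
  ij <- arrayInd(which.max(raw$stack), dim(raw$stack))
  ctr <- (dim(raw$stack) + 1) / 2
  expect_true(all(abs(ij - ctr) <= 1))
})

test_that("depth elongation shrinks as the arc length grows", {
  vol <- one_clip_phantom()
  g <- recon_geom()
  cfg <- small_recon_cfg()
  fwhm <- vapply(c(3, 15), function(L) {
    raw <- backproject(acquire_arc(vol, arc_spec(0, L), g, 0, seed = 1), cfg)
    ctr <- (dim(raw$stack) + 1) / 2
    prof <- raw$stack[ctr[1], ctr[2], ]
    bg <- median(raw$stack)
    sum(prof - bg > (max(prof) - bg) / 2) * cfg$slice_spacing
  }, numeric(1))
  expect_gt(fwhm[1], fwhm[2])
})

test_that("a window holding only the slice itself leaves the stack unchanged", {
  pr <- small_pair()
  raw <- backproject(acquire_arc(pr$vol, pr$arc, recon_geom(), 0, seed = 1),
                     pr$cfg)
  cfg_id <- pr$cfg
  cfg_id$deblur_fraction <- 0.01  # window smaller than one slice spacing
  out <- deblur(raw, cfg_id)
  nuf <- dim(out$slices)[1]
  iu <- match(out$ucoord, raw$ucoord)
  iv <- match(out$vcoord, raw$vcoord)
  ik <- match(out$depth, raw$depth)
  expect_identical(out$slices, raw$stack[iu, iv, ik])
})

test_that("deblurring removes most of an out-of-plane feature's leakage", {
  # two point clips 28 mm apart along the beam axis; at 1 mm pixels the
  # whole guard band lies well inside the separation
  g <- acquisition_geometry(detector_size = c(122, 122),
                            detector_pixels = c(121, 121))
  cfg <- recon_config(initial_depth = 80, final_volume = c(40, 40, 30),
                      slice_spacing = 2, in_plane_pixel = 1,
                      in_plane_margin = 8)
  fr <- unclass(beam_frame(0))
  cB <- 10 * fr[, "u"] - 28 * fr[, "w"]
  sp <- phantom_spec(c(70, 70, 66), body_hu = 0, clips = list(
    clip_spec(c(0, 0, 0), c(0, 1, 0), 2, 2, 2000),
    clip_spec(cB, c(0, 1, 0), 2, 2, 2000)))
  vol <- build_phantom(sp, c(1, 1, 1))
  ps <- acquire_arc(vol, arc_spec(0, 10), g, noise_sigma = 0, seed = 1)
  raw <- backproject(ps, cfg)
  deb <- deblur(raw, cfg)
  near <- function(coord, x) which.min(abs(coord - x))
  leak_amp <- function(slices, uc, vc, dep) {
    k <- near(dep, 0)
    iu <- near(uc, 10); iv <- near(vc, 0)
    max(slices[iu + (-3:3), iv + (-3:3), k]) - median(slices[, , k])
  }
  amp_raw <- leak_amp(raw$stack, raw$ucoord, raw$vcoord, raw$depth)
  amp_deb <- leak_amp(deb$slices, deb$ucoord, deb$vcoord, deb$depth)
  expect_lt(amp_deb, 0.5 * amp_raw)
})

test_that("a full deblurring window gives a quieter background than 20%", {
  vol <- one_clip_phantom()
  g <- recon_geom()
  vars <- vapply(c(0.2, 1.0), function(f) {
    cfg <- small_recon_cfg(deblur_fraction = f)
    ps <- acquire_arc(vol, arc_spec(0, 10), g, noise_sigma = 0.01, seed = 9)
    d <- reconstruct_treatment_dts(ps, cfg)
    ctr <- d$slices[, , (dim(d$slices)[3] + 1) / 2]
    mask <- outer(abs(d$ucoord) > 8, abs(d$vcoord) > 8, "|")
    var(ctr[mask])
  }, numeric(1))
  expect_lt(vars[2], vars[1])
})

test_that("treatment DTS spans the configured final volume", {
  pr <- small_pair()
  d <- pr$trt
  expect_equal(d$kind, "treatment")
  n <- dim(d$slices)
  expect_equal(n, c(21, 21, 21))  # 40 x 40 x 40 mm at 2 mm pitch, odd counts
  expect_true(n[3] %% 2 == 1)  # odd, isocenter-centered
  expect_equal(d$depth[(n[3] + 1) / 2], 0)
  # the default configuration spans the 60 x 60 x 75 mm treatment volume
  expect_equal(c(dtsetup:::odd_count(60, 1), dtsetup:::odd_count(75, 3)),
               c(61, 25))
})

test_that("in-plane clip contrast is stable across slice spacings", {
  vol <- one_clip_phantom()
  g <- recon_geom()
  ps <- acquire_arc(vol, arc_spec(0, 10), g, noise_sigma = 0, seed = 2)
  peaks <- vapply(c(1, 2, 4), function(sp) {
    cfg <- small_recon_cfg(slice_spacing = sp)
    d <- reconstruct_treatment_dts(ps, cfg)
    k <- (dim(d$slices)[3] + 1) / 2
    max(d$slices[, , k]) - median(d$slices[, , k])
  }, numeric(1))
  expect_lt(diff(range(peaks)) / mean(peaks), 0.05)
})

test_that("reslicing at gantry zero permutes the axes exactly", {
  vol <- one_clip_phantom()
  cfg <- small_recon_cfg(in_plane_pixel = 1, in_plane_margin = 5)
  rs <- reslice_ct(vol, beam_frame(0), cfg, depth_pitch = 1)
  # beam coords (u, v, w) map to room (u, v, -w)
  nu <- dim(rs$voxels)
  probe <- expand.grid(iu = c(10, 26, 40), iv = c(12, 25, 39),
                       iw = c(5, 30, 55))
  for (r in seq_len(nrow(probe))) {
    i <- as.numeric(probe[r, ])
    u <- rs$origin[1] + (i[1] - 1) * rs$spacing[1]
    v <- rs$origin[2] + (i[2] - 1) * rs$spacing[2]
    w <- rs$origin[3] + (i[3] - 1) * rs$spacing[3]
    room <- c(u, v, -w)
    j <- round((room - vol$origin) / vol$spacing) + 1
    expect_equal(rs$voxels[i[1], i[2], i[3]],
                 vol$voxels[j[1], j[2], j[3]], tolerance = 1e-9)
  }
})

test_that("reslicing preserves the clip centroid", {
  vol <- one_clip_phantom()
  cfg <- small_recon_cfg()
  fr <- beam_frame(305)
  rs <- reslice_ct(vol, fr, cfg)
  w <- rs$voxels > 600
  idx <- which(w, arr.ind = TRUE)
  beam_ctr <- colSums(sweep(sweep(idx - 1, 2, rs$spacing, "*"),
                            2, rs$origin, "+")) / nrow(idx)
  room_ctr <- unclass(fr) %*% beam_ctr
  # the clip sits at the isocenter
  expect_equal(as.numeric(room_ctr), c(0, 0, 0), tolerance = 0.5)
})

test_that("reslicing a too-small CT names the uncovered points", {
  tiny <- ct_volume(array(0, c(11, 11, 11)), c(1, 1, 1), c(-5, -5, -5))
  expect_error(reslice_ct(tiny, beam_frame(305), small_recon_cfg()),
               "exits the CT")
})

test_that("a uniform CT reconstructs into flat reference slices", {
  g <- recon_geom()
  u <- build_phantom(phantom_spec(c(200, 200, 200)), c(2, 2, 2))
  cfg <- small_recon_cfg()
  ref <- reconstruct_reference_dts(u, arc_spec(0, 10), g,
                                   reference_config(cfg, final_depth = 28))
  ctr <- which(abs(ref$ucoord) <= 12)
  for (k in seq_len(dim(ref$slices)[3])) {
    sl <- ref$slices[ctr, ctr, k]
    expect_lt(max(sl) - min(sl), 1e-3)
  }
})

test_that("reference and treatment DTS of the same scene correlate strongly", {
  pr <- small_pair()
  a <- pr$ref$slices[, , (dim(pr$ref$slices)[3] + 1) / 2]
  b <- pr$trt$slices[, , (dim(pr$trt$slices)[3] + 1) / 2]
  expect_gt(cor(as.numeric(a), as.numeric(b)), 0.9)
  expect_equal(pr$ref$kind, "reference")
})
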
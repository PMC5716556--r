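test_that("rectangular preset matches its published layout", {
  spec <- preset_phantom("rectangular")
  expect_equal(spec$body_size, c(120, 200, 40))
  expect_length(spec$clips, 5)
  for (cl in spec$clips) {
    expect_equal(cl$length, 4)
    expect_equal(cl$diameter, 1)
    expect_equal(cl$hu, 1200)
  }
})

test_that("breast preset accepts per-clip HU overrides", {
  hu <- c(1000, 1100, 1200, 1300, 1350)
  spec <- preset_phantom("breast", clip_hu = hu)
  expect_equal(spec$shape, "hemiellipsoid")
  expect_equal(vapply(spec$clips, `[[`, numeric(1), "hu"), hu)
  expect_true(all(vapply(spec$clips, `[[`, numeric(1), "hu") >= 1000))
  expect_true(all(vapply(spec$clips, `[[`, numeric(1), "hu") <= 1350))
})

test_that("unknown preset names are rejected with the valid list", {
  expect_error(preset_phantom("cylinder"), "rectangular.*breast")
})

test_that("clips outside the body are rejected at construction", {
  expect_error(
    phantom_spec(c(40, 40, 40),
                 clips = list(clip_spec(c(0, 0, 0), hu = 1200),
                              clip_spec(c(25, 0, 0), hu = 1200))),
    "clip 2")
})

test_that("clip_spec validates geometry and HU", {
  expect_error(clip_spec(c(0, 0, 0), length = 0), "length")
  expect_error(clip_spec(c(0, 0, 0), diameter = -1), "diameter")
  expect_error(clip_spec(c(0, 0, 0), hu = 5000), "hu")
  expect_error(clip_spec(c(0, 0, 0), axis = c(0, 0, 0)), "axis")
  expect_equal(sum(clip_spec(c(0, 0, 0), axis = c(2, 0, 0))$axis^2), 1)
})

test_that("voxelization covers the body plus the air margin", {
  vol <- build_phantom(preset_phantom("rectangular"), c(1, 1, 1))
  expect_true(all(dim(vol$voxels) >= c(120, 200, 40)))
  # outside-body voxels are air; body fill is exact
  expect_equal(vol$voxels[1, 1, 1], -1000)
  n <- dim(vol$voxels)
  ctr <- (n + 1) / 2
  expect_equal(vol$voxels[ctr[1] + 30, ctr[2] + 60, ctr[3] + 10], 0)
})

test_that("a clip-free phantom is exactly the body fill", {
  spec <- phantom_spec(c(30, 30, 30), body_hu = 40)
  vol <- build_phantom(spec, c(1, 1, 1))
  # interior voxels take the fill exactly; faces blend toward air
  expect_equal(sum(abs(vol$voxels - 40) < 1e-12), 29^3)
  expect_true(all(vol$voxels >= -1000 & vol$voxels <= 40))
  n <- dim(vol$voxels); ctr <- (n + 1) / 2
  expect_equal(vol$voxels[ctr[1], ctr[2], ctr[3]], 40)
})

test_that("aligned clip interiors take the clip HU, boundaries blend", {
  spec <- phantom_spec(c(40, 40, 40),
                       clips = list(clip_spec(c(0, 0, 0), c(0, 1, 0),
                                              length = 6, diameter = 3,
                                              hu = 1200)))
  vol <- build_phantom(spec, c(1, 1, 1))
  n <- dim(vol$voxels)
  ctr <- (n + 1) / 2
  expect_equal(vol$voxels[ctr[1], ctr[2], ctr[3]], 1200)
  mx <- max(vol$voxels)
  expect_true(mx > 0 && mx <= 1200)
  # partial-volume values strictly between background and clip HU exist
  expect_true(any(vol$voxels > 100 & vol$voxels < 1100))
})

test_that("rendering is deterministic", {
  spec <- preset_phantom("breast")
  expect_identical(build_phantom(spec, c(2, 2, 2))$voxels,
                   build_phantom(spec, c(2, 2, 2))$voxels)
})

test_that("clip signal is conserved under sub-voxel displacement", {
  mk <- function(center) {
    spec <- phantom_spec(c(40, 40, 40),
                         clips = list(clip_spec(center, c(0, 1, 0), 4, 1, 1200)))
    v <- build_phantom(spec, c(1, 1, 1))
    sum(v$voxels[v$voxels > 0])  # excess over the zero-HU body
  }
  base <- mk(c(0, 0, 0))
  for (off in list(c(0.3, 0.45, 0.2), c(-0.25, 0.1, 0.4), c(0.49, -0.38, 0.11)))
    expect_equal(mk(off), base, tolerance = 0.01)
})

test_that("zero shift returns the identical volume", {
  vol <- one_clip_phantom()
  expect_identical(apply_shift(vol, c(0, 0, 0))$voxels, vol$voxels)
})

test_that("apply_shift moves the clip centroid by the applied amount", {
  vol <- one_clip_phantom()
  sh <- apply_shift(vol, c(5, 0, 0))
  expect_equal(clip_centroid_mm(sh, thr = 600) - clip_centroid_mm(vol, thr = 600),
               c(5, 0, 0), tolerance = 0.1)
  sub <- apply_shift(vol, c(1.5, -2.25, 0.5))
  expect_equal(clip_centroid_mm(sub) - clip_centroid_mm(vol),
               c(1.5, -2.25, 0.5), tolerance = 0.1)
})

test_that("shifting forward and back restores smooth regions", {
  vol <- one_clip_phantom()
  s <- c(2.3, -1.7, 0.9)
  back <- apply_shift(apply_shift(vol, s), -s)
  # compare away from the body edge and the clip (interpolation is exact on
  # constant regions, approximate near gradients)
  n <- dim(vol$voxels)
  ctr <- (n + 1) / 2
  reg <- list((ctr[1] + 8):(ctr[1] + 20), (ctr[2] + 8):(ctr[2] + 20),
              (ctr[3] - 20):(ctr[3] - 8))
  expect_equal(back$voxels[reg[[1]], reg[[2]], reg[[3]]],
               vol$voxels[reg[[1]], reg[[2]], reg[[3]]], tolerance = 1e-8)
})

test_that("shifts that would push a clip off the grid are rejected", {
  vol <- one_clip_phantom()
  expect_error(apply_shift(vol, c(80, 0, 0)), "outside")
})
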
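test_that("prefilter with sigma zero is the identity", {
  pr <- small_pair()
  expect_identical(prefilter(pr$ref, 0), pr$ref)
})

test_that("prefilter spreads an impulse into a Gaussian of the right width", {
  v <- small_pair()$ref
  v$slices[] <- 0
  ctr <- (dim(v$slices) + 1) / 2
  v$slices[ctr[1], ctr[2], ctr[3]] <- 1
  sigma <- 3  # mm
  f <- prefilter(v, sigma)
  sl <- f$slices[, , ctr[3]]
  m2u <- sum(sl * outer(v$ucoord^2, rep(1, length(v$vcoord)))) / sum(sl)
  m2v <- sum(sl * outer(rep(1, length(v$ucoord)), v$vcoord^2)) / sum(sl)
  expect_equal(m2u, sigma^2, tolerance = 0.02 * sigma^2)
  expect_equal(m2v, sigma^2, tolerance = 0.02 * sigma^2)
  # other slices untouched (in-plane filter)
  expect_true(all(f$slices[, , ctr[3] - 1] == 0))
})

test_that("prefiltering raises the correlation of a noisy pair", {
  vol <- one_clip_phantom()
  g <- recon_geom()
  arc <- arc_spec(0, 10)
  cfg <- small_recon_cfg()
  ref <- small_pair()$ref
  ps <- acquire_arc(vol, arc, g, noise_sigma = 0.05, seed = 31)
  trt <- reconstruct_treatment_dts(ps, cfg)
  ncc0 <- match_template(ref, trt,
                         match_config(template_center = c(0, 0, 0)))$ncc
  ncc1 <- match_template(prefilter(ref, 2), prefilter(trt, 2),
                         match_config(template_center = c(0, 0, 0)))$ncc
  expect_gt(ncc1, ncc0)
})

test_that("matching a volume against itself is exact", {
  ref <- small_pair()$ref
  m <- match_template(ref, ref, match_config(template_center = c(0, 0, 0)))
  expect_equal(as.numeric(m$displacement), c(0, 0, 0), tolerance = 1e-3)
  expect_equal(m$ncc, 1, tolerance = 1e-9)
  expect_true(m$valid)
})

test_that("known integer translations are recovered exactly", {
  pr <- small_pair()
  cfg <- match_config(template_center = c(0, 0, 0))
  for (d in list(c(1, -2, 0), c(-3, 1, 1), c(2, 2, -1))) {
    trt <- translate_dts(pr$trt, d[1], d[2], d[3])
    m <- match_template(pr$ref, trt, cfg)
    expect_equal(as.numeric(m$displacement),
                 d * c(2, 2, 2), tolerance = 0.51)  # 2 mm voxels
    expect_true(m$ncc > 0.9)
  }
})

test_that("the NCC peak moves exactly with integer-lattice translations", {
  # translation equivariance on the lattice, noise-free
  pr <- small_pair()
  cfg <- match_config(template_center = c(0, 0, 0))
  base <- match_template(pr$ref, pr$trt, cfg)
  for (d in list(c(2, 0, 0), c(0, -3, 0), c(-1, 2, 1))) {
    m <- match_template(pr$ref, translate_dts(pr$trt, d[1], d[2], d[3]), cfg)
    expect_equal(as.numeric(m$displacement - base$displacement),
                 d * c(2, 2, 2), tolerance = 1e-6)
  }
})

test_that("NCC stays within [-1, 1] across random templates", {
  pr <- small_pair()
  set.seed(44)
  for (i in 1:6) {
    ctr <- c(runif(2, -4, 4), runif(1, -2, 2))
    m <- match_template(pr$ref, pr$trt,
                        match_config(template_center = ctr, template_size = 16))
    expect_true(m$ncc >= -1 && m$ncc <= 1)
  }
})

test_that("an in-plane shift beyond the search region invalidates the match", {
  pr <- small_pair()
  # 8 mm along u exceeds the 7.5 mm half-width: peak pinned to the boundary
  trt <- translate_dts(pr$trt, 4, 0, 0)  # 4 voxels x 2 mm = 8 mm
  m <- match_template(prefilter(pr$ref, 2), prefilter(trt, 2),
                      match_config(template_center = c(0, 0, 0)))
  expect_false(m$valid)
  expect_true(m$on_boundary)
})

test_that("degenerate templates are rejected", {
  pr <- small_pair()
  flat <- pr$ref
  flat$slices[] <- 3.14
  expect_error(match_template(flat, pr$trt,
                              match_config(template_center = c(0, 0, 0))),
               "degenerate template")
})

test_that("matching requires a shared arc orientation and grid", {
  pr <- small_pair()
  other <- pr$trt
  other$theta_c <- pr$trt$theta_c + 20
  expect_error(match_template(pr$ref, other), "orientation")
  coarse <- pr$trt
  coarse$slice_spacing <- 7
  expect_error(match_template(pr$ref, coarse), "grid")
})

make_match <- function(shift, theta_c, duvw = NULL, valid = TRUE) {
  fr <- beam_frame(theta_c)
  d <- if (is.null(duvw)) drop(crossprod(unclass(fr), shift)) else duvw
  names(d) <- c("u", "v", "w")
  structure(list(displacement = d, ncc = 0.95, valid = valid,
                 on_boundary = FALSE, depth_on_boundary = FALSE,
                 theta_c = theta_c, frame = fr, arc = arc_spec(theta_c, 10)),
            class = "match_result")
}

test_that("triangulation inverts exact in-plane projections", {
  s <- c(3, -2, 5)
  tri <- triangulate(list(make_match(s, 305), make_match(s, 325)))
  expect_equal(as.numeric(tri$shift), s, tolerance = 1e-6)
  expect_equal(tri$separation, 20)
  expect_equal(tri$arcs_used, 2)
  expect_true(tri$valid_3d)

  # all-zero matches triangulate to a zero shift
  z <- triangulate(list(make_match(c(0, 0, 0), 305),
                        make_match(c(0, 0, 0), 325)))
  expect_equal(as.numeric(z$shift), c(0, 0, 0), tolerance = 1e-12)

  # random shifts, random arc pairs: exact inversion
  set.seed(11)
  for (i in 1:8) {
    s <- runif(3, -6, 6)
    t1 <- runif(1, 0, 360); t2 <- t1 + runif(1, 15, 90)
    tri <- triangulate(list(make_match(s, t1), make_match(s, t2)))
    expect_equal(as.numeric(tri$shift), s, tolerance = 1e-6)
  }
})

test_that("depth recovery degrades as the arc separation shrinks", {
  # fixed +/-0.3 mm in-plane perturbation; the depth error amplification
  # follows the conditioning of the two-arc system
  s <- c(3, -2, 5)
  derr <- vapply(c(10, 20), function(sep) {
    m1 <- make_match(s, 305)
    m2 <- make_match(s, 305 + sep)
    m1$displacement["u"] <- m1$displacement["u"] + 0.3
    m2$displacement["u"] <- m2$displacement["u"] - 0.3
    tri <- triangulate(list(m1, m2))
    abs(sum((tri$shift - s) * unclass(beam_frame(305))[, "w"]))
  }, numeric(1))
  expect_gt(derr[1], derr[2])

  cond <- vapply(c(10, 20, 30), function(sep)
    triangulate(list(make_match(s, 305), make_match(s, 305 + sep)))$condition,
    numeric(1))
  expect_true(all(diff(cond) < 0))
})

test_that("a single arc is flagged rank-deficient and uses its own depth", {
  s <- c(3, -2, 5)
  tri <- triangulate(make_match(s, 305))
  expect_false(tri$valid_3d)
  expect_equal(tri$arcs_used, 1)
  # with the (here exact) depth component the basis reconstruction is exact
  expect_equal(as.numeric(tri$shift), s, tolerance = 1e-9)
})

test_that("triangulation with no valid matches reports the ncc values", {
  bad <- make_match(c(1, 1, 1), 305, valid = FALSE)
  expect_error(triangulate(list(bad)), "registration failed.*0.950")
})

test_that("positive depth weight incorporates the depth equations", {
  s <- c(3, -2, 5)
  m1 <- make_match(s, 305); m2 <- make_match(s, 325)
  tri <- triangulate(list(m1, m2), w_depth = 1)
  expect_equal(as.numeric(tri$shift), s, tolerance = 1e-6)
  # corrupt depths pull the solution only when weighted in
  m1$displacement["w"] <- m1$displacement["w"] + 4
  m2$displacement["w"] <- m2$displacement["w"] + 4
  t0 <- triangulate(list(m1, m2), w_depth = 0)
  t1 <- triangulate(list(m1, m2), w_depth = 1)
  expect_equal(as.numeric(t0$shift), s, tolerance = 1e-6)
  expect_gt(sqrt(sum((t1$shift - s)^2)), 1)
})

test_that("arc orientation scoring flags poor clip layouts", {
  # a single clip cannot support registration
  sc1 <- score_arc_orientation(clip_spec(c(0, 0, 0)), 305)
  expect_true(sc1$insufficient_clips)
  expect_true(is.na(sc1$score))

  # two clips stacked along the beam axis collapse in the BEV
  w <- unclass(beam_frame(40))[, "w"]
  sc2 <- score_arc_orientation(list(clip_spec(c(0, 0, 0)),
                                    clip_spec(20 * w)), 40)
  expect_true(sc2$overlap)

  # three clips in a 10 mm in-plane triangle are fine
  u <- unclass(beam_frame(40))[, "u"]; v <- unclass(beam_frame(40))[, "v"]
  tri <- list(clip_spec(-5 * u), clip_spec(5 * u), clip_spec(10 * v))
  sc3 <- score_arc_orientation(tri, 40)
  expect_false(sc3$insufficient_clips)
  expect_false(sc3$overlap)
  expect_equal(sc3$score, 10, tolerance = 0.01)
})
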
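#' Matching configuration
#'
#' @param search_region search extent (u, v, depth), mm; the template is
#'   shifted over the integer voxel lattice within plus/minus half these
#'   widths.
#' @param gaussian_sigma in-plane Gaussian prefilter width, mm, applied to
#'   both volumes before matching to equalize their resolution character.
#' @param template_center template center in beam-frame mm (u, v, depth), or
#'   NULL to center on the bright-structure (clip) centroid of the reference.
#' @param template_size template cube side, mm.
#' @param min_ncc minimum peak correlation for a match to be valid.
#' @return An object of class `match_config`.
#' @export
match_config <- function(search_region = c(15, 15, 15), gaussian_sigma = 1.5,
                         template_center = NULL, template_size = 24,
                         min_ncc = 0.3) {
  search_region <- rep_len(as.numeric(search_region), 3)
  if (any(search_region <= 0)) stop("search_region must be positive")
  if (min_ncc <= 0 || min_ncc >= 1) stop("min_ncc must lie in (0, 1)")
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  structure(list(search_region = search_region,
                 gaussian_sigma = gaussian_sigma,
                 template_center = template_center,
                 template_size = template_size, min_ncc = min_ncc),
            class = "match_config")
}

#' In-plane Gaussian prefilter
#'
#' Smooths every slice of a DTS volume with an isotropic in-plane Gaussian
#' of the given width (mm). Reference and treatment DTS volumes are filtered
#' identically before matching so that residual differences in resolution
#' character do not depress the correlation. `sigma = 0` is the identity.
#'
#' @param v a `dts_volume`.
#' @param sigma Gaussian standard deviation, mm.
#' @return The filtered `dts_volume`.
#' @export
prefilter <- function(v, sigma = 1.5) {
  stopifnot(inherits(v, "dts_volume"), sigma >= 0)
  if (sigma == 0) return(v)
  spx <- sigma / v$in_plane_pixel
  for (k in seq_len(dim(v$slices)[3]))
    v$slices[, , k] <- EBImage::gblur(v$slices[, , k], sigma = spx)
  v
}

# Centroid (beam-frame mm) of above-threshold structure in a DTS volume;
# used as the default template center when no clip layout is known. The
# outer quarter of the in-plane field is masked out so body-edge bands do
# not hijack the centroid.
bright_centroid <- function(v) {
  s <- v$slices
  mu <- abs(v$ucoord) <= 0.75 * max(abs(v$ucoord))
  mv <- abs(v$vcoord) <= 0.75 * max(abs(v$vcoord))
  s <- s[mu, mv, , drop = FALSE]
  bg <- median(s)
  mx <- max(s)
  if (mx <= bg) return(c(0, 0, 0))
  w <- pmax(s - (bg + 0.5 * (mx - bg)), 0)
  W <- sum(w)
  gu <- apply(w, 1, sum); gv <- apply(w, 2, sum); gd <- apply(w, 3, sum)
  c(sum(gu * v$ucoord[mu]), sum(gv * v$vcoord[mv]), sum(gd * v$depth)) / W
}

# Beam-frame coordinates of the clip centroid of a phantom-built planning
# CT, or NULL when the volume carries no clip layout.
clips_centroid_beam <- function(planning_ct, frame) {
  spec <- attr(planning_ct, "phantom_spec")
  if (is.null(spec) || !length(spec$clips)) return(NULL)
  ctr <- colMeans(do.call(rbind, lapply(spec$clips, `[[`, "center")))
  drop(crossprod(unclass(frame), ctr))
}

#' Match a treatment DTS against a reference DTS
#'
#' Zero-mean normalized cross-correlation of a template cut from the
#' reference volume against the treatment volume, evaluated on the integer
#' voxel displacement lattice within the search region, with the peak
#' refined to sub-voxel precision by a separable quadratic fit over its
#' 3x3x3 neighborhood. The reported displacement maps the treatment onto
#' the reference: for a phantom displaced by a shift s, the match peaks at
#' the beam-frame components of s. Lattice ties break toward the smallest
#' displacement magnitude, then lexicographically. A peak on the search
#' boundary is flagged invalid (the true shift may exceed the region).
#'
#' @param ref reference `dts_volume`.
#' @param trt treatment `dts_volume` with the same arc orientation, pixel
#'   size and slice spacing.
#' @param cfg a [match_config()].
#' @return An object of class `match_result`: `displacement` (u, v, depth
#'   mm), `ncc`, `valid`, and the arc frame.
#' @export
match_template <- function(ref, trt, cfg = match_config()) {
  stopifnot(inherits(ref, "dts_volume"), inherits(trt, "dts_volume"))
  if (abs((ref$theta_c - trt$theta_c) %% 360) > 1e-6)
    stop("reference and treatment DTS must share the arc orientation")
  if (ref$in_plane_pixel != trt$in_plane_pixel ||
      ref$slice_spacing != trt$slice_spacing)
    stop("reference and treatment DTS must share the reconstruction grid")
  px <- ref$in_plane_pixel
  sp <- ref$slice_spacing
  ctr <- cfg$template_center
  auto <- is.null(ctr) || isTRUE(cfg$.clamp)
  if (is.null(ctr)) ctr <- bright_centroid(ref)
  half <- cfg$template_size / 2
  hu <- max(1L, as.integer(round(half / px)))
  hv <- hu
  hd <- max(1L, as.integer(round(half / sp)))
  ic <- c(round((ctr[1] - ref$ucoord[1]) / px),
          round((ctr[2] - ref$vcoord[1]) / px),
          round((ctr[3] - ref$depth[1]) / sp)) + 1
  if (auto)  # keep the automatic center where the template fits
    ic <- pmin(pmax(ic, c(hu, hv, hd) + 1L), dim(ref$slices) - c(hu, hv, hd))
  lo <- ic - c(hu, hv, hd)
  hi <- ic + c(hu, hv, hd)
  if (any(lo < 1) || any(hi > dim(ref$slices)))
    stop("template does not fit inside the reference volume")
  tmpl <- ref$slices[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (sd(tmpl) == 0) stop("degenerate template (zero variance)")
  # template origin inside the treatment grid at zero displacement (0-based)
  t0 <- c(round((ref$ucoord[lo[1]] - trt$ucoord[1]) / px),
          round((ref$vcoord[lo[2]] - trt$vcoord[1]) / px),
          round((ref$depth[lo[3]] - trt$depth[1]) / sp))
  nsr <- c(floor(cfg$search_region[1] / 2 / px),
           floor(cfg$search_region[2] / 2 / px),
           floor(cfg$search_region[3] / 2 / sp))
  offs <- as.matrix(expand.grid(u = -nsr[1]:nsr[1], v = -nsr[2]:nsr[2],
                                w = -nsr[3]:nsr[3]))
  ncc <- cpp_ncc_lattice(tmpl, trt$slices, as.integer(t0), offs)
  sc <- ifelse(is.na(ncc), -Inf, ncc)
  # tie-break: smallest displacement magnitude, then lexicographic
  mm <- sweep(offs, 2, c(px, px, sp), "*")
  ord <- order(rowSums(mm^2), offs[, 1], offs[, 2], offs[, 3])
  best <- ord[which.max(sc[ord])]
  peak <- offs[best, ]
  # A peak on the outermost in-plane lattice node means the true shift may
  # exceed the search region: the match is rejected. The depth lattice is
  # much coarser (one node per slice spacing) and its component is the
  # documented-unreliable one that triangulation discards, so a depth-edge
  # peak is only recorded, not used to reject the in-plane match.
  on_boundary <- any(abs(peak[1:2]) == nsr[1:2] & nsr[1:2] > 0)
  depth_on_boundary <- abs(peak[3]) == nsr[3] && nsr[3] > 0
  # sub-voxel quadratic refinement per axis
  delta <- numeric(3)
  arr <- array(sc, dim = 2 * nsr + 1)
  pidx <- peak + nsr + 1
  for (a in 1:3) {
    if (pidx[a] > 1 && pidx[a] < dim(arr)[a]) {
      im <- pidx; ip <- pidx
      im[a] <- im[a] - 1; ip[a] <- ip[a] + 1
      cm <- arr[im[1], im[2], im[3]]
      c0 <- arr[pidx[1], pidx[2], pidx[3]]
      cp <- arr[ip[1], ip[2], ip[3]]
      den <- cm - 2 * c0 + cp
      if (is.finite(cm) && is.finite(cp) && den < 0)
        delta[a] <- max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
    }
  }
  disp <- (as.numeric(peak) + delta) * c(px, px, sp)
  names(disp) <- c("u", "v", "w")
  ncc_peak <- sc[best]
  structure(list(displacement = disp, ncc = ncc_peak,
                 valid = is.finite(ncc_peak) && ncc_peak >= cfg$min_ncc &&
                   !on_boundary,
                 on_boundary = on_boundary,
                 depth_on_boundary = depth_on_boundary,
                 theta_c = ref$theta_c, frame = ref$frame, arc = ref$arc),
            class = "match_result")
}

# Minimum pairwise angular separation between arc centers, degrees in [0, 180].
arc_separation <- function(thetas) {
  if (length(thetas) < 2) return(NA_real_)
  d <- outer(thetas, thetas, function(a, b) abs(a - b) %% 360)
  d <- pmin(d, 360 - d)
  min(d[upper.tri(d)])
}

#' Triangulate per-arc matches into a 3D shift
#'
#' Weighted least squares for the room-frame shift s: each valid match
#' contributes its two in-plane equations (u . s = d_u, v . s = d_v) at
#' weight 1 and its depth equation (w . s = d_w) at weight `w_depth`. The
#' depth weight defaults to 0 because a single DTS volume has poor depth
#' resolution; the depth is then recovered purely from the in-plane
#' equations of arcs at different orientations. With a single arc the
#' in-plane system is rank-deficient: the result is flagged not 3D-valid
#' and the depth is taken from that arc's own (unreliable) depth component.
#'
#' @param matches list of [match_template()] results (or a single one).
#' @param w_depth weight of the per-arc depth equations.
#' @return An object of class `triangulation_result`: `shift` (x, y, z mm),
#'   `condition` (singular-value ratio of the weighted design), `arcs_used`,
#'   `separation` (degrees), `valid_3d`.
#' @export
triangulate <- function(matches, w_depth = 0) {
  if (inherits(matches, "match_result")) matches <- list(matches)
  ok <- vapply(matches, function(m) isTRUE(m$valid), logical(1))
  if (!any(ok))
    stop(sprintf("registration failed: no valid match (ncc: %s)",
                 paste(sprintf("%.3f", vapply(matches, `[[`, numeric(1), "ncc")),
                       collapse = ", ")))
  used <- matches[ok]
  rows <- NULL; rhs <- NULL; wts <- NULL
  for (m in used) {
    F <- unclass(m$frame)
    rows <- rbind(rows, t(F[, "u"]), t(F[, "v"]), t(F[, "w"]))
    rhs <- c(rhs, m$displacement[c("u", "v", "w")])
    wts <- c(wts, 1, 1, w_depth)
  }
  keep <- wts > 0
  A <- rows[keep, , drop = FALSE] * sqrt(wts[keep])
  b <- rhs[keep] * sqrt(wts[keep])
  sv <- svd(A)
  tol <- max(sv$d) * 1e-8
  rank <- sum(sv$d > tol)
  valid_3d <- length(used) >= 2 && rank == 3
  if (rank == 3) {
    shift <- sv$v %*% ((crossprod(sv$u, b)) / sv$d)
    condition <- sv$d[1] / sv$d[3]
  } else {
    # rank-deficient in-plane system: bring in the depth equations
    A2 <- rows; b2 <- rhs
    w2 <- pmax(wts, rep(c(0, 0, 1), length(used)))
    A2 <- A2 * sqrt(w2); b2 <- b2 * sqrt(w2)
    sv2 <- svd(A2)
    shift <- sv2$v %*% ((crossprod(sv2$u, b2)) / pmax(sv2$d, tol))
    condition <- if (sv$d[length(sv$d)] > 0) sv$d[1] / sv$d[length(sv$d)] else Inf
  }
  shift <- drop(shift)
  names(shift) <- c("x", "y", "z")
  structure(list(shift = shift, condition = condition,
                 arcs_used = length(used),
                 separation = arc_separation(vapply(used, `[[`, numeric(1),
                                                    "theta_c")),
                 valid_3d = valid_3d, matches = matches),
            class = "triangulation_result")
}

#' Register treatment arcs against a planning CT
#'
#' Full registration pipeline: for each acquired arc, reconstruct the
#' reference DTS from the planning CT and the treatment DTS from the
#' projections, prefilter both, and match; then triangulate the valid
#' matches into a 3D couch shift.
#'
#' @param planning_ct the planning [ct_volume()].
#' @param ps_list list of [acquire_arc()] projection sets (two or more arcs
#'   recommended for a 3D-valid result).
#' @param cfg treatment [recon_config()]; the reference uses
#'   [reference_config()] of the same.
#' @param mcfg a [match_config()].
#' @param w_depth depth-equation weight for [triangulate()].
#' @param references optional pre-computed list of reference `dts_volume`s
#'   (one per arc), e.g. reused across repeated registrations.
#' @return An object of class `registration_report`: per-arc matches, the
#'   triangulated `shift`, `separation`, `condition`, `valid_3d`.
#' @export
register_dts <- function(planning_ct, ps_list, cfg = recon_config(),
                         mcfg = match_config(), w_depth = 0,
                         references = NULL) {
  if (inherits(ps_list, "projection_set")) ps_list <- list(ps_list)
  stopifnot(length(ps_list) >= 1)
  matches <- vector("list", length(ps_list))
  for (i in seq_along(ps_list)) {
    ps <- ps_list[[i]]
    ref <- if (!is.null(references)) references[[i]]
           else reconstruct_reference_dts(planning_ct, ps$arc, ps$geom,
                                          reference_config(cfg))
    trt <- reconstruct_treatment_dts(ps, cfg)
    ref <- prefilter(ref, mcfg$gaussian_sigma)
    trt <- prefilter(trt, mcfg$gaussian_sigma)
    amcfg <- mcfg
    if (is.null(amcfg$template_center)) {  # center the template on the clips
      amcfg$template_center <- clips_centroid_beam(planning_ct, ref$frame)
      amcfg$.clamp <- TRUE
    }
    matches[[i]] <- match_template(ref, trt, cfg = amcfg)
  }
  tri <- triangulate(matches, w_depth = w_depth)
  structure(list(matches = matches, shift = tri$shift,
                 condition = tri$condition, separation = tri$separation,
                 arcs_used = tri$arcs_used, valid_3d = tri$valid_3d),
            class = "registration_report")
}

#' Score a candidate arc orientation by clip distribution
#'
#' Projects the clip centers into the beam's-eye view (BEV) of the candidate
#' middle arc angle and checks their separation: clips closer than 3 mm in
#' the BEV merge into one bright cluster and mislead the correlation match,
#' and fewer than three well-separated clips give weak registration. The
#' score is the minimum pairwise BEV separation among the retained
#' (well-separated) clips; higher is better.
#'
#' @param clips list of [clip_spec()] objects (or a single one).
#' @param theta_c candidate middle arc angle, degrees.
#' @param min_sep separation threshold in the BEV, mm.
#' @return A list: `score` (mm, NA when fewer than two clips are retained),
#'   `insufficient_clips`, `overlap`, and the BEV coordinates.
#' @export
score_arc_orientation <- function(clips, theta_c, min_sep = 3) {
  if (inherits(clips, "clip_spec")) clips <- list(clips)
  stopifnot(length(clips) >= 1)
  fr <- beam_frame(theta_c)
  bev <- t(vapply(clips, function(cl)
    c(sum(cl$center * fr[, "u"]), sum(cl$center * fr[, "v"])), numeric(2)))
  n <- nrow(bev)
  if (n == 1)
    return(list(score = NA_real_, insufficient_clips = TRUE, overlap = FALSE,
                bev = bev))
  d <- as.matrix(dist(bev))
  overlap <- any(d[upper.tri(d)] < min_sep)
  keep <- logical(n)
  for (i in seq_len(n))
    keep[i] <- !any(keep & d[i, ] < min_sep & seq_len(n) != i)
  retained <- which(keep)
  score <- if (length(retained) >= 2) {
    dr <- d[retained, retained]
    min(dr[upper.tri(dr)])
  } else NA_real_
  list(score = score,
       insufficient_clips = length(retained) < 3,
       overlap = overlap, bev = bev)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "Match (theta_c %.1f deg): displacement u %.2f, v %.2f, depth %.2f mm; ncc %.3f%s\n",
    x$theta_c %% 360, x$displacement[1], x$displacement[2], x$displacement[3],
    x$ncc, if (x$valid) "" else " [invalid]"))
  invisible(x)
}

#' @export
print.triangulation_result <- function(x, ...) {
  cat(sprintf("Triangulated shift: x %.2f, y %.2f, z %.2f mm (%d arc(s), separation %s deg)%s\n",
              x$shift[1], x$shift[2], x$shift[3], x$arcs_used,
              ifelse(is.na(x$separation), "-", sprintf("%.0f", x$separation)),
              if (x$valid_3d) "" else " [not 3D-valid]"))
  invisible(x)
}

#' @export
print.registration_report <- function(x, ...) {
  cat("DTS registration report\n")
  for (m in x$matches) print(m)
  cat(sprintf("Couch shift: x %.2f, y %.2f, z %.2f mm%s (condition %.2f)\n",
              x$shift[1], x$shift[2], x$shift[3],
              if (x$valid_3d) "" else " [not 3D-valid]", x$condition))
  invisible(x)
}
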
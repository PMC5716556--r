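#' Write a volume as MetaImage (.mha)
#'
#' Minimal uncompressed MetaImage writer: text header (mm spacing and
#' offset) followed by little-endian raw voxel data in one file.
#'
#' @param vol a [ct_volume()] (2D matrices are written as NDims = 2).
#' @param path output path ending in `.mha`.
#' @return The path, invisibly.
#' @export
write_mha <- function(vol, path) {
  if (inherits(vol, "ct_volume")) {
    a <- vol$voxels; spacing <- vol$spacing; origin <- vol$origin
  } else {
    a <- vol
    spacing <- rep(1, max(2, length(dim(a))))
    origin <- rep(0, length(spacing))
  }
  d <- dim(a)
  if (is.null(d)) stop("volume must be a matrix or array")
  nd <- length(d)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           sprintf("NDims = %d", nd),
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("TransformMatrix = %s",
                   paste(as.integer(diag(nd)), collapse = " ")),
           sprintf("Offset = %s", paste(origin[seq_len(nd)], collapse = " ")),
           sprintf("ElementSpacing = %s",
                   paste(spacing[seq_len(nd)], collapse = " ")),
           sprintf("DimSize = %s", paste(d, collapse = " ")),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(a), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage (.mha) volume
#'
#' Reads the uncompressed single-file MetaImage layout written by
#' [write_mha()] (MET_DOUBLE, MET_FLOAT, MET_SHORT or MET_UCHAR elements).
#'
#' @param path path to a `.mha` file.
#' @return A [ct_volume()] (3D data) or a matrix with spacing/origin
#'   attributes (2D data).
#' @export
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("unexpected end of MetaImage header")
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only single-file (LOCAL) MetaImage data is supported")
  d <- as.integer(strsplit(hdr[["DimSize"]], " ")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], " ")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]], " ")[[1]])
  type <- hdr[["ElementType"]]
  n <- prod(d)
  vals <- switch(type,
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "numeric", n, size = 4, endian = "little"),
    MET_SHORT = readBin(con, "integer", n, size = 2, endian = "little"),
    MET_UCHAR = readBin(con, "integer", n, size = 1, signed = FALSE),
    stop(sprintf("unsupported MetaImage element type %s", type)))
  a <- array(as.numeric(vals), dim = d)
  if (length(d) == 3) ct_volume(a, spacing, origin)
  else structure(a, spacing = spacing, origin = origin)
}

#' Write a CT volume to disk
#'
#' Dispatches on the file extension: `.mha` (MetaImage, via [write_mha()])
#' or `.nii`/`.nii.gz` (NIfTI, via RNifti; mm spacing in the header).
#'
#' @param vol a [ct_volume()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (grepl("\\.mha$", path)) return(write_mha(vol, path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$voxels)
    m <- diag(4)
    m[1:3, 1:3] <- diag(vol$spacing)
    m[1:3, 4] <- vol$origin
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  stop("unsupported volume format; use .mha, .nii or .nii.gz")
}

#' Read a CT volume from disk
#'
#' @param path a `.mha`, `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.mha$", path)) {
    v <- read_mha(path)
    if (!inherits(v, "ct_volume")) stop("expected a 3D volume")
    return(v)
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    ct_volume(array(as.numeric(img), dim = dim(img)),
              spacing = abs(diag(xf[1:3, 1:3])), origin = xf[1:3, 4])
  } else stop("unsupported volume format; use .mha, .nii or .nii.gz")
}

#' Serialize a phantom specification to YAML
#'
#' @param spec a [phantom_spec()].
#' @param path output `.yaml` path.
#' @return The path, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- list(body_size = spec$body_size, body_hu = spec$body_hu,
            shape = spec$shape,
            clips = lapply(spec$clips, function(cl)
              list(center = cl$center, axis = cl$axis, length = cl$length,
                   diameter = cl$diameter, hu = cl$hu)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a phantom specification from YAML
#'
#' @param path a `.yaml` file written by [write_phantom_spec()] (or edited
#'   by hand in the same layout).
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  clips <- lapply(x$clips, function(cl)
    clip_spec(cl$center, cl$axis, cl$length, cl$diameter, cl$hu))
  phantom_spec(x$body_size, body_hu = x$body_hu %||% 0, clips = clips,
               shape = x$shape %||% "box")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a projection set to a directory
#'
#' One 2D MetaImage per projection (`proj_###.mha`, detector mm spacing)
#' plus a JSON sidecar with angles, geometry, noise level and seed.
#'
#' @param ps a [acquire_arc()] projection set.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_projection_set <- function(ps, dir) {
  stopifnot(inherits(ps, "projection_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(ps$pixels)[3]
  for (k in seq_len(n)) {
    img <- ps$pixels[, , k]
    path <- file.path(dir, sprintf("proj_%03d.mha", k))
    v <- list(voxels = img, spacing = ps$geom$pixel_mm,
              origin = -((dim(img) - 1) / 2) * ps$geom$pixel_mm)
    # write as 2D MetaImage
    con <- file(path, "wb")
    writeLines(c("ObjectType = Image", "NDims = 2", "BinaryData = True",
                 "BinaryDataByteOrderMSB = False", "CompressedData = False",
                 "TransformMatrix = 1 0 0 1",
                 sprintf("Offset = %s", paste(v$origin, collapse = " ")),
                 sprintf("ElementSpacing = %s", paste(v$spacing, collapse = " ")),
                 sprintf("DimSize = %s", paste(dim(img), collapse = " ")),
                 "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"),
               con, sep = "\n")
    writeBin(as.numeric(img), con, size = 8, endian = "little")
    close(con)
  }
  side <- list(angles = ps$angles, angles_unwrapped = ps$angles_unwrapped,
               arc = unclass(ps$arc), noise_sigma = ps$noise_sigma,
               seed = ps$seed,
               geometry = list(sad = ps$geom$sad, sid = ps$geom$sid,
                               detector_size = ps$geom$detector_size,
                               detector_pixels = ps$geom$detector_pixels))
  jsonlite::write_json(side, file.path(dir, "projections.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a projection set from a directory
#'
#' @param dir a directory written by [write_projection_set()].
#' @return A projection set.
#' @export
read_projection_set <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "projections.json"),
                              simplifyVector = TRUE)
  geom <- acquisition_geometry(side$geometry$sad, side$geometry$sid,
                               side$geometry$detector_size,
                               side$geometry$detector_pixels)
  files <- sort(list.files(dir, pattern = "^proj_\\d+\\.mha$",
                           full.names = TRUE))
  pix <- array(0, dim = c(geom$detector_pixels, length(files)))
  for (k in seq_along(files)) {
    img <- read_mha(files[k])
    pix[, , k] <- img
  }
  arc <- arc_spec(side$arc$theta_c, side$arc$arc_length, side$arc$angular_step)
  structure(list(pixels = pix, angles = side$angles,
                 angles_unwrapped = side$angles_unwrapped, arc = arc,
                 geom = geom, noise_sigma = side$noise_sigma,
                 seed = side$seed),
            class = "projection_set")
}

#' Write a registration report as JSON
#'
#' @param report a [register_dts()] result.
#' @param path output `.json` path.
#' @return The path, invisibly.
#' @export
write_registration_report <- function(report, path) {
  stopifnot(inherits(report, "registration_report"))
  x <- list(shift = as.list(report$shift),
            separation = report$separation,
            condition = report$condition,
            arcs_used = report$arcs_used,
            valid_3d = report$valid_3d,
            matches = lapply(report$matches, function(m)
              list(theta_c = m$theta_c %% 360,
                   displacement = as.list(m$displacement),
                   ncc = m$ncc, valid = m$valid)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write sweep results as CSV (plus a JSON summary)
#'
#' @param res a [run_sweep()] result.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_sweep_results <- function(res, dir) {
  stopifnot(inherits(res, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(res), file.path(dir, "sweep.csv"),
                   row.names = FALSE)
  agg <- summary(res)
  jsonlite::write_json(list(summary = agg, n_failed = attr(agg, "n_failed")),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
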
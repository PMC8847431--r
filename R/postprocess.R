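# Image analysis: peak finding, spherical-ROI integration and intensity
# ratios, multi-channel fusion, slice extraction.

#' Locate the image peak
#'
#' Argmax voxel of a 3D image; ties are broken by the lowest flattened
#' index.  Per-axis FWHM is measured on the profiles through the peak by
#' linear interpolation of the half-maximum crossings.
#'
#' @param img a `hcc_image`.
#' @return list with `index` (1-based voxel indices), `position` (world mm
#'   of the voxel center), `value`, `fwhm_mm` (per axis, `NA` when a
#'   half-maximum crossing is outside the grid).
#' @export
find_peak <- function(img) {
  v <- img$values
  if (all(v == 0)) stop("all-zero image")
  flat <- which.max(v)
  idx <- arrayInd(flat, dim(v))[1, ]
  g <- img$grid
  pos <- g$origin + (idx - 0.5) * g$pitch
  half <- v[flat] / 2
  fwhm <- rep(NA_real_, 3)
  for (ax in 1:3) {
    prof <- switch(ax,
                   v[, idx[2], idx[3]],
                   v[idx[1], , idx[3]],
                   v[idx[1], idx[2], ])
    p <- idx[ax]
    lo <- hi <- NA_real_
    i <- p
    while (i > 1 && prof[i - 1] >= half) i <- i - 1
    if (i > 1) lo <- (i - 1) + (half - prof[i - 1]) / (prof[i] - prof[i - 1])
    i <- p
    while (i < length(prof) && prof[i + 1] >= half) i <- i + 1
    if (i < length(prof)) hi <- i + (prof[i] - half) / (prof[i] - prof[i + 1])
    if (!is.na(lo) && !is.na(hi)) fwhm[ax] <- (hi - lo) * g$pitch
  }
  list(index = idx, position = pos, value = v[flat], fwhm_mm = fwhm)
}

.roi_sum <- function(img, center, radius) {
  vox <- voxel_centers(img$grid)
  d2 <- rowSums((vox - matrix(center, nrow(vox), 3, byrow = TRUE))^2)
  sum(img$values[d2 <= radius^2])
}

#' Intensity ratio of two spherical ROIs
#'
#' Ratio of summed voxel values in spheres around `center_a` and
#' `center_b`.  The default radius of 3 voxels (~7 mm at the 2.3 mm pitch)
#' matches point-like sources of diameter < 1 cm.  An optional event-level
#' bootstrap (resampling the event list and re-reconstructing) provides the
#' error bar.
#'
#' @param img a `hcc_image`.
#' @param center_a,center_b sphere centers, world mm.
#' @param radius sphere radius in mm (default 3 voxels).
#' @param events,recon optional event data.frame and reconstruction
#'   function `function(events) -> hcc_image` used for the bootstrap.
#' @param reps bootstrap replicates (0 disables; 20 is a desk-scale
#'   default).
#' @return list with `ratio`, `err` (`NA` without bootstrap), `sum_a`,
#'   `sum_b`.
#' @export
roi_ratio <- function(img, center_a, center_b, radius = NULL,
                      events = NULL, recon = NULL, reps = 0) {
  g <- img$grid
  if (is.null(radius)) radius <- 3 * g$pitch
  if (sqrt(sum((center_a - center_b)^2)) <= 2 * radius)
    stop("ROI spheres overlap")
  lo <- g$origin; hi <- g$origin + g$n * g$pitch
  for (cen in list(center_a, center_b))
    if (any(cen - radius < lo) || any(cen + radius > hi))
      stop("ROI sphere extends outside the grid")
  sa <- .roi_sum(img, center_a, radius)
  sb <- .roi_sum(img, center_b, radius)
  if (sb == 0) stop("zero denominator ROI")
  err <- NA_real_
  if (reps > 0) {
    if (is.null(events) || is.null(recon))
      stop("bootstrap needs `events` and `recon`")
    rs <- vapply(seq_len(reps), function(r) {
      ev <- events[sample.int(nrow(events), nrow(events), replace = TRUE), ,
                   drop = FALSE]
      im <- recon(ev)
      .roi_sum(im, center_a, radius) / .roi_sum(im, center_b, radius)
    }, numeric(1))
    err <- stats::sd(rs)
  }
  list(ratio = sa / sb, err = err, sum_a = sa, sum_b = sb)
}

#' Fuse single-modality images into a multi-channel volume
#'
#' Max-normalizes each channel and stacks them on the shared grid (channel
#' order preserved), the form used to project the modalities into one
#' multi-color 3D rendering.
#'
#' @param images list of `hcc_image` on identical grids.
#' @param tags channel names (default `chan1..n`).
#' @return list with `channels` (4D array x,y,z,channel), `tags`, `grid`.
#' @export
fuse_multimodal <- function(images, tags = NULL) {
  if (length(images) == 0) stop("empty image list")
  g <- images[[1]]$grid
  for (im in images)
    if (!identical(im$grid$n, g$n) || !identical(im$grid$pitch, g$pitch) ||
        !isTRUE(all.equal(im$grid$origin, g$origin)))
      stop("images are not on the same grid")
  if (is.null(tags)) tags <- paste0("chan", seq_along(images))
  arr <- array(0, c(g$n, length(images)))
  for (i in seq_along(images)) {
    m <- max(images[[i]]$values)
    arr[, , , i] <- if (m > 0) images[[i]]$values / m else images[[i]]$values
  }
  list(channels = arr, tags = tags, grid = g)
}

#' Export image slices as a 16-bit TIFF stack
#'
#' Writes the slices of [extract_slices()] as 16-bit grayscale TIFFs for
#' inspection, scaled so that the global image maximum maps to 65535; the
#' scale factor is recorded in a JSON sidecar (`scale.json`) next to the
#' images.
#'
#' @param img a `hcc_image`.
#' @param dir output directory (created if needed).
#' @param axis,pitch_mm passed to [extract_slices()].
#' @return invisibly, the written file names.
#' @export
export_slices_tiff <- function(img, dir, axis = 2, pitch_mm = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("slice export requires the tiff package")
  sl <- extract_slices(img, axis = axis, pitch_mm = pitch_mm)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(img$values)
  scale <- if (mx > 0) 1 / mx else 1
  files <- vapply(seq_along(sl), function(i) {
    f <- file.path(dir, sprintf("slice_%03d.tiff", i))
    tiff::writeTIFF(sl[[i]] * scale, f, bits.per.sample = 16L)
    f
  }, character(1))
  jsonlite::write_json(
    list(axis = axis, coords_mm = attr(sl, "coords"),
         value_at_65535 = mx, pitch_mm = img$grid$pitch),
    file.path(dir, "scale.json"), auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Extract ordered 2D slices from a 3D image
#'
#' @param img a `hcc_image`.
#' @param axis slicing axis, 1 (x), 2 (y) or 3 (z).
#' @param pitch_mm slice pitch in mm; must be a multiple of the voxel
#'   pitch (default: every voxel plane).
#' @return list of 2D matrices ordered by world coordinate along the axis;
#'   attribute `coords` gives each slice's center coordinate (mm).
#' @export
extract_slices <- function(img, axis = 2, pitch_mm = NULL) {
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  g <- img$grid
  if (is.null(pitch_mm)) pitch_mm <- g$pitch
  step <- pitch_mm / g$pitch
  if (abs(step - round(step)) > 1e-9)
    stop("slice pitch must be a multiple of the voxel pitch")
  step <- as.integer(round(step))
  planes <- seq(1, g$n[axis], by = step)
  slices <- lapply(planes, function(i)
    switch(axis, img$values[i, , ], img$values[, i, ], img$values[, , i]))
  attr(slices, "coords") <- g$origin[axis] + (planes - 0.5) * g$pitch
  slices
}
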
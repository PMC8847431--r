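# File formats: list-mode CSV (bit-exact round trip), YAML/JSON acquisition
# configs, and float32 raw volumes with a JSON sidecar (optional NIfTI
# export through RNifti).

#' Write list-mode hits to CSV
#'
#' Header `time_ns,camera_id,plane,ix,iy,energy_kev` (plus `angle_id` when
#' present).  Numeric columns are written with 17 significant digits so the
#' round trip through [read_listmode()] is bit exact.
#'
#' @param hits hits data.frame.
#' @param path output file.
#' @export
write_listmode <- function(hits, path) {
  cols <- intersect(c("angle_id", "time_ns", "camera_id", "plane",
                      "ix", "iy", "energy_kev"), names(hits))
  out <- hits[, cols, drop = FALSE]
  for (cc in cols)
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read list-mode hits from CSV
#'
#' @param path CSV written by [write_listmode()] (or conforming external
#'   data; pixel indices are 0-based, plane is `front`/`rear`).
#' @return hits data.frame.
#' @export
read_listmode <- function(path) {
  df <- utils::read.csv(path, colClasses = c(plane = "character"))
  for (cc in intersect(c("angle_id", "camera_id", "ix", "iy"), names(df)))
    df[[cc]] <- as.integer(df[[cc]])
  df
}

#' Read an acquisition configuration
#'
#' YAML (or JSON) schema:
#' \preformatted{
#' setup:
#'   n_cameras: 4
#'   angles_deg: [0, 30, 60]
#'   ring_diameter_mm: 300
#' grid: {n_voxels: [31, 31, 31], pitch_mm: 2.3}
#' sources:
#'   - {nuclide: cs137, activity_bq: 904000, position_mm: [20, 0, 20]}
#' phantoms:
#'   - {thickness_cm: 5, camera_id: 0, material: water}
#' duration_s: 60
#' }
#'
#' @param path YAML file.
#' @return list with `setup`, `grid`, `sources`, `phantoms`, `duration_s`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  su <- cfg$setup
  setup <- acquisition_setup(
    n_cameras = su$n_cameras %||% 4,
    angles_deg = unlist(su$angles_deg %||% c(0, 30, 60)),
    ring_diameter = su$ring_diameter_mm %||% 300)
  grid <- if (!is.null(cfg$grid))
    voxel_grid(n = unlist(cfg$grid$n_voxels), pitch = cfg$grid$pitch_mm %||% 2.3)
  else voxel_grid()
  sources <- lapply(cfg$sources, function(s)
    source_spec(s$nuclide, s$activity_bq, unlist(s$position_mm),
                radius = s$radius_mm %||% 0))
  phantoms <- lapply(cfg$phantoms, function(p)
    phantom_slab(p$thickness_cm, p$camera_id %||% 0L,
                 p$material %||% "water"))
  list(setup = setup, grid = grid, sources = sources, phantoms = phantoms,
       duration_s = cfg$duration_s %||% 60)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reconstructed volume as float32 raw + JSON sidecar
#'
#' @param img a `hcc_image`.
#' @param path output `.raw` path; the sidecar is written next to it as
#'   `<path>.json` with dims, pitch and origin.
#' @param nifti also write `<path>.nii.gz` (requires the RNifti package).
#' @export
write_volume <- function(img, path, nifti = FALSE) {
  con <- file(path, "wb")
  writeBin(as.vector(img$values), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(
    list(dims = img$grid$n, pitch_mm = img$grid$pitch,
         origin_mm = img$grid$origin, dtype = "float32", order = "xyz",
         n_iter = img$n_iter),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  if (nifti) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI export requires the RNifti package")
    nii <- RNifti::asNifti(img$values, pixdim = rep(img$grid$pitch, 3))
    RNifti::writeNifti(nii, paste0(path, ".nii.gz"))
  }
  invisible(path)
}

#' Read a raw volume written by [write_volume()]
#'
#' @param path `.raw` path with its `.json` sidecar.
#' @return a `hcc_image`.
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(path, "rb")
  vals <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  close(con)
  hcc_image(vals, voxel_grid(n = meta$dims, pitch = meta$pitch_mm,
                             origin = meta$origin_mm),
            n_iter = meta$n_iter %||% 0L)
}

#' Export a spectrum as two-column CSV (keV, counts)
#'
#' @param spec a `hcc_spectrum`.
#' @param path output file.
#' @export
write_spectrum <- function(spec, path) {
  bw <- diff(spec$edges)[1]
  utils::write.csv(
    data.frame(kev = spec$edges[-length(spec$edges)] + bw / 2,
               counts = spec$counts),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
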
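# PET: simple back projection of lines of response (LORs) by exact ray
# traversal.  Each LOR adds to every voxel it crosses the intersection
# length of the line with that voxel; iterative PET reconstruction is
# deliberately out of scope.

#' Back-project PET lines of response
#'
#' Siddon-style exact traversal: each LOR deposits, into every voxel it
#' crosses, the chord length (mm) of the segment inside that voxel.  Voxel
#' boundaries are half-open (a grazing segment belongs to the lower-index
#' voxel); LORs entirely outside the grid contribute nothing.
#'
#' @param lors data.frame with endpoint columns `ax, ay, az, bx, by, bz`
#'   (world mm), e.g. from [pair_pet_events()].
#' @param grid a `hcc_grid`.
#' @return a `hcc_image`; attribute `chord` holds each LOR's total chord
#'   length inside the grid (the per-LOR sum of its voxel increments).
#' @export
backproject_lors <- function(lors, grid) {
  stopifnot(prod(grid$n) > 0)
  if (nrow(lors) == 0) {
    img <- hcc_image(numeric(prod(grid$n)), grid)
    attr(img, "chord") <- numeric(0)
    return(img)
  }
  p0 <- as.matrix(lors[, c("ax", "ay", "az")])
  p1 <- as.matrix(lors[, c("bx", "by", "bz")])
  res <- cpp_siddon_backproject(p0, p1, grid$origin, grid$pitch, grid$n)
  img <- hcc_image(res$img, grid)
  attr(img, "chord") <- res$chord
  img
}
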
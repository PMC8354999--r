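#' Analysis volume grid
#'
#' A `volume_grid` is a 3-D scalar or label array on an axis-aligned grid
#' (default 2 mm isotropic) whose world origin sits at a voxel center and
#' whose x = 0 plane is the interhemispheric midline. The x dimension must be
#' odd so that the midline passes through voxel centers and the left-right
#' mirror maps voxel centers onto voxel centers.
#'
#' World coordinates of voxel `(i, j, k)` (1-based) are
#' `(idx - origin) * voxel_mm` per axis.
#'
#' @param data 3-D numeric or logical array.
#' @param voxel_mm voxel edge length in mm (isotropic), default 2.
#' @param origin 1-based voxel index (length 3) whose center is world (0,0,0).
#'   Defaults to the grid center, `(dim + 1) / 2`; the x component must then
#'   be integral, which is why the x dimension must be odd.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_mm = 2,
                        origin = (dim(data) + 1) / 2) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || voxel_mm <= 0)
    stop("`voxel_mm` must be a positive scalar")
  if (dim(data)[1] %% 2L == 0L)
    stop("x dimension must be odd so the midline plane falls on voxel centers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || origin[1] != round(origin[1]))
    stop("`origin` must be length 3 with an integral x component")
  structure(list(data = data, voxel_mm = voxel_mm, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d @ %g mm, origin voxel (%g, %g, %g)\n",
              d[1], d[2], d[3], x$voxel_mm,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' Check that two grids share shape, resolution and origin
#' @param a,b `volume_grid` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b) {
  is_volume_grid(a) && is_volume_grid(b) &&
    identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_mm, b$voxel_mm)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
  invisible(TRUE)
}

#' World coordinates of the voxel centers along one axis
#' @param grid a `volume_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of mm coordinates.
#' @export
axis_coords <- function(grid, axis) {
  (seq_len(dim(grid$data)[axis]) - grid$origin[axis]) * grid$voxel_mm
}

#' Convert world mm coordinates to (fractional) 1-based voxel indices
#' @param grid a `volume_grid`.
#' @param xyz numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @return n x 3 matrix of fractional voxel indices.
#' @export
mm_to_voxel <- function(grid, xyz) {
  xyz <- rbind(xyz)
  sweep(xyz / grid$voxel_mm, 2, grid$origin, "+")
}

#' Convert 1-based voxel indices to world mm coordinates
#' @param grid a `volume_grid`.
#' @param ijk integer matrix (n x 3) or length-3 vector of voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep(ijk, 2, grid$origin, "-") * grid$voxel_mm
}

#' Mirror a voxel index across the midline plane
#'
#' Maps `(i, j, k)` to `(nx + 1 - i, j, k)` (1-based), the reflection through
#' the x = 0 plane. The map is an involution and fixes the midline column
#' `i = (nx + 1) / 2`.
#'
#' @param ijk length-3 integer vector or n x 3 matrix of 1-based voxel indices.
#' @param grid a `volume_grid` (x dimension odd).
#' @return Mirrored indices, same shape as `ijk`.
#' @export
mirror_voxel <- function(ijk, grid) {
  nx <- dim(grid$data)[1]
  if (nx %% 2L == 0L) stop("x dimension must be odd")
  m <- rbind(ijk)
  m[, 1] <- nx + 1L - m[, 1]
  if (is.vector(ijk)) drop(m) else m
}

#' Flip a 3-D array across the midline (x) axis
#' @param arr 3-D array.
#' @return The array with the first index reversed.
#' @keywords internal
flip_x <- function(arr) {
  arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
}
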
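# Core containers. All are thin S3 wrappers around base arrays so that the
# numerical kernels can work on raw memory:
#   orv_volume : 3D array, attributes spacing (mm/voxel) and origin (mm)
#   orv_mask   : orv_volume whose data are integers {0,1}
#   orv_field  : 4D array [nx,ny,nz,3] of mm displacements + convention tag
#   orv_landmarks : n x 3 matrix of mm positions + ids
# Physical coordinates: voxel (i,j,k) (1-based) sits at
# origin + (c(i,j,k) - 1) * spacing. Axis order is x = left-right,
# y = anterior-posterior, z = superior-inferior.

#' Construct a 3D volume
#'
#' @param data 3D numeric array (x, y, z).
#' @param spacing voxel spacing in mm, length-3 (recycled if scalar).
#' @param origin physical position (mm) of voxel (1,1,1).
#' @return An `orv_volume`: the array with `spacing` and `origin` attributes.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive and finite")
  storage.mode(data) <- "double"
  structure(data, spacing = spacing, origin = rep_len(as.numeric(origin), 3L),
            class = "orv_volume")
}

#' Construct a binary mask on a volume grid
#'
#' @param data 3D array coercible to 0/1.
#' @inheritParams volume3d
#' @return An `orv_mask` (also an `orv_volume`).
#' @export
mask3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- volume3d((data != 0) * 1.0, spacing = spacing, origin = origin)
  class(v) <- c("orv_mask", class(v))
  v
}

#' Construct a dense deformation field
#'
#' @param displacements 4D array `[nx, ny, nz, 3]`, mm displacement per voxel.
#' @param spacing,origin grid geometry as for [volume3d()].
#' @param convention `"backward"` (resampling: output at x samples input at
#'   x + u(x)) or `"forward"` (point transport: a point at x moves to
#'   x + u(x)). Only backward fields are accepted by [warp_volume()].
#' @return An `orv_field`.
#' @export
deformation_field <- function(displacements, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0),
                              convention = c("backward", "forward")) {
  stopifnot(is.array(displacements), length(dim(displacements)) == 4L,
            dim(displacements)[4] == 3L)
  if (any(!is.finite(displacements)))
    stop("deformation field must be finite everywhere")
  convention <- match.arg(convention)
  storage.mode(displacements) <- "double"
  structure(displacements,
            spacing = rep_len(as.numeric(spacing), 3L),
            origin = rep_len(as.numeric(origin), 3L),
            convention = convention, class = "orv_field")
}

#' Construct an all-zero deformation field on a grid
#' @param grid_shape integer triple.
#' @inheritParams deformation_field
#' @export
zero_field <- function(grid_shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       convention = "backward") {
  deformation_field(array(0, c(grid_shape, 3L)), spacing, origin, convention)
}

#' Construct a landmark set
#'
#' @param points n x 3 matrix of physical positions (mm).
#' @param ids landmark identifiers (default `1:n`).
#' @return An `orv_landmarks` object.
#' @export
landmark_set <- function(points, ids = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  storage.mode(points) <- "double"
  if (is.null(ids)) ids <- seq_len(nrow(points))
  stopifnot(length(ids) == nrow(points))
  structure(list(points = points, ids = ids), class = "orv_landmarks")
}

#' @export
print.orv_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              class(x)[1], paste(dim(x), collapse = "x"),
              paste(signif(attr(x, "spacing"), 4), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.orv_field <- function(x, ...) {
  mag <- sqrt(x[, , , 1]^2 + x[, , , 2]^2 + x[, , , 3]^2)
  cat(sprintf("<orv_field:%s> %s voxels, |u| max %.3f mm, mean %.3f mm\n",
              attr(x, "convention"), paste(dim(x)[1:3], collapse = "x"),
              max(mag), mean(mag)))
  invisible(x)
}

#' @export
print.orv_landmarks <- function(x, ...) {
  cat(sprintf("<orv_landmarks> %d points (mm)\n", nrow(x$points)))
  invisible(x)
}

vox_spacing <- function(x) attr(x, "spacing")
vox_origin  <- function(x) attr(x, "origin")
grid_dim    <- function(x) dim(x)[1:3]

# mm position -> 0-based continuous voxel coordinate
mm_to_vox0 <- function(x, pts_mm) {
  sweep(sweep(pts_mm, 2, vox_origin(x), "-"), 2, vox_spacing(x), "/")
}
vox0_to_mm <- function(x, pts_vox) {
  sweep(sweep(pts_vox, 2, vox_spacing(x), "*"), 2, vox_origin(x), "+")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(grid_dim(a), grid_dim(b))) &&
    isTRUE(all.equal(vox_spacing(a), vox_spacing(b), tolerance = 1e-8))
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share grid shape and spacing (got %s vs %s)",
                 what, paste(grid_dim(a), collapse = "x"),
                 paste(grid_dim(b), collapse = "x")))
  invisible(TRUE)
}

# strip classes/attributes down to a bare array (for kernels)
bare <- function(x) {
  a <- as.vector(x)
  dim(a) <- dim(x)
  a
}

# field mm -> voxel units (per-axis division by spacing), bare 4D array
field_to_vox <- function(field) {
  sp <- vox_spacing(field)
  f <- bare(field)
  f[, , , 1] <- f[, , , 1] / sp[1]
  f[, , , 2] <- f[, , , 2] / sp[2]
  f[, , , 3] <- f[, , , 3] / sp[3]
  f
}

field_mag <- function(field) {
  sqrt(field[, , , 1]^2 + field[, , , 2]^2 + field[, , , 3]^2)
}
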
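# Digitally reconstructed radiographs by ray casting. A DRR follows the
# Beer-Lambert law I_n = I0 * exp(-integral mu dl): the kernel accumulates
# the line integral of the volume (interpreted as attenuation per mm) along
# each detector ray; the exponentiated intensity image is available via
# to_intensity(). Angle 0 projects along the anterior-posterior (y) axis,
# angle 90 along left-right (x); the detector v-axis is superior-inferior.

#' Projection geometry for DRR generation
#'
#' @param beam_model `"parallel"` (default; admits exact summation oracles)
#'   or `"cone"` (point source).
#' @param angles_deg the two projection angles; an orthogonal pair must
#'   differ by exactly 90 degrees.
#' @param detector_shape detector pixels (u, v).
#' @param detector_spacing detector pixel pitch mm (u, v).
#' @param source_to_axis_mm source-isocentre distance (cone beam only).
#' @param source_intensity_I0 unattenuated beam intensity.
#' @param step_mm ray-march step; must not exceed the smallest voxel spacing
#'   of the projected volume.
#' @return An `orv_proj_geometry`.
#' @export
projection_geometry <- function(beam_model = c("parallel", "cone"),
                                angles_deg = c(0, 90),
                                detector_shape = c(128L, 128L),
                                detector_spacing = c(1, 1),
                                source_to_axis_mm = 1000,
                                source_intensity_I0 = 1,
                                step_mm = 0.5) {
  beam_model <- match.arg(beam_model)
  if (any(detector_shape < 1)) stop("degenerate geometry: empty detector")
  if (step_mm <= 0) stop("step_mm must be positive")
  structure(list(beam_model = beam_model, angles_deg = angles_deg,
                 detector_shape = as.integer(detector_shape),
                 detector_spacing = as.numeric(detector_spacing),
                 source_to_axis_mm = source_to_axis_mm,
                 source_intensity_I0 = source_intensity_I0,
                 step_mm = step_mm),
            class = "orv_proj_geometry")
}

#' Line-integral image of a volume at one angle
#'
#' Ray marching with trilinear sampling at `step_mm` intervals; each sample
#' is weighted by the step length, so a homogeneous region of attenuation mu
#' crossed over a path of length l contributes mu * l. Rays outside the
#' volume contribute zero.
#'
#' @param volume an `orv_volume` (values = attenuation per mm).
#' @param geometry an `orv_proj_geometry`.
#' @param angle_deg projection angle (degrees about the SI axis).
#' @return A `detector_shape` matrix of accumulated attenuation.
#' @export
line_integral_image <- function(volume, geometry, angle_deg) {
  if (geometry$step_mm > min(vox_spacing(volume)) + 1e-9)
    stop("step_mm exceeds the smallest voxel spacing")
  cpp_raycast(bare(volume), vox_spacing(volume), angle_deg,
              geometry$detector_shape, geometry$detector_spacing,
              geometry$step_mm, geometry$beam_model == "parallel",
              geometry$source_to_axis_mm)
}

#' Convert a line-integral image to beam intensities
#'
#' Applies the Beer-Lambert law `I = I0 * exp(-L)` pixel-wise.
#'
#' @param line_image non-negative matrix of line integrals.
#' @param I0 unattenuated intensity (> 0).
#' @return Intensity image with values in `(0, I0]`.
#' @export
to_intensity <- function(line_image, I0 = 1) {
  if (I0 <= 0) stop("I0 must be positive")
  I0 * exp(-line_image)
}

#' Orthogonal DRR pair of a volume
#'
#' Renders the two projections of the geometry (default 0 and 90 degrees)
#' and min-max normalizes each to `[0, 1]` in the line-integral domain,
#' the network-input convention.
#'
#' @param volume an `orv_volume`.
#' @param geometry an `orv_proj_geometry` whose angles differ by 90 degrees.
#' @param normalize min-max normalize each image (default `TRUE`).
#' @return An `orv_projection_pair`: list with `drr_0`, `drr_90`, `geometry`
#'   and `domain_tag = "line_integral"`.
#' @export
orthogonal_pair <- function(volume, geometry = projection_geometry(),
                            normalize = TRUE) {
  if (abs(abs(diff(geometry$angles_deg)) - 90) > 1e-9)
    stop("orthogonal pair requires angles exactly 90 degrees apart")
  imgs <- lapply(geometry$angles_deg, function(a)
    line_integral_image(volume, geometry, a))
  if (normalize) imgs <- lapply(imgs, minmax01)
  structure(list(drr_0 = imgs[[1]], drr_90 = imgs[[2]], geometry = geometry,
                 domain_tag = "line_integral"),
            class = "orv_projection_pair")
}

minmax01 <- function(img) {
  r <- range(img)
  if (r[2] - r[1] < 1e-12) return(img * 0)
  (img - r[1]) / (r[2] - r[1])
}

#' @export
print.orv_projection_pair <- function(x, ...) {
  cat(sprintf("<orv_projection_pair> %s px, angles %s deg, %s beam (%s)\n",
              paste(dim(x$drr_0), collapse = "x"),
              paste(x$geometry$angles_deg, collapse = "/"),
              x$geometry$beam_model, x$domain_tag))
  invisible(x)
}
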
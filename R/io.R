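# File I/O: NIfTI volumes and 4D vector fields via RNifti, DIR-Lab-style
# landmark text files, and 32-bit float TIFF projections.

#' Write a volume or mask as NIfTI
#'
#' Spacing is stored in the header `pixdim`; the origin goes into the sform
#' translation.
#'
#' @param vol an `orv_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(bare(vol))
  RNifti::pixdim(img) <- vox_spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path input path.
#' @param mask if `TRUE` return an `orv_mask` (values binarised).
#' @return An `orv_volume` / `orv_mask`.
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  a <- array(as.numeric(img), dim = dim(img)[1:3])
  if (mask) mask3d(a, spacing = sp) else volume3d(a, spacing = sp)
}

#' Write a deformation field as 4D NIfTI
#'
#' The last axis holds the x/y/z displacement components in mm; the field
#' convention (`forward`/`backward`) is recorded in the header description.
#'
#' @param field an `orv_field`.
#' @param path output path.
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(bare(field))
  RNifti::pixdim(img) <- c(vox_spacing(field), 1)
  img$descrip <- paste0("orthoreg field convention=", attr(field, "convention"))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a deformation field written by [write_field()]
#' @param path input path.
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  conv <- if (grepl("forward", hdr$descrip)) "forward" else "backward"
  sp <- RNifti::pixdim(img)[1:3]
  deformation_field(array(as.numeric(img), dim = dim(img)[1:4]),
                    spacing = sp, convention = conv)
}

#' Write landmarks as DIR-Lab-style text
#'
#' One `x y z` triple per line, 1-based voxel indices on the stated grid. A
#' sidecar `<path>.spacing.txt` records the voxel spacing so the mm positions
#' can be recovered.
#'
#' @param lm an `orv_landmarks` (positions in mm).
#' @param path output path.
#' @param spacing,origin grid geometry used to convert mm to voxel indices.
#' @export
write_landmarks <- function(lm, path, spacing, origin = c(0, 0, 0)) {
  vox <- sweep(sweep(lm$points, 2, origin, "-"), 2, spacing, "/") + 1
  utils::write.table(format(vox, digits = 6), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(paste(spacing, collapse = " "), paste0(path, ".spacing.txt"))
  invisible(path)
}

#' Read DIR-Lab-style landmark text
#'
#' @param path input path (1-based voxel indices, whitespace separated).
#' @param spacing voxel spacing mm; if `NULL`, read from the sidecar file.
#' @param origin grid origin mm.
#' @return An `orv_landmarks` with positions in mm.
#' @export
read_landmarks <- function(path, spacing = NULL, origin = c(0, 0, 0)) {
  if (is.null(spacing)) {
    sc <- paste0(path, ".spacing.txt")
    if (!file.exists(sc)) stop("spacing not given and no sidecar found: ", sc)
    spacing <- as.numeric(strsplit(readLines(sc, n = 1), "\\s+")[[1]])
  }
  vox <- as.matrix(utils::read.table(path))
  mm <- sweep(sweep(vox - 1, 2, spacing, "*"), 2, origin, "+")
  landmark_set(mm)
}

#' Write a projection image as 32-bit float TIFF
#' @param img 2D matrix.
#' @param path output path.
#' @export
write_projection <- function(img, path) {
  tiff::writeTIFF(img / max(max(img), 1e-12), path, bits.per.sample = 32L)
  invisible(path)
}
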
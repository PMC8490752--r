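#' Read a 4-D diffusion volume with its b-values
#'
#' Reads a NIfTI volume and an FSL-style `.bval` text file (whitespace
#' separated, one value per volume) into a [dwi_volume()]. Voxel size is taken
#' from the NIfTI header.
#'
#' @param nifti_path Path to a `.nii`/`.nii.gz` file with 4 dimensions.
#' @param bval_path Path to the b-value text file.
#'
#' @return A [dwi_volume()]; the NIfTI header is kept in attribute
#'   `"reference"` so maps can be written back on the same grid.
#' @export
read_dwi <- function(nifti_path, bval_path) {
  img <- RNifti::readNifti(nifti_path)
  bvals <- read_bvals(bval_path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 4) {
    stop("expected a 4-D NIfTI, got ", length(dim(arr)), " dimensions", call. = FALSE)
  }
  if (dim(arr)[4] != length(bvals)) {
    stop("volume count (", dim(arr)[4], ") does not match b-value count (",
         length(bvals), ")", call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  dwi <- dwi_volume(arr, bvals, voxel_size = pd[1:3])
  attr(dwi, "reference") <- img
  dwi
}

#' @rdname read_dwi
#' @export
read_bvals <- function(bval_path) {
  vals <- scan(bval_path, what = numeric(), quiet = TRUE)
  if (any(vals < 0)) stop("negative b-value in ", bval_path, call. = FALSE)
  b_scheme(vals, require_b0 = FALSE)
}

#' @rdname read_dwi
#' @param bvals b-values to write.
#' @param path Output path.
#' @export
write_bvals <- function(bvals, path) {
  writeLines(paste(as.numeric(bvals), collapse = " "), path)
  invisible(path)
}

#' Write parameter maps as NIfTI with a JSON sidecar
#'
#' Writes one floating-point NIfTI per map (`<out_prefix><name>.nii.gz`,
#' `NaN` preserved for unfitted voxels) plus `<out_prefix>report.json`
#' recording the software version and any extra metadata supplied (seed,
#' configuration, ...).
#'
#' @param maps Named list of 3-D arrays on one grid.
#' @param out_prefix Output path prefix.
#' @param reference Optional NIfTI image (or [dwi_volume()] carrying one) that
#'   supplies the spatial header.
#' @param sidecar Named list merged into the JSON report.
#'
#' @return Invisibly, the paths written.
#' @export
write_maps <- function(maps, out_prefix, reference = NULL, sidecar = list()) {
  if (length(maps) == 0) {
    warning("no maps to write")
    return(invisible(character()))
  }
  dims <- unique(lapply(maps, dim))
  if (length(dims) != 1) stop("maps must share one grid", call. = FALSE)
  if (inherits(reference, "dwi_volume")) reference <- attr(reference, "reference")
  paths <- character()
  for (nm in names(maps)) {
    p <- paste0(out_prefix, nm, ".nii.gz")
    img <- if (is.null(reference)) {
      RNifti::asNifti(maps[[nm]])
    } else {
      RNifti::asNifti(maps[[nm]], reference = reference)
    }
    RNifti::writeNifti(img, p, datatype = "double")
    paths <- c(paths, p)
  }
  report <- c(list(software = "tracefit",
                   version = as.character(utils::packageVersion("tracefit")),
                   maps = names(maps)),
              sidecar)
  jp <- paste0(out_prefix, "report.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, jp))
}

#' Write a 4-D volume and its b-values
#'
#' @param dwi A [dwi_volume()].
#' @param nifti_path,bval_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_dwi <- function(dwi, nifti_path, bval_path = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::writeNifti(img, nifti_path, datatype = "double")
  if (!is.null(bval_path)) write_bvals(dwi$bvals, bval_path)
  invisible(c(nifti_path, bval_path))
}
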
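#' Read a 4D DWI volume into a stack
#'
#' The acquisition order of the 4th dimension must match the protocol's
#' sequence order (each sequence's b-values in listed order), which is the
#' layout written by [write_dwi_stack()].
#'
#' @param image path to a 4D NIfTI file.
#' @param prot a `dwi_protocol` describing the acquisitions.
#' @return A [dwi_stack()] with the NIfTI affine preserved.
#' @export
read_dwi_stack <- function(image, prot) {
  img <- RNifti::readNifti(image)
  vol <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vol)) != 4L) stop("expected a 4D NIfTI volume")
  idx <- protocol_index(prot)
  if (nrow(idx) != dim(vol)[4])
    stop("protocol implies ", nrow(idx), " acquisitions but image has ",
         dim(vol)[4])
  dwi_stack(vol, idx, affine = RNifti::xform(img))
}

#' Write a DWI stack / parameter maps / mask to NIfTI
#'
#' Parameter maps are written one 3D float32 NIfTI per map
#' (`d`, `v_in`, `d_ex`, `cellularity`, `rss`, `converged`,
#' `adc_<label>`...), preserving the affine.
#'
#' @param stack a [dwi_stack()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return The written path(s), invisibly.
#' @export
write_dwi_stack <- function(stack, path) {
  stopifnot(inherits(stack, "dwi_stack"))
  img <- RNifti::asNifti(stack$volume)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @param maps a `param_maps` object from [fit_volume()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @rdname write_dwi_stack
#' @export
write_param_maps <- function(maps, dir, prefix = "map") {
  stopifnot(inherits(maps, "param_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  names <- c("d", "v_in", "d_ex", "cellularity", "rss", "converged",
             "at_bound", paste0("adc_", maps$labels))
  out <- character(0)
  for (nm in names) {
    arr <- maps[[nm]]
    if (is.logical(arr)) arr <- array(as.numeric(arr), dim(arr))
    arr[is.na(arr)] <- 0
    f <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(arr), f, datatype = "float")
    out <- c(out, f)
  }
  invisible(out)
}

#' @param mask 3D logical array.
#' @param path output file.
#' @rdname write_dwi_stack
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))),
                     path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_dwi_stack
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0, dim = dim(img))
}
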
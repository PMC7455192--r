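#' Write a BOLD series to a NIfTI volume plus ROI mask
#'
#' Lays the voxels of a `bold_series` out along one spatial axis of a 4-D
#' NIfTI image (x = voxel, t = volume) and writes a matching binary ROI
#' mask, so the series can round-trip through standard neuroimaging
#' containers. A plain tab-separated matrix (volumes x voxels) writer is
#' also available via `format = "tsv"`.
#'
#' @param bold A `bold_series`.
#' @param path Output path (`.nii`/`.nii.gz`, or `.tsv`).
#' @param format `"nifti"` or `"tsv"`.
#' @param mask_path Where to write the ROI mask (NIfTI only); default
#'   alongside `path` with a `_mask` suffix.
#' @return `path`, invisibly.
#' @export
write_bold <- function(bold, path, format = c("nifti", "tsv"),
                       mask_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(bold$data, path, sep = "\t", quote = FALSE,
                       row.names = FALSE,
                       col.names = paste0("v", seq_len(ncol(bold$data))))
    return(invisible(path))
  }
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required to write NIfTI volumes")
  }
  nv <- ncol(bold$data)
  arr <- array(t(bold$data), dim = c(nv, 1, 1, nrow(bold$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, bold$tr)  # time step carries the TR
  RNifti::writeNifti(img, path)
  mask_path <- mask_path %||% sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  RNifti::writeNifti(RNifti::asNifti(array(1L, dim = c(nv, 1, 1))),
                     mask_path)
  invisible(path)
}

#' Read an ROI BOLD series from a NIfTI volume
#'
#' Extracts the time series of all voxels inside `mask` (nonzero mask
#' values) from a 4-D NIfTI image and returns a `bold_series` usable by
#' the pattern-similarity pipeline.
#'
#' @param path 4-D NIfTI image path.
#' @param mask_path Optional 3-D mask path; all voxels are used when
#'   missing.
#' @param tr Repetition time in seconds; taken from the NIfTI header's
#'   time step when `NULL` and positive.
#' @param roi_label Label for the returned series.
#' @return A `bold_series`.
#' @export
read_bold_nifti <- function(path, mask_path = NULL, tr = NULL,
                            roi_label = "roi") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required to read NIfTI volumes")
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  stopifnot(length(dim(arr)) == 4)
  n_vol <- dim(arr)[4]
  flat <- matrix(arr, ncol = n_vol)  # voxels x volumes
  if (!is.null(mask_path)) {
    m <- as.array(RNifti::readNifti(mask_path))
    flat <- flat[as.logical(m != 0), , drop = FALSE]
  }
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2.5
  }
  structure(
    list(data = t(flat), tr = tr, n_volumes = n_vol,
         volume_onsets = (seq_len(n_vol) - 1) * tr,
         roi_label = roi_label),
    class = "bold_series"
  )
}
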
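#' Read a CT or mask volume from NRRD or NIfTI
#'
#' Volumes are normalized to the internal `(slice, row, col)` axis order on
#' read, whatever the on-disk order of the format. The through-plane spacing
#' (voxel depth) is taken from the file header.
#'
#' @param path Path to a `.nrrd`, `.nii` or `.nii.gz` file.
#' @param format `"nrrd"` or `"nifti"`; guessed from the extension by default.
#' @param case_id Case identifier; defaults to the file name without extension.
#' @return A [ct_volume()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path, format = guess_format(path),
                        case_id = sub("\\.(nrrd|nii|nii\\.gz)$", "",
                                      basename(path))) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  format <- match.arg(format, c("nrrd", "nifti"))
  if (format == "nrrd") {
    r <- read_nrrd(path)
    ct_volume(r$data, voxel_depth = r$spacings[3],
              in_plane_spacing = c(r$spacings[2], r$spacings[1]),
              case_id = case_id)
  } else {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("non-3D payload: NIfTI has ", length(d), " dimensions", call. = FALSE)
    pd <- RNifti::pixdim(img)  # (col, row, slice) spacing
    ct_volume(aperm(unclass(as.array(img)), c(3, 2, 1)),
              voxel_depth = pd[3], in_plane_spacing = c(pd[2], pd[1]),
              case_id = case_id)
  }
}

#' Write a CT volume to NRRD or NIfTI
#'
#' The file round-trips through [read_volume()] with identical intensities,
#' shape, and spacing.
#'
#' @param volume A [ct_volume()].
#' @param path Output path.
#' @param format `"nrrd"` or `"nifti"`; guessed from the extension by default.
#' @param type On-disk scalar type for NRRD (`"double"`, `"float"`,
#'   `"int16"`, `"uint8"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = guess_format(path),
                         type = "double") {
  format <- match.arg(format, c("nrrd", "nifti"))
  sp <- c(volume$in_plane_spacing[2], volume$in_plane_spacing[1],
          volume$voxel_depth)
  if (format == "nrrd") {
    write_nrrd(volume$slices, path, spacings = sp, type = type)
  } else {
    arr <- aperm(volume$slices, c(3, 2, 1))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path,
                       datatype = if (type == "double") "double" else type)
  }
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, format = guess_format(path),
                      case_id = sub("\\.(nrrd|nii|nii\\.gz)$", "",
                                    basename(path))) {
  v <- read_volume(path, format, case_id)
  mask_volume(v$slices, case_id = case_id)
}

#' @rdname write_volume
#' @param mask A [mask_volume()].
#' @export
write_mask <- function(mask, path, format = guess_format(path)) {
  v <- ct_volume(mask$masks + 0, voxel_depth = 1, case_id = mask$case_id)
  write_volume(v, path, format, type = "uint8")
}

guess_format <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else stop("cannot guess format from extension: ", path, call. = FALSE)
}

#' Case manifests
#'
#' A case manifest records, per case, the image path, contrast level
#' (from [classify_level()]), voxel depth and slice count. Persisted as CSV
#' with columns `case_id, path, level, voxel_depth_mm, n_slices`
#' (plus `mask_path` and `seed` when known).
#'
#' @param entries A data frame with at least the columns above.
#' @return A `case_manifest` (a classed data frame).
#' @export
case_manifest <- function(entries) {
  req <- c("case_id", "path", "level", "voxel_depth_mm", "n_slices")
  miss <- setdiff(req, names(entries))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(entries$case_id))
    stop("case_ids must be unique", call. = FALSE)
  structure(as.data.frame(entries), class = c("case_manifest", "data.frame"))
}

#' @rdname case_manifest
#' @param path CSV path.
#' @export
write_manifest <- function(entries, path) {
  utils::write.csv(as.data.frame(entries), path, row.names = FALSE)
  invisible(path)
}

#' @rdname case_manifest
#' @export
read_manifest <- function(path) {
  case_manifest(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = c(level = "character")))
}
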
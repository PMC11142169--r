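sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a scalar volume as NIfTI-1 with a JSON sidecar
#'
#' The NIfTI header carries the diagonal affine (voxel size in mm); quantity
#' labels, units and provenance that the header cannot hold go to a JSON
#' sidecar next to the image.
#'
#' @param vol 3D numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size Voxel edge length in mm.
#' @param quantity Quantity label (e.g. `"OSS"`, `"t"`, `"AFD"`); defaults to
#'   the volume's `quantity` attribute.
#' @param provenance Optional list stored verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = 2, quantity = NULL, provenance = NULL) {
  if (is.null(quantity)) quantity <- attr(vol, "quantity") %||% "scalar"
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)[1:3]))
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(quantity = quantity, voxel_size_mm = voxel_size, provenance = provenance),
    sidecar_path(path),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' Read a NIfTI-1 scalar volume (with optional sidecar and grid check)
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param reference Optional array (or dim triple) the volume must align to;
#'   a mismatch raises an alignment error naming both shapes.
#' @return 3D array with `voxel_size` and `quantity` attributes.
#' @export
read_volume <- function(path, reference = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  img <- tryCatch(
    suppressWarnings(RNifti::readNifti(path)),
    error = function(e) {
      stop(sprintf("malformed NIfTI file %s: %s", path, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  arr <- array(as.numeric(img), dim(img)[1:3])
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[1]
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    attr(arr, "quantity") <- meta$quantity
    if (!is.null(meta$voxel_size_mm)) attr(arr, "voxel_size") <- meta$voxel_size_mm
  }
  if (!is.null(reference)) {
    ref_dim <- if (is.numeric(reference) && length(reference) == 3L) {
      as.integer(reference)
    } else {
      dim(reference)[1:3]
    }
    if (!identical(dim(arr)[1:3], ref_dim)) {
      stop(sprintf(
        "alignment error: volume %s is %s but the reference grid is %s",
        path, paste(dim(arr)[1:3], collapse = "x"), paste(ref_dim, collapse = "x")
      ), call. = FALSE)
    }
  }
  arr
}

#' Write a complex displacement field as paired real/imaginary NIfTI volumes
#'
#' Stored as two 4D files (`<stem>_real.nii.gz`, `<stem>_imag.nii.gz`, last
#' dimension the three displacement components) plus a JSON sidecar with the
#' frequency and actuation labels.
#'
#' @param u `displacement_vol` (complex `nx x ny x nz x 3` array).
#' @param stem Output path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_displacement <- function(u, stem) {
  stopifnot(length(dim(u)) == 4L, dim(u)[4] == 3L)
  vs <- attr(u, "voxel_size") %||% 2
  for (part in c("real", "imag")) {
    vals <- if (part == "real") Re(u) else Im(u)
    img <- RNifti::asNifti(array(vals, dim(u)))
    RNifti::pixdim(img) <- c(rep(vs, 3), 1)
    RNifti::writeNifti(img, paste0(stem, "_", part, ".nii.gz"))
  }
  jsonlite::write_json(
    list(
      quantity = "displacement_mm",
      frequency_hz = attr(u, "frequency"), actuation = attr(u, "actuation"),
      voxel_size_mm = vs
    ),
    paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' Read a displacement field written by [write_displacement()]
#'
#' @param stem Path stem used at write time.
#' @return Complex `displacement_vol` array.
#' @export
read_displacement <- function(stem) {
  re <- RNifti::readNifti(paste0(stem, "_real.nii.gz"))
  im <- RNifti::readNifti(paste0(stem, "_imag.nii.gz"))
  u <- array(as.numeric(re) + 1i * as.numeric(im), dim(re))
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  structure(u,
    class = "displacement_vol",
    frequency = meta$frequency_hz, actuation = meta$actuation,
    voxel_size = meta$voxel_size_mm
  )
}

#' Write / read a cohort manifest TSV
#'
#' @param manifest Tibble of per-subject records (e.g. `subject_id`, `group`,
#'   `path`, `actuation`, `frequency`).
#' @param path TSV path.
#' @return The manifest (invisibly on write).
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
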
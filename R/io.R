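#' Read and write volumes as NIfTI
#'
#' Voxel geometries, field maps and parametric maps are exchanged as NIfTI
#' volumes with the grid spacing in the header (`pixdim`, micrometres for
#' micro-scale volumes). Occupancy volumes are binary-valued; field maps are
#' in rad/s.
#'
#' @param v a `vmrf_voxel`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly (writers); the reconstructed object (readers).
#' @export
write_voxel_nifti <- function(v, path) {
  img <- RNifti::asNifti(array(as.numeric(v$occupancy), dim(v$occupancy)))
  RNifti::pixdim(img) <- v$grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_voxel_nifti
#' @export
read_voxel_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  sp[sp == 0] <- 1
  grid <- grid_spec(dim(arr), sp)
  voxel_geometry(arr != 0, grid, provenance = "user")
}

#' @rdname write_voxel_nifti
#' @param field a `vmrf_field`.
#' @export
write_field_nifti <- function(field, path) {
  img <- RNifti::asNifti(field$db)
  RNifti::pixdim(img) <- field$grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_voxel_nifti
#' @param maps a `vmrf_maps`.
#' @param dir output directory; one file per parameter plus the mask.
#' @param spacing acquisition voxel spacing recorded in the headers.
#' @export
write_maps_nifti <- function(maps, dir, spacing = c(1, 1, 1)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in names(maps$maps)) {
    arr <- maps$maps[[p]]
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing[seq_along(dim(arr))]
    RNifti::writeNifti(img, file.path(dir, paste0(p, ".nii.gz")))
  }
  mask <- RNifti::asNifti(array(as.numeric(maps$mask), dim(maps$mask)))
  RNifti::writeNifti(mask, file.path(dir, "mask.nii.gz"))
  invisible(dir)
}

#' @rdname write_voxel_nifti
#' @param series fingerprint series array (last dimension = samples).
#' @export
write_series_nifti <- function(series, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(series)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_voxel_nifti
#' @export
read_series_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Export GESFIDSE signals or fingerprints as CSV
#'
#' @param x a tibble from [simulate_gesfidse()] or a `vmrf_fingerprint`.
#' @param path output CSV path.
#' @export
write_signal_csv <- function(x, path) {
  if (inherits(x, "vmrf_fingerprint")) {
    x <- tibble(
      sample = seq_along(x$values),
      phase = rep(c("pre", "post"), each = x$n_echoes),
      value = x$values
    )
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
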
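#' Write a simulated BOLD run as a NIfTI-1 volume
#'
#' Packs a voxels x timepoints matrix into a 4D volume using the voxel
#' grid of a [simulate_bold()] dataset and writes it with the dataset's
#' affine and TR. Grid cells not covered by any simulated voxel are zero.
#'
#' @param sim a `bold_sim` object.
#' @param run run index.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_bold_nifti <- function(sim, run, path) {
  stopifnot(inherits(sim, "bold_sim"))
  data <- sim$runs[[run]]
  vm <- sim$voxel_map
  idx <- cbind(vm$i, vm$j, vm$k)
  idx <- sweep(idx, 2, apply(idx, 2, min))          # shift to 0-based grid
  dims <- apply(idx, 2, max) + 1L
  vol <- array(0, dim = c(dims, ncol(data)))
  for (t in seq_len(ncol(data))) {
    vol[cbind(idx + 1L, t)] <- data[, t]
  }
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(diag(sim$affine)[1:3], sim$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI volume as a voxels x timepoints matrix
#'
#' @param path NIfTI file.
#' @param mask optional logical 3D array selecting voxels; default all
#'   voxels with any non-zero timepoint.
#' @return list with `data` (voxels x timepoints), `voxel_map` (0-based
#'   grid indices), `tr`, `affine`.
#' @export
read_bold_nifti <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  stopifnot(length(dim(vol)) == 4)
  if (is.null(mask)) {
    mask <- apply(vol != 0, 1:3, any)
  }
  idx <- which(mask, arr.ind = TRUE)
  data <- t(apply(idx, 1, function(v) vol[v[1], v[2], v[3], ]))
  list(data = data,
       voxel_map = data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                              k = idx[, 3] - 1L),
       tr = RNifti::pixdim(img)[4],
       affine = structure(RNifti::xform(img), class = "matrix"))
}

#' Write / read BIDS-style event tables
#'
#' Tab-separated with columns `onset` (s), `duration` (s), `condition`,
#' `item_id`, `rt_ms`, `correct` (0/1).
#'
#' @param events data.frame of events.
#' @param path file path (`.tsv`).
#' @return `write_events` returns the path invisibly; `read_events`
#'   returns the data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
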
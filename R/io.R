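#' Read a Sleuth-style foci table
#'
#' Tab-separated with header columns `experiment_id`, `study_id`, `x_mm`,
#' `y_mm`, `z_mm`, `n_subjects`, `direction`, `diagnosis`, `space`; one row
#' per focus. `direction` is `"increase"` or `"decrease"`.
#'
#' @param path TSV file path.
#' @return data.frame of foci.
#' @export
read_foci <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_foci(df)
  df
}

#' Write a foci table
#' @param foci foci data.frame (see [read_foci()] for columns).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_foci <- function(foci, path) {
  validate_foci(foci)
  utils::write.table(foci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

foci_columns <- c("experiment_id", "study_id", "x_mm", "y_mm", "z_mm",
                  "n_subjects", "direction", "diagnosis", "space")

validate_foci <- function(df) {
  missing <- setdiff(foci_columns, names(df))
  if (length(missing))
    stop("foci table is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) > 0) {
    if (any(!is.finite(df$x_mm) | !is.finite(df$y_mm) | !is.finite(df$z_mm)))
      stop("focus coordinates must be finite")
    if (any(df$n_subjects < 1)) stop("`n_subjects` must be >= 1")
    if (!all(df$direction %in% c("increase", "decrease")))
      stop("`direction` must be 'increase' or 'decrease'")
  }
  invisible(df)
}

# Split a foci table into a list of experiments, preserving first-seen order.
split_foci <- function(df) {
  validate_foci(df)
  ids <- unique(df$experiment_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$experiment_id == id, , drop = FALSE]
    list(experiment_id = id,
         foci = as.matrix(rows[, c("x_mm", "y_mm", "z_mm")]),
         n_subjects = rows$n_subjects[1],
         direction = rows$direction[1],
         diagnosis = rows$diagnosis[1])
  })
  stats::setNames(out, ids)
}

#' Apply a user-supplied stereotactic space transform to a foci table
#'
#' Applies a 4x4 affine (e.g. an MNI-to-Talairach conversion) to the focus
#' coordinates at load time; no conversion matrix is built in.
#'
#' @param foci foci data.frame.
#' @param transform 4x4 affine matrix, or `NULL` for identity.
#' @param target_space label written into the `space` column.
#' @return The transformed foci table.
#' @export
transform_foci <- function(foci, transform = NULL, target_space = NULL) {
  validate_foci(foci)
  if (!is.null(transform)) {
    if (!is.matrix(transform) || !all(dim(transform) == c(4L, 4L)))
      stop("`transform` must be a 4x4 matrix")
    xyz <- cbind(as.matrix(foci[, c("x_mm", "y_mm", "z_mm")]), 1) %*% t(transform)
    foci[, c("x_mm", "y_mm", "z_mm")] <- xyz[, 1:3]
  }
  if (!is.null(target_space)) foci$space <- target_space
  foci
}

#' Read a NIfTI-1 volume as a `volume_grid`
#'
#' Expects an axis-aligned affine with positive scales; the world origin is
#' recovered from the translation column and must land on a voxel center.
#'
#' @param path NIfTI file path.
#' @return A `volume_grid`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  sc <- diag(aff[1:3, 1:3])
  off <- aff[1:3, 4]
  if (any(abs(aff[1:3, 1:3] - diag(sc)) > 1e-6))
    stop("only axis-aligned volumes are supported")
  if (max(abs(sc - sc[1])) > 1e-6) stop("anisotropic voxels are not supported")
  origin <- round(1 - off / sc, 4)   # snap float32 header error
  if (abs(origin[1] - round(origin[1])) > 1e-4)
    stop("midline (x) origin does not fall on a voxel center")
  origin[1] <- round(origin[1])
  volume_grid(as.array(img), voxel_mm = sc[1], origin = origin)
}

#' Write a `volume_grid` as NIfTI-1
#' @param grid a `volume_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(is_volume_grid(grid))
  aff <- diag(c(rep(grid$voxel_mm, 3), 1))
  aff[1:3, 4] <- -(grid$origin - 1) * grid$voxel_mm
  img <- RNifti::asNifti(grid$data * 1)
  RNifti::pixdim(img) <- rep(grid$voxel_mm, 3)
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an edge-statistics table as TSV
#' @param edges edge table from [edge_statistics()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-statistics table written by [write_edges()]
#' @param path TSV path.
#' @return data.frame of edge statistics.
#' @export
read_edges <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write the synthetic ground truth as JSON
#' @param truth list of [ground_truth()] entries.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(lapply(truth, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
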
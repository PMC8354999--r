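#' Mirror-symmetric parcellation with homotopic pairs
#'
#' Container for a symmetrized label volume plus the table of homotopic node
#' pairs. The left hemisphere is an exact mirror copy of the right one, so
#' every labeled voxel at x > 0 has a partner voxel at -x carrying the paired
#' left node id. Midline-plane voxels (x = 0) are labeled `midline` and take
#' part in no pair.
#'
#' @param labels `volume_grid` of integer node ids (0 = background).
#' @param pairs data.frame with columns `pair_id`, `right_node_id`,
#'   `left_node_id`, `n_voxels_per_side`.
#' @param node_side named character vector mapping node id to
#'   `"right"`, `"left"` or `"midline"`.
#' @return An object of class `symmetric_atlas`.
#' @export
symmetric_atlas <- function(labels, pairs, node_side) {
  stopifnot(is_volume_grid(labels))
  req <- c("pair_id", "right_node_id", "left_node_id", "n_voxels_per_side")
  if (!all(req %in% names(pairs))) stop("`pairs` is missing required columns")
  if (anyDuplicated(c(pairs$right_node_id, pairs$left_node_id)))
    stop("node ids must be unique across pairs")
  structure(list(labels = labels, pairs = pairs, node_side = node_side),
            class = "symmetric_atlas")
}

#' @export
print.symmetric_atlas <- function(x, ...) {
  cat(sprintf("<symmetric_atlas> %d homotopic pairs, grid %s\n",
              nrow(x$pairs), paste(dim(x$labels$data), collapse = " x ")))
  invisible(x)
}

#' Validate a symmetric atlas
#'
#' Checks the mirror invariant exhaustively (every labeled voxel's mirror
#' carries the paired label), equal per-side voxel counts, and that no pair
#' node has zero voxels.
#'
#' @param atlas a `symmetric_atlas`.
#' @return `TRUE` invisibly; errors describe the violated invariant.
#' @export
validate_symmetric_atlas <- function(atlas) {
  lab <- atlas$labels$data
  pr <- atlas$pairs
  nx <- dim(lab)[1]
  mid <- (nx + 1L) / 2L
  flip <- flip_x(lab)
  r2l <- stats::setNames(pr$left_node_id, pr$right_node_id)
  l2r <- stats::setNames(pr$right_node_id, pr$left_node_id)
  for (p in seq_len(nrow(pr))) {
    rmask <- lab == pr$right_node_id[p]
    if (!identical(which(flip == pr$left_node_id[p]), which(rmask)))
      stop(sprintf("pair %s violates mirror symmetry", pr$pair_id[p]))
    nr <- sum(rmask)
    nl <- sum(lab == pr$left_node_id[p])
    if (nr == 0L) stop(sprintf("pair %s has an empty node", pr$pair_id[p]))
    if (nr != nl) stop(sprintf("pair %s has unequal voxel counts", pr$pair_id[p]))
    if (any(rmask[mid, , ])) stop("paired labels must not touch the midline plane")
  }
  invisible(TRUE)
}

#' Symmetrize a parcellation about the midline
#'
#' Replaces the left hemisphere (x < 0) with the mirror image of the right
#' one (x > 0). Each right-hemisphere node id keeps its label on the right
#' and is assigned a fresh partner id on the left; the pair table records the
#' correspondence. Voxels on the x = 0 plane keep their original label,
#' are marked `midline`, and enter no pair.
#'
#' @param raw_labels `volume_grid` of integer labels (0 = background),
#'   already resampled to the analysis grid (see [resample_labels()]).
#' @return A `symmetric_atlas`.
#' @export
symmetrize_atlas <- function(raw_labels) {
  stopifnot(is_volume_grid(raw_labels))
  lab <- raw_labels$data
  storage.mode(lab) <- "integer"
  nx <- dim(lab)[1]
  mid <- (nx + 1L) / 2L
  right <- seq_len(mid - 1L) + mid          # indices with x > 0
  right_ids <- sort(unique(as.vector(lab[right, , , drop = FALSE])))
  right_ids <- right_ids[right_ids != 0L]
  if (length(right_ids) == 0L)
    stop("atlas has no right-hemisphere labels to mirror")

  offset <- max(as.vector(lab))             # fresh ids for left partners
  left_ids <- right_ids + offset
  remap <- integer(max(right_ids))
  remap[right_ids] <- left_ids

  out <- lab
  rblock <- lab[right, , , drop = FALSE]
  lblock <- rblock
  pos <- rblock != 0L
  lblock[pos] <- remap[rblock[pos]]
  out[rev(seq_len(mid - 1L)), , ] <- lblock  # mirror: right row r -> left row mid - r

  counts <- tabulate(rblock[pos], nbins = max(right_ids))
  pairs <- data.frame(
    pair_id = paste0("P", seq_along(right_ids)),
    right_node_id = right_ids,
    left_node_id = left_ids,
    n_voxels_per_side = counts[right_ids],
    stringsAsFactors = FALSE
  )
  # midline-plane voxels keep their anatomy but get ids disjoint from the
  # pair nodes, so a label spanning the plane cannot alias its right node
  mslice <- out[mid, , ]
  mpos <- mslice != 0L
  mslice[mpos] <- mslice[mpos] + 2L * offset
  out[mid, , ] <- mslice
  mid_ids <- setdiff(unique(as.vector(mslice)), 0L)
  node_side <- c(
    stats::setNames(rep("right", length(right_ids)), right_ids),
    stats::setNames(rep("left", length(left_ids)), left_ids),
    stats::setNames(rep("midline", length(mid_ids)), mid_ids)
  )
  symmetric_atlas(volume_grid(out, raw_labels$voxel_mm, raw_labels$origin),
                  pairs, node_side)
}

#' Nearest-neighbour resampling of a label volume onto the analysis grid
#'
#' Labels are categorical, so resampling is nearest-neighbour: each target
#' voxel center is mapped through the (optional) affine into the source
#' volume and takes the label of the closest source voxel; targets falling
#' outside the source get background 0.
#'
#' @param raw_labels source `volume_grid` of integer labels.
#' @param target_grid `volume_grid` defining the output geometry.
#' @param transform optional 4x4 affine mapping target world mm to source
#'   world mm (e.g. a user-supplied MNI-to-Talairach matrix); identity by
#'   default. Must be invertible.
#' @return `volume_grid` of labels on `target_grid`.
#' @export
resample_labels <- function(raw_labels, target_grid, transform = NULL) {
  stopifnot(is_volume_grid(raw_labels), is_volume_grid(target_grid))
  if (is.null(transform)) transform <- diag(4)
  if (!is.matrix(transform) || !all(dim(transform) == c(4L, 4L)))
    stop("`transform` must be a 4x4 matrix")
  if (abs(det(transform)) < .Machine$double.eps^0.5)
    stop("`transform` is not invertible")

  dims <- dim(target_grid$data)
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  mm <- voxel_to_mm(target_grid, ijk)
  src_mm <- cbind(mm, 1) %*% t(transform)
  src_vox <- round(mm_to_voxel(raw_labels, src_mm[, 1:3, drop = FALSE]))
  sd <- dim(raw_labels$data)
  ok <- src_vox[, 1] >= 1 & src_vox[, 1] <= sd[1] &
        src_vox[, 2] >= 1 & src_vox[, 2] <= sd[2] &
        src_vox[, 3] >= 1 & src_vox[, 3] <= sd[3]
  out <- integer(prod(dims))
  out[ok] <- raw_labels$data[src_vox[ok, , drop = FALSE]]
  volume_grid(array(out, dims), target_grid$voxel_mm, target_grid$origin)
}
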
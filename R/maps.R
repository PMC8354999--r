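#' Render edge statistics into a brain volume
#'
#' Paints each pair's statistic onto all voxels of both member regions, on
#' the x100 reporting scale. For `stat_kind = "kappa"` both members receive
#' kappa x 100, so the map is exactly mirror-symmetric. For `"tau"` the
#' right member receives +tau x 100 and the left member -tau x 100
#' (antisymmetric rendering: directionality proceeds from positive toward
#' negative areas), so the map equals the negative of its x-flip.
#'
#' @param atlas a `symmetric_atlas`.
#' @param edges edge table from [edge_statistics()].
#' @param stat_kind `"kappa"` or `"tau"`.
#' @param only_significant if `TRUE` (default) only significant edges are
#'   painted; with `FALSE`, kappa is painted wherever defined and tau is
#'   recomputed from the stored joint counts for every pair with defined
#'   marginals (the unthresholded variant).
#' @return A `volume_grid` of stat x 100 values (0 where unpainted), with
#'   attributes `stat_kind` and `rendering`.
#' @export
render_pair_map <- function(atlas, edges, stat_kind = c("kappa", "tau"),
                            only_significant = TRUE) {
  stat_kind <- match.arg(stat_kind)
  lab <- atlas$labels$data
  out <- array(0, dim(lab))
  for (p in seq_len(nrow(edges))) {
    if (only_significant && !isTRUE(edges$significant[p])) next
    if (stat_kind == "kappa") {
      v <- edges$kappa[p]
      if (is.na(v)) next
      sel <- lab == edges$right_node[p] | lab == edges$left_node[p]
      out[sel] <- v * 100
    } else {
      v <- edges$tau[p]
      if (is.na(v) && !only_significant) {
        N <- edges$N[p]
        v <- patel_tau(c(edges$z1[p], edges$z2[p], edges$z3[p], edges$z4[p]) / N)
      }
      if (is.na(v)) next
      out[lab == edges$right_node[p]] <- v * 100
      out[lab == edges$left_node[p]] <- -v * 100
    }
  }
  res <- volume_grid(out, atlas$labels$voxel_mm, atlas$labels$origin)
  attr(res, "stat_kind") <- stat_kind
  attr(res, "rendering") <- if (stat_kind == "kappa") "symmetric"
                            else "antisymmetric (+ right member, - left member)"
  res
}

#' Decompose a rendered map over large-scale network labels
#'
#' For each network id, the mean of the rendered statistic over the
#' network's in-mask voxels (zeros included), already on the x100 scale.
#' Networks with no in-mask voxels are reported with `NA` mean and zero
#' voxels.
#'
#' @param map a rendered `volume_grid` (values on the x100 scale).
#' @param network_labels `volume_grid` of integer network ids (0 =
#'   background) on the same grid.
#' @param mask optional logical array or `volume_grid` restricting the
#'   decomposition (default: all voxels with a network label).
#' @return data.frame: `network_id`, `mean_stat_x100`, `n_voxels`.
#' @export
network_decomposition <- function(map, network_labels, mask = NULL) {
  stop_if_grid_mismatch(map, network_labels)
  lab <- network_labels$data
  keep <- lab > 0
  if (!is.null(mask)) keep <- keep & as_mask_array(mask, map)
  ids <- sort(unique(as.vector(lab[lab > 0])))
  res <- data.frame(network_id = ids,
                    mean_stat_x100 = NA_real_,
                    n_voxels = 0L)
  for (r in seq_along(ids)) {
    sel <- keep & lab == ids[r]
    n <- sum(sel)
    res$n_voxels[r] <- n
    if (n > 0) res$mean_stat_x100[r] <- mean(map$data[sel])
  }
  res
}

#' Region-wise correlation of two edge profiles
#'
#' Pearson correlation of kappa over the homotopic pairs shared by two edge
#' tables (e.g. a PHAC run vs an MHC run), matched by `pair_id` and using
#' only pairs with defined kappa in both.
#'
#' @param edges_a,edges_b edge tables from [edge_statistics()].
#' @return List: `r` (Pearson correlation), `n_pairs` (pairs used).
#' @export
compare_edge_profiles <- function(edges_a, edges_b) {
  m <- merge(edges_a[, c("pair_id", "kappa")],
             edges_b[, c("pair_id", "kappa")],
             by = "pair_id", suffixes = c("_a", "_b"))
  m <- m[is.finite(m$kappa_a) & is.finite(m$kappa_b), ]
  if (nrow(m) < 3L)
    stop("need at least 3 shared pairs with defined kappa")
  if (stats::sd(m$kappa_a) == 0 || stats::sd(m$kappa_b) == 0)
    stop("an edge profile has zero variance; correlation undefined")
  list(r = stats::cor(m$kappa_a, m$kappa_b), n_pairs = nrow(m))
}
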
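#' Run the full foci-to-edges pipeline
#'
#' For each experiment: build the MA map from its foci, apply midline
#' compensation, threshold into a binary alteration volume; then summarise
#' all experiments over the atlas into the alteration matrix and compute
#' per-pair edge statistics (Patel's kappa, Monte Carlo significance,
#' Patel's tau on significant edges).
#'
#' The identical code path serves morphometric alteration foci (PHAC) and
#' functional activation foci (MHC); only the `label` differs.
#'
#' @param foci foci data.frame (see [read_foci()]).
#' @param atlas a `symmetric_atlas`.
#' @param mask logical array or `volume_grid` of in-brain voxels.
#' @param config a [phac_config()].
#' @param label free-text run label stored in the result (e.g. `"PHAC"`,
#'   `"MHC"`).
#' @return An object of class `phac_result`: `edges` (see
#'   [edge_statistics()]), `matrix` (alteration matrix), `binary_maps`
#'   (list of binary `volume_grid`s), `config`, `label`.
#' @export
run_phac <- function(foci, atlas, mask, config = phac_config(),
                     label = "PHAC") {
  foci_list <- as_foci_list(foci)
  if (length(foci_list) == 0L) stop("foci table contains no experiments")
  grid <- atlas$labels
  if (!is.null(config$seed)) set.seed(config$seed)

  binary_maps <- lapply(foci_list, function(fe) {
    ma <- build_ma_map(fe$foci, grid, mask, fwhm = config$fwhm,
                       n_subjects = fe$n_subjects,
                       experiment_id = fe$experiment_id)
    ma <- apply_midline_compensation(ma, config$midline_radius_mm,
                                     config$midline_kernel)
    attr(ma, "n_foci") <- nrow(fe$foci)
    threshold_ma(ma, mask, method = config$threshold_method,
                 alpha = config$alpha, cutoff = config$cutoff,
                 n_null = config$n_null, seed = NULL)
  })
  mat <- build_alteration_matrix(binary_maps, atlas, frac = config$frac)
  cfg_edges <- config
  cfg_edges$seed <- NULL        # continue the run's RNG stream
  edges <- edge_statistics(mat, atlas, cfg_edges)
  structure(list(edges = edges, matrix = mat, binary_maps = binary_maps,
                 config = config, label = label),
            class = "phac_result")
}

#' @export
print.phac_result <- function(x, ...) {
  cat(sprintf("<phac_result> %s: %d experiments x %d nodes, %d/%d pairs significant\n",
              x$label, nrow(x$matrix), ncol(x$matrix),
              sum(x$edges$significant), nrow(x$edges)))
  invisible(x)
}

#' Run the pipeline on functional activation foci (MHC)
#'
#' Same code path as [run_phac()]; the result is labeled `"MHC"` so that
#' downstream comparisons read naturally.
#'
#' @inheritParams run_phac
#' @return A `phac_result` labeled MHC.
#' @export
run_mhc <- function(foci, atlas, mask, config = phac_config()) {
  run_phac(foci, atlas, mask, config, label = "MHC")
}
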
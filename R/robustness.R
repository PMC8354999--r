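#' Jackknife quadratic error per experiment
#'
#' Publication-bias screen: with S0 the ALE union of all experiments' MA
#' maps and S_k the union with experiment k removed,
#' E_k = sum_i (S_ik - S_i0)^2 over voxels i. E_k is minimal when the
#' leave-one-out map converges to the total map; it is reported x 100.
#'
#' The per-experiment MA maps are built once; each leave-one-out union is
#' recovered exactly from the cached product form 1 - prod(1 - MA_i) by
#' dividing out the removed factor (with the 1 - MA = 0 factors tracked
#' separately so saturated voxels stay exact).
#'
#' @param foci foci table (see [read_foci()]) or a named list of n x 3 foci
#'   matrices, one per experiment.
#' @param grid analysis `volume_grid`.
#' @param mask logical array or `volume_grid` of in-brain voxels.
#' @param config a [phac_config()] (FWHM and midline settings are used).
#' @return An object of class `jackknife_result`: data.frame `errors`
#'   (`experiment_id`, `E_k`, `E_k_x100`), `frac_low` (fraction of
#'   experiments with E_k x 100 in \[0, 0.5\]), and `histogram`
#'   (`graphics::hist` object of E_k x 100, not plotted).
#' @export
jackknife_errors <- function(foci, grid, mask, config = phac_config()) {
  foci_list <- as_foci_list(foci)
  if (length(foci_list) == 0L) stop("no experiments supplied")
  mas <- lapply(seq_along(foci_list), function(i) {
    ma <- build_ma_map(foci_list[[i]]$foci, grid, mask, fwhm = config$fwhm,
                       n_subjects = foci_list[[i]]$n_subjects,
                       experiment_id = names(foci_list)[i])
    apply_midline_compensation(ma, config$midline_radius_mm,
                               config$midline_kernel)
  })

  one_minus <- lapply(mas, function(m) 1 - m$volume$data)
  log_sum <- array(0, dim(grid$data))       # sum of log(1 - MA) over nonzero factors
  n_zero <- array(0L, dim(grid$data))       # count of factors equal to zero
  for (om in one_minus) {
    z <- om == 0
    n_zero <- n_zero + z
    log_sum <- log_sum + ifelse(z, 0, log(om))
  }
  S0 <- 1 - ifelse(n_zero > 0L, 0, exp(log_sum))

  E <- vapply(seq_along(one_minus), function(k) {
    om <- one_minus[[k]]
    z <- om == 0
    rest_zero <- n_zero - z
    rest_log <- log_sum - ifelse(z, 0, log(om))
    Sk <- 1 - ifelse(rest_zero > 0L, 0, exp(rest_log))
    sum((Sk - S0)^2)
  }, numeric(1))

  errors <- data.frame(
    experiment_id = names(foci_list) %||% as.character(seq_along(foci_list)),
    E_k = E,
    E_k_x100 = E * 100,
    stringsAsFactors = FALSE
  )
  structure(list(
    errors = errors,
    frac_low = mean(errors$E_k_x100 >= 0 & errors$E_k_x100 <= 0.5),
    histogram = graphics::hist(errors$E_k_x100, plot = FALSE)
  ), class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("<jackknife_result> %d experiments, %.1f%% with E_k (x100) in [0, 0.5]\n",
              nrow(x$errors), 100 * x$frac_low))
  invisible(x)
}

# Accept a foci data.frame (Sleuth-style columns) or a prepared list.
as_foci_list <- function(foci) {
  if (is.data.frame(foci)) return(split_foci(foci))
  foci
}

#' Bootstrap reliability of the edge statistics
#'
#' Resamples experiments (the exchangeable unit: rows of the alteration
#' matrix) with replacement `B` times, recomputes the edge statistics per
#' resample, and summarises per pair the fraction of resamples in which the
#' edge is significant, plus the Pearson correlation between the
#' bootstrap-mean kappa and the full-data kappa.
#'
#' @param matrix alteration matrix from [build_alteration_matrix()].
#' @param atlas a `symmetric_atlas`.
#' @param B number of bootstrap resamples (>= 1; default 200 keeps full
#'   refits at desk scale; the published analysis used 5000).
#' @param config a [phac_config()]; its `n_samples`, `e`, `criterion` and
#'   `prior_mode` drive each refit.
#' @param seed RNG seed (resampling and posterior draws).
#' @return List: `table` (data.frame `pair_id`, `freq_significant`,
#'   `kappa_full`, `kappa_boot_mean`), `r_kappa` (correlation of bootstrap
#'   mean vs full-data kappa over pairs defined in both), `B`.
#' @export
bootstrap_reliability <- function(matrix, atlas, B = 200,
                                  config = phac_config(), seed = NULL) {
  if (B < 1) stop("`B` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$seed <- NULL                          # one RNG stream for the whole run
  full <- edge_statistics(matrix, atlas, cfg)
  n <- nrow(matrix)
  np <- nrow(full)
  sig_count <- numeric(np)
  kap_sum <- numeric(np)
  kap_n <- numeric(np)
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    eb <- edge_statistics(matrix[rows, , drop = FALSE], atlas, cfg)
    sig_count <- sig_count + (eb$significant %in% TRUE)
    ok <- is.finite(eb$kappa)
    kap_sum[ok] <- kap_sum[ok] + eb$kappa[ok]
    kap_n[ok] <- kap_n[ok] + 1
  }
  tab <- data.frame(
    pair_id = full$pair_id,
    freq_significant = sig_count / B,
    kappa_full = full$kappa,
    kappa_boot_mean = ifelse(kap_n > 0, kap_sum / kap_n, NA_real_),
    stringsAsFactors = FALSE
  )
  ok <- is.finite(tab$kappa_full) & is.finite(tab$kappa_boot_mean)
  r <- if (sum(ok) >= 3 &&
           stats::sd(tab$kappa_full[ok]) > 0 &&
           stats::sd(tab$kappa_boot_mean[ok]) > 0)
    stats::cor(tab$kappa_full[ok], tab$kappa_boot_mean[ok])
  else NA_real_
  list(table = tab, r_kappa = r, B = B)
}
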
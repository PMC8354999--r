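#' Gaussian width from full-width at half-maximum
#'
#' sigma = FWHM / sqrt(8 ln 2).
#'
#' @param fwhm_mm full-width at half-maximum in mm, > 0.
#' @return Standard deviation sigma in mm.
#' @export
sigma_from_fwhm <- function(fwhm_mm) {
  if (!is.numeric(fwhm_mm) || any(!is.finite(fwhm_mm)) || any(fwhm_mm <= 0))
    stop("`fwhm_mm` must be positive and finite")
  fwhm_mm / sqrt(8 * log(2))
}

#' Spatial uncertainty model for an experiment
#'
#' Every reported focus is modeled as the center of an isotropic 3-D Gaussian
#' whose width reflects spatial uncertainty. The width can be fixed (default
#' FWHM 10 mm) or depend on the number of subjects through a user-supplied
#' function; the subject-based mapping published elsewhere is not hardcoded.
#'
#' @param kind `"fixed"` or `"subject_based"`.
#' @param fixed_fwhm_mm FWHM in mm used when `kind = "fixed"`.
#' @param subject_based_fn function `n_subjects -> FWHM mm`; required when
#'   `kind = "subject_based"`; must return positive values for all n >= 1.
#' @return An object of class `fwhm_model`.
#' @export
fwhm_model <- function(kind = c("fixed", "subject_based"),
                       fixed_fwhm_mm = 10,
                       subject_based_fn = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (fixed_fwhm_mm <= 0) stop("`fixed_fwhm_mm` must be positive")
  } else if (!is.function(subject_based_fn)) {
    stop("`subject_based_fn` must be a function for subject-based models")
  }
  structure(list(kind = kind, fixed_fwhm_mm = fixed_fwhm_mm,
                 subject_based_fn = subject_based_fn),
            class = "fwhm_model")
}

fwhm_for <- function(model, n_subjects) {
  f <- if (model$kind == "fixed") model$fixed_fwhm_mm
       else model$subject_based_fn(n_subjects)
  if (!is.finite(f) || f <= 0)
    stop("FWHM model produced a non-positive width")
  f
}

#' Gaussian focus density
#'
#' Density per mm^3 at Euclidean distance `d_mm` from a focus:
#' p(d) = sigma^-3 (2 pi)^-3/2 exp(-d^2 / (2 sigma^2)).
#'
#' @param d_mm nonnegative distance(s) in mm.
#' @param sigma_mm Gaussian standard deviation in mm, > 0.
#' @return Density value(s), per mm^3.
#' @export
gaussian_focus_density <- function(d_mm, sigma_mm) {
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || sigma_mm <= 0)
    stop("`sigma_mm` must be a positive scalar")
  if (any(d_mm < 0)) stop("`d_mm` must be nonnegative")
  (2 * pi)^(-1.5) / sigma_mm^3 * exp(-d_mm^2 / (2 * sigma_mm^2))
}

#' Build a modeled alteration (MA) map for one experiment
#'
#' Each focus contributes a truncated Gaussian probability cloud; the
#' per-voxel MA value is the maximum over foci of density x voxel volume,
#' clipped to \[0, 1\], and zero outside the brain mask. Foci falling outside
#' the mask are dropped with a warning (the count is recorded).
#'
#' @param foci n x 3 matrix of focus coordinates in mm (world space of the
#'   grid); zero rows give an all-zero map.
#' @param grid a `volume_grid` defining the analysis space.
#' @param mask logical array on `grid` (in-brain voxels), or a `volume_grid`
#'   of logicals.
#' @param fwhm an `fwhm_model`, or a single FWHM in mm.
#' @param n_subjects subject count of the experiment (used by subject-based
#'   FWHM models).
#' @param experiment_id identifier stored in the result.
#' @param trunc_sd truncation radius of the Gaussian cloud in units of sigma
#'   (default 4; contributions beyond it are numerically negligible).
#' @return An object of class `ma_map`: fields `volume` (`volume_grid` of
#'   probabilities), `experiment_id`, `sigma_mm`, `n_dropped_foci`.
#' @export
build_ma_map <- function(foci, grid, mask, fwhm = fwhm_model(),
                         n_subjects = NA_integer_,
                         experiment_id = NA_character_,
                         trunc_sd = 4) {
  mask_arr <- as_mask_array(mask, grid)
  if (is.numeric(fwhm) && length(fwhm) == 1L)
    fwhm <- fwhm_model(fixed_fwhm_mm = fwhm)
  sigma <- sigma_from_fwhm(fwhm_for(fwhm, n_subjects))

  dims <- dim(grid$data)
  out <- array(0, dims)
  foci <- if (is.null(foci) || length(foci) == 0L) {
    matrix(numeric(0), ncol = 3)
  } else rbind(foci)
  if (ncol(foci) != 3L) stop("`foci` must have three columns (x, y, z mm)")
  if (any(!is.finite(foci))) stop("focus coordinates must be finite")

  n_dropped <- 0L
  if (nrow(foci) > 0) {
    vox <- mm_to_voxel(grid, foci)
    nearest <- round(vox)
    inside <- nearest[, 1] >= 1 & nearest[, 1] <= dims[1] &
              nearest[, 2] >= 1 & nearest[, 2] <= dims[2] &
              nearest[, 3] >= 1 & nearest[, 3] <= dims[3]
    in_mask <- inside
    in_mask[inside] <- mask_arr[nearest[inside, , drop = FALSE]]
    n_dropped <- sum(!in_mask)
    if (n_dropped > 0)
      warning(sprintf("dropped %d focus/foci outside the brain mask", n_dropped))
    foci <- foci[in_mask, , drop = FALSE]

    vol_mm3 <- grid$voxel_mm^3
    r_mm <- trunc_sd * sigma
    r_vox <- ceiling(r_mm / grid$voxel_mm)
    cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
    for (f in seq_len(nrow(foci))) {
      ctr <- round(mm_to_voxel(grid, foci[f, ]))
      i0 <- max(1L, ctr[1] - r_vox); i1 <- min(dims[1], ctr[1] + r_vox)
      j0 <- max(1L, ctr[2] - r_vox); j1 <- min(dims[2], ctr[2] + r_vox)
      k0 <- max(1L, ctr[3] - r_vox); k1 <- min(dims[3], ctr[3] + r_vox)
      dx2 <- (cx[i0:i1] - foci[f, 1])^2
      dy2 <- (cy[j0:j1] - foci[f, 2])^2
      dz2 <- (cz[k0:k1] - foci[f, 3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      val <- vol_mm3 * (2 * pi)^(-1.5) / sigma^3 * exp(-d2 / (2 * sigma^2))
      blk <- out[i0:i1, j0:j1, k0:k1]
      out[i0:i1, j0:j1, k0:k1] <- pmax(blk, val)
    }
  }
  out <- pmin(out, 1)
  out[!mask_arr] <- 0
  structure(list(volume = volume_grid(out, grid$voxel_mm, grid$origin),
                 experiment_id = experiment_id,
                 sigma_mm = sigma,
                 n_dropped_foci = n_dropped),
            class = "ma_map")
}

as_mask_array <- function(mask, grid) {
  arr <- if (is_volume_grid(mask)) {
    stop_if_grid_mismatch(mask, grid)
    mask$data
  } else mask
  if (!identical(dim(arr), dim(grid$data)))
    stop("mask does not match the analysis grid")
  arr <- arr != 0
  arr
}

#' Midline compensation of an MA map
#'
#' A focus close to the interhemispheric plane spills probability into both
#' hemispheres, producing spurious homotopic co-alteration. Voxels whose
#' midline distance |x| is below `radius_mm` (default 12 mm, the mean extent
#' of the probabilistic cloud for typical meta-analytic uncertainty) are
#' re-weighted by a function of their distance d to the midline:
#'
#' * `kernel = "inverse"` (default, weight proportional to 1/d):
#'   w(d) = radius / max(d, voxel size), value <- min(1, value x w);
#' * `kernel = "attenuate"`: w(d) = d / radius, value <- value x w.
#'
#' Voxels with |x| >= `radius_mm` are unchanged. The kernel used is recorded
#' in the returned object.
#'
#' @param ma an `ma_map`.
#' @param radius_mm compensation radius in mm (default 12).
#' @param kernel `"inverse"` or `"attenuate"`.
#' @return The compensated `ma_map`, with a `midline_kernel` field added.
#' @export
apply_midline_compensation <- function(ma, radius_mm = 12,
                                       kernel = c("inverse", "attenuate")) {
  kernel <- match.arg(kernel)
  grid <- ma$volume
  x <- abs(axis_coords(grid, 1))
  w <- rep(1, length(x))
  near <- x < radius_mm
  if (kernel == "inverse") {
    w[near] <- radius_mm / pmax(x[near], grid$voxel_mm)
  } else {
    w[near] <- pmax(x[near], 0) / radius_mm
  }
  out <- grid$data * w[slice.index(grid$data, 1)]
  out <- pmin(out, 1)
  ma$volume <- volume_grid(out, grid$voxel_mm, grid$origin)
  ma$midline_kernel <- kernel
  ma$midline_radius_mm <- radius_mm
  ma
}

#' Threshold an MA map into a binary alteration volume
#'
#' Two operational readings of "thresholded at p = 0.05" are provided:
#'
#' * `method = "null_quantile"` (default): the null distribution of a
#'   voxel's MA value is estimated by `n_null` random placements of the same
#'   number of foci uniformly over mask voxel centers (one random in-mask
#'   target voxel per draw); the threshold is the (1 - alpha) quantile of
#'   those null values. Seeded and reproducible.
#' * `method = "absolute"`: a user-supplied cutoff on the MA value.
#'
#' @param ma an `ma_map` (its recorded sigma drives the null kernel).
#' @param mask logical array or `volume_grid` of in-brain voxels.
#' @param method `"null_quantile"` or `"absolute"`.
#' @param alpha tail probability for the null quantile (default 0.05).
#' @param cutoff absolute MA cutoff when `method = "absolute"`.
#' @param n_null number of null placements (default 1000).
#' @param n_foci number of foci to match in the null; defaults to the
#'   experiment's own (taken from `attr(ma, "n_foci")` if present, else 1).
#' @param seed RNG seed for the null placements.
#' @return A binary (0/1) `volume_grid`; the threshold used is attached as
#'   attribute `"threshold"`.
#' @export
threshold_ma <- function(ma, mask, method = c("null_quantile", "absolute"),
                         alpha = 0.05, cutoff = NULL, n_null = 1000,
                         n_foci = NULL, seed = NULL) {
  method <- match.arg(method)
  grid <- ma$volume
  mask_arr <- as_mask_array(mask, grid)
  if (!any(mask_arr)) stop("mask is empty")
  if (method == "absolute") {
    if (is.null(cutoff) || cutoff < 0) stop("`cutoff` must be supplied and >= 0")
    thr <- cutoff
  } else {
    if (is.null(n_foci)) n_foci <- attr(ma, "n_foci") %||% 1L
    n_foci <- max(1L, as.integer(n_foci))
    thr <- null_ma_threshold(grid, mask_arr, ma$sigma_mm, n_foci,
                             alpha = alpha, n_null = n_null, seed = seed)
  }
  out <- (grid$data >= thr & grid$data > 0 & mask_arr) * 1
  res <- volume_grid(out, grid$voxel_mm, grid$origin)
  attr(res, "threshold") <- thr
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Null distribution of a voxel's MA value under uniform random placement of
# n_foci foci in the mask: per draw, one random target voxel and n_foci focus
# voxels, value = max over foci of the truncated Gaussian kernel.
null_ma_threshold <- function(grid, mask_arr, sigma_mm, n_foci,
                              alpha = 0.05, n_null = 1000, seed = NULL) {
  if (n_null < 1) stop("`n_null` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- which(mask_arr)
  dims <- dim(mask_arr)
  coords <- arrayInd(idx, dims)
  mm <- voxel_to_mm(volume_grid(array(0, dims), grid$voxel_mm, grid$origin),
                    coords)
  vol_mm3 <- grid$voxel_mm^3
  vals <- numeric(n_null)
  for (b in seq_len(n_null)) {
    tgt <- mm[sample.int(nrow(mm), 1L), ]
    foc <- mm[sample.int(nrow(mm), n_foci, replace = TRUE), , drop = FALSE]
    d2 <- (foc[, 1] - tgt[1])^2 + (foc[, 2] - tgt[2])^2 + (foc[, 3] - tgt[3])^2
    vals[b] <- min(1, vol_mm3 * max(gaussian_focus_density(sqrt(d2), sigma_mm)))
  }
  stats::quantile(vals, 1 - alpha, names = FALSE, type = 7)
}

#' ALE union of modeled alteration maps
#'
#' Per voxel, ALE = 1 - prod_i (1 - MA_i): the probability that at least one
#' experiment models an alteration there. Permutation-invariant and
#' associative over groupings.
#'
#' @param ma_maps non-empty list of `ma_map` objects (or `volume_grid`s) on
#'   a shared grid.
#' @return A `volume_grid` of ALE values in \[0, 1\].
#' @export
ale_union <- function(ma_maps) {
  if (length(ma_maps) == 0L) stop("`ma_maps` must contain at least one map")
  grids <- lapply(ma_maps, function(m) if (inherits(m, "ma_map")) m$volume else m)
  g0 <- grids[[1]]
  acc <- 1 - g0$data
  for (g in grids[-1]) {
    stop_if_grid_mismatch(g0, g)
    acc <- acc * (1 - g$data)
  }
  volume_grid(1 - acc, g0$voxel_mm, g0$origin)
}
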
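#' Pipeline configuration
#'
#' Collects the tunable parameters of the foci-to-edges pipeline. Defaults
#' follow the published analysis settings where they are stated (midline
#' radius 12 mm, 20% VOI rule, 5000 posterior samples, e = 0.01, 0.95
#' criterion) and the package's documented choices elsewhere (fixed FWHM
#' 10 mm, inverse midline kernel, conjugate Dirichlet posterior).
#'
#' @param fwhm an [fwhm_model()] or a single FWHM in mm (default 10).
#' @param midline_kernel `"inverse"` or `"attenuate"` (see
#'   [apply_midline_compensation()]).
#' @param midline_radius_mm compensation radius (default 12).
#' @param threshold_method `"null_quantile"` or `"absolute"` (see
#'   [threshold_ma()]).
#' @param alpha tail probability for the null-quantile threshold.
#' @param cutoff absolute MA cutoff used when `threshold_method =
#'   "absolute"` (default 0.005, roughly a 3 mm reach around a focus at
#'   FWHM 10 mm).
#' @param n_null null placements for the quantile threshold.
#' @param frac VOI alteration fraction, inclusive (default 0.20).
#' @param n_samples Dirichlet posterior draws per edge (default 5000).
#' @param e kappa significance margin (default 0.01).
#' @param criterion posterior proportion for significance (default 0.95,
#'   exceeded strictly).
#' @param prior_mode `"conjugate"` or `"paper"` (see
#'   [kappa_significance()]).
#' @param seed RNG seed for threshold nulls and posterior draws.
#' @return An object of class `phac_config`.
#' @export
phac_config <- function(fwhm = 10,
                        midline_kernel = c("inverse", "attenuate"),
                        midline_radius_mm = 12,
                        threshold_method = c("null_quantile", "absolute"),
                        alpha = 0.05, cutoff = 0.005, n_null = 1000,
                        frac = 0.20,
                        n_samples = 5000, e = 0.01, criterion = 0.95,
                        prior_mode = c("conjugate", "paper"),
                        seed = NULL) {
  if (is.numeric(fwhm)) fwhm <- fwhm_model(fixed_fwhm_mm = fwhm)
  structure(list(
    fwhm = fwhm,
    midline_kernel = match.arg(midline_kernel),
    midline_radius_mm = midline_radius_mm,
    threshold_method = match.arg(threshold_method),
    alpha = alpha, cutoff = cutoff, n_null = n_null,
    frac = frac,
    n_samples = n_samples, e = e, criterion = criterion,
    prior_mode = match.arg(prior_mode),
    seed = seed
  ), class = "phac_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [phac_config()]; `fwhm` may be a
#' number (fixed model). Unknown keys are rejected to catch typos.
#'
#' @param path YAML file path.
#' @return A `phac_config`.
#' @export
read_phac_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(phac_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(phac_config, vals)
}
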
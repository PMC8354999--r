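#' Build the experiments x nodes alteration matrix
#'
#' A node counts as altered in an experiment when the thresholded MA map
#' covers at least `frac` (default 20%, boundary inclusive) of the node's
#' voxels.
#'
#' @param binary_maps list of binary `volume_grid`s (one per experiment,
#'   names taken as experiment ids) on the atlas grid.
#' @param atlas a `symmetric_atlas`; every pair node must have >= 1 voxel.
#' @param frac minimum altered-voxel fraction, inclusive (default 0.20).
#' @return Binary integer matrix, rows = experiments, columns = all pair
#'   nodes of the atlas (column names = node ids, right nodes first per pair
#'   order then left nodes).
#' @export
build_alteration_matrix <- function(binary_maps, atlas, frac = 0.20) {
  lab <- atlas$labels$data
  node_ids <- c(atlas$pairs$right_node_id, atlas$pairs$left_node_id)
  nmax <- max(node_ids, 1L)
  sizes <- tabulate(lab[lab > 0L], nbins = nmax)[node_ids]
  if (any(sizes == 0L)) stop("atlas contains pair nodes with zero voxels")

  out <- matrix(0L, nrow = length(binary_maps), ncol = length(node_ids),
                dimnames = list(names(binary_maps), node_ids))
  for (e in seq_along(binary_maps)) {
    bm <- binary_maps[[e]]
    stop_if_grid_mismatch(bm, atlas$labels)
    hit <- lab[bm$data != 0]
    cnt <- tabulate(hit[hit > 0L], nbins = nmax)[node_ids]
    out[e, ] <- as.integer(cnt / sizes >= frac)
  }
  out
}

#' Joint alteration counts for a homotopic pair
#'
#' Counts, over the N experiments, the four joint states of the pair
#' (a = right-hemisphere member, b = left member):
#' z1: a = 1, b = 1; z2: a = 0, b = 1; z3: a = 1, b = 0; z4: a = 0, b = 0.
#' theta = z / N are the joint state probabilities.
#'
#' @param matrix binary alteration matrix from [build_alteration_matrix()].
#' @param right_node,left_node node ids (matched against column names).
#' @return List with integer `z` (length 4), `theta` (length 4) and `N`.
#' @export
joint_counts <- function(matrix, right_node, left_node) {
  N <- nrow(matrix)
  if (N == 0L) stop("alteration matrix has no experiments")
  a <- matrix[, as.character(right_node)]
  b <- matrix[, as.character(left_node)]
  z <- c(sum(a == 1 & b == 1), sum(a == 0 & b == 1),
         sum(a == 1 & b == 0), sum(a == 0 & b == 0))
  list(z = as.integer(z), theta = z / N, N = N)
}

#' Patel's kappa
#'
#' Normalized excess of the joint alteration probability theta1 over the
#' independence expectation E = (theta1 + theta2)(theta1 + theta3):
#'
#' kappa = (theta1 - E) / \[D (max(theta1) - E) + (1 - D)(E - min(theta1))\]
#'
#' with max(theta1) = min(theta1 + theta2, theta1 + theta3),
#' min(theta1) = max(0, 2 theta1 + theta2 + theta3 - 1), and the weight
#' D = (theta1 - E) / (2 (max(theta1) - E)) + 0.5 when theta1 >= E,
#' else 0.5 - (E - theta1) / (2 (E - min(theta1))). The weight runs from 0
#' (theta1 at its Frechet lower bound) through 0.5 (independence) to 1
#' (theta1 at its upper bound), so the normalizer interpolates between the
#' two attainable extremes and kappa lies in \[-1, 1\];
#' it is 0 at independence, 1 at perfect co-occurrence and -1 at perfect
#' exclusion. When a marginal is 0 or 1 the normalizer degenerates and
#' `NA` is returned (the reason is attached as attribute `"degenerate"`
#' for scalar input).
#'
#' @param theta probability 4-vector (theta1..theta4) on the simplex, or an
#'   n x 4 matrix of such rows.
#' @return kappa value(s); `NA_real_` where degenerate.
#' @export
patel_kappa <- function(theta) {
  th <- check_theta(theta)
  t1 <- th[, 1]; t2 <- th[, 2]; t3 <- th[, 3]
  pb <- t1 + t2                 # P(b = 1), left member
  pa <- t1 + t3                 # P(a = 1), right member
  E <- pa * pb
  mx <- pmin(pa, pb)
  mn <- pmax(0, 2 * t1 + t2 + t3 - 1)
  eps <- 1e-12
  degen <- pa < eps | pb < eps | pa > 1 - eps | pb > 1 - eps
  num <- t1 - E
  up <- num >= 0
  D <- numeric(length(num))
  D[up] <- num[up] / (2 * (mx[up] - E[up])) + 0.5
  D[!up] <- 0.5 + num[!up] / (2 * (E[!up] - mn[!up]))
  k <- num / (D * (mx - E) + (1 - D) * (E - mn))
  k <- pmin(1, pmax(-1, k))   # guard float overshoot at the attained bounds
  k[degen] <- NA_real_
  if (!is.matrix(theta) && length(degen) == 1L && degen)
    attr(k, "degenerate") <- "marginal probability of a node is 0 or 1"
  k
}

#' Patel's tau
#'
#' Directionality index built from the two marginal alteration
#' probabilities P(a) = theta1 + theta3 and P(b) = theta1 + theta2:
#'
#' tau = 1 - P(a)/P(b) if theta2 >= theta3, else P(b)/P(a) - 1.
#'
#' tau lies in \[-1, 1\] and sign(tau) = sign(theta2 - theta3)
#' = sign(P(b) - P(a)). It is undefined (`NA`) only when the pair is never
#' altered (theta1 = theta2 = theta3 = 0), where the active branch's
#' denominator vanishes.
#'
#' @param theta probability 4-vector or n x 4 matrix of rows on the simplex.
#' @return tau value(s); `NA_real_` where undefined.
#' @export
patel_tau <- function(theta) {
  th <- check_theta(theta)
  t1 <- th[, 1]; t2 <- th[, 2]; t3 <- th[, 3]
  pb <- t1 + t2
  pa <- t1 + t3
  eps <- 1e-12
  undef <- (t1 + t2 + t3) < eps
  b1 <- t2 >= t3
  tau <- numeric(length(t1))
  tau[b1] <- 1 - pa[b1] / pb[b1]
  tau[!b1] <- pb[!b1] / pa[!b1] - 1
  tau[undef] <- NA_real_
  tau
}

check_theta <- function(theta) {
  th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1L)
  if (ncol(th) != 4L) stop("`theta` must have four components")
  if (any(th < -1e-9)) stop("`theta` components must be nonnegative")
  s <- rowSums(th)
  if (any(abs(s - 1) > 1e-6)) stop("`theta` rows must sum to 1")
  th
}

#' Monte Carlo significance of Patel's kappa
#'
#' Multinomial likelihood with a Dirichlet prior gives a Dirichlet
#' posterior over theta; `n_samples` posterior draws are scored and the edge
#' is significant when the fraction of draws with kappa > `e` exceeds
#' `criterion` (strictly).
#'
#' Two posterior parameterizations are available. The conjugate default uses
#' gamma_i = z_i + alpha_i with a flat prior alpha_i = 1, which is proper for
#' any counts. `prior_mode = "paper"` uses the mode-centred form
#' gamma_i = alpha_i + z_i - 1 (alpha_i = 1), guarding empty cells with
#' gamma_i = max(z_i, 0.5). The mode used is recorded on the result.
#'
#' @param z integer joint counts (z1..z4) or the list from [joint_counts()].
#' @param n_samples posterior draws (default 5000).
#' @param e kappa significance margin (default 0.01).
#' @param criterion posterior proportion required for significance,
#'   exceeded strictly (default 0.95).
#' @param prior_mode `"conjugate"` (default) or `"paper"`.
#' @param seed RNG seed for reproducible draws.
#' @return List: `prop_exceed` (fraction of draws with kappa > e),
#'   `significant` (logical), `prior_mode`.
#' @export
kappa_significance <- function(z, n_samples = 5000, e = 0.01,
                               criterion = 0.95,
                               prior_mode = c("conjugate", "paper"),
                               seed = NULL) {
  prior_mode <- match.arg(prior_mode)
  if (is.list(z)) z <- z$z
  if (length(z) != 4L || any(z < 0)) stop("`z` must be four nonnegative counts")
  if (sum(z) < 1) stop("joint counts cover no experiments")
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  gamma <- if (prior_mode == "conjugate") z + 1 else pmax(z, 0.5)
  draws <- rdirichlet(n_samples, gamma)
  kap <- patel_kappa(draws)
  prop <- mean(kap > e, na.rm = TRUE)
  list(prop_exceed = prop, significant = prop > criterion,
       prior_mode = prior_mode)
}

# Dirichlet sampler via normalized gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Edge statistics for every homotopic pair
#'
#' For each atlas pair (a = right member, b = left member): joint counts,
#' Patel's kappa from the observed theta, Monte Carlo significance, and
#' Patel's tau computed only on edges whose kappa reached significance
#' (`NA` elsewhere). Pairs with degenerate marginals keep their row with
#' `NA` kappa so column bookkeeping stays aligned.
#'
#' @param matrix alteration matrix from [build_alteration_matrix()].
#' @param atlas a `symmetric_atlas`.
#' @param config a [phac_config()] (fields `n_samples`, `e`, `criterion`,
#'   `prior_mode`, `seed` are used).
#' @return data.frame with one row per pair: `pair_id`, `right_node`,
#'   `left_node`, `N`, `z1`..`z4`, `kappa`, `prop_exceed`, `significant`,
#'   `tau`. Attribute `"convention"` records the a = right / b = left sign
#'   convention and the prior mode.
#' @export
edge_statistics <- function(matrix, atlas, config = phac_config()) {
  pr <- atlas$pairs
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(pr)
  out <- data.frame(
    pair_id = pr$pair_id,
    right_node = pr$right_node_id,
    left_node = pr$left_node_id,
    N = nrow(matrix),
    z1 = integer(n), z2 = integer(n), z3 = integer(n), z4 = integer(n),
    kappa = NA_real_, prop_exceed = NA_real_,
    significant = FALSE, tau = NA_real_,
    stringsAsFactors = FALSE
  )
  for (p in seq_len(n)) {
    jc <- joint_counts(matrix, pr$right_node_id[p], pr$left_node_id[p])
    out[p, c("z1", "z2", "z3", "z4")] <- as.list(jc$z)
    kap <- patel_kappa(jc$theta)
    out$kappa[p] <- kap
    if (is.na(kap)) next        # degenerate marginals: reported, not tested
    sig <- kappa_significance(jc$z, n_samples = config$n_samples,
                              e = config$e, criterion = config$criterion,
                              prior_mode = config$prior_mode, seed = NULL)
    out$prop_exceed[p] <- sig$prop_exceed
    out$significant[p] <- sig$significant
    if (sig$significant) out$tau[p] <- patel_tau(jc$theta)
  }
  attr(out, "convention") <-
    list(a = "right-hemisphere member", b = "left-hemisphere member",
         tau_sign = "tau > 0 when P(b) > P(a)",
         prior_mode = config$prior_mode)
  out
}

#' Grid-search bounds of kappa and tau over the probability simplex
#'
#' Evaluates both statistics on the full lattice
#' theta = (i, j, k, n - i - j - k) / n with n = 1/step, drops undefined
#' (degenerate) points, and returns the attained extrema. Used to verify
#' the published \[-1, 1\] ranges are sharp.
#'
#' @param step lattice spacing on the simplex (default 0.005).
#' @return List: `kappa_max`, `kappa_min`, `tau_max`, `tau_min`,
#'   `n_grid_points` (lattice size before dropping degenerate points).
#' @export
patel_bounds <- function(step = 0.005) {
  n <- round(1 / step)
  if (abs(n * step - 1) > 1e-9) stop("`step` must divide 1")
  # enumerate i + j + k <= n
  ij <- do.call(rbind, lapply(0:n, function(a)
    cbind(a, 0:(n - a))))
  reps <- n - ij[, 1] - ij[, 2] + 1L
  th12 <- ij[rep(seq_len(nrow(ij)), reps), , drop = FALSE]
  k <- unlist(lapply(reps, function(r) 0:(r - 1L)), use.names = FALSE)
  th <- cbind(th12, k, n - th12[, 1] - th12[, 2] - k) / n
  colnames(th) <- NULL
  kap <- patel_kappa(th)
  tau <- patel_tau(th)
  list(kappa_max = max(kap, na.rm = TRUE),
       kappa_min = min(kap, na.rm = TRUE),
       tau_max = max(tau, na.rm = TRUE),
       tau_min = min(tau, na.rm = TRUE),
       n_grid_points = nrow(th))
}
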
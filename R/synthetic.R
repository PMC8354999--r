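#' Ground truth for one synthetic homotopic pair
#'
#' A planted (non-null) pair follows the spread model: the source-side node
#' is altered with probability `p_source`; given a source alteration the
#' contralateral homologue is altered with probability `p_spread`, otherwise
#' with the spontaneous rate `p_spont` (so `p_spread >= p_spont` is
#' required). A null pair has independent node alterations: the right node
#' with marginal `p_source` and the left node with marginal `p_spont`.
#'
#' @param pair_id identifier matching the atlas pair table.
#' @param p_source probability of a source-node alteration per experiment.
#' @param p_spread conditional probability of contralateral spread.
#' @param p_spont spontaneous alteration probability of the non-source node.
#' @param source_side `"right"` or `"left"` (ignored for null pairs).
#' @param null_pair if `TRUE` the two nodes are independent.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(pair_id, p_source, p_spread, p_spont,
                         source_side = c("right", "left"),
                         null_pair = FALSE) {
  source_side <- match.arg(source_side)
  probs <- c(p_source, p_spread, p_spont)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!null_pair && p_spread < p_spont)
    stop("planted pairs require p_spread >= p_spont")
  structure(list(pair_id = pair_id, p_source = p_source,
                 p_spread = p_spread, p_spont = p_spont,
                 source_side = source_side, null_pair = null_pair),
            class = "ground_truth")
}

#' Simulation configuration
#'
#' Defaults define the reference synthetic conditions used throughout the
#' test fixtures: a 41 x 48 x 40 grid at 2 mm (x odd so the midline falls on
#' voxel centers), a shifted-Poisson foci count per altered node (mean 2,
#' minimum 1), and subject counts uniform on \[10, 30\] — typical VBM group
#' sizes.
#'
#' @param n_experiments number of experiments (>= 1).
#' @param n_pairs number of homotopic pairs to plant in the atlas.
#' @param grid_shape length-3 integer dims; the x dimension must be odd.
#' @param voxel_mm voxel size (default 2).
#' @param foci_per_node_mean mean foci count per altered node (shifted
#'   Poisson: 1 + Poisson(mean - 1); must be >= 1).
#' @param subjects_range integer range \[min, max\] for subject counts.
#' @param jitter if `TRUE`, foci get sub-voxel uniform jitter; by default
#'   they sit exactly at voxel centers so kernel peaks are analytic.
#' @param direction direction label written into the foci tables.
#' @param seed RNG seed; a fixed seed reproduces the outputs exactly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_experiments = 200, n_pairs = 50,
                       grid_shape = c(41, 48, 40), voxel_mm = 2,
                       foci_per_node_mean = 2,
                       subjects_range = c(10, 30),
                       jitter = FALSE,
                       direction = "decrease",
                       seed = 1L) {
  if (n_experiments < 1) stop("`n_experiments` must be >= 1")
  if (n_pairs < 0) stop("`n_pairs` must be >= 0")
  if (length(grid_shape) != 3L || grid_shape[1] %% 2L == 0L)
    stop("`grid_shape` must be three integers with an odd x dimension")
  if (foci_per_node_mean < 1) stop("`foci_per_node_mean` must be >= 1")
  if (length(subjects_range) != 2L || subjects_range[1] > subjects_range[2] ||
      subjects_range[1] < 1)
    stop("`subjects_range` must be [min, max] with min >= 1")
  structure(list(n_experiments = as.integer(n_experiments),
                 n_pairs = as.integer(n_pairs),
                 grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 foci_per_node_mean = foci_per_node_mean,
                 subjects_range = as.integer(subjects_range),
                 jitter = jitter, direction = direction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Node geometry of the synthetic atlas: rectangular blocks of bx x by x bz
# voxels separated by 2-voxel gaps, right-hemisphere blocks starting at
# |x| >= 12 mm so fixtures sit outside the midline-compensation zone.
synthetic_block <- c(2L, 2L, 3L)
synthetic_gap <- 2L
synthetic_min_x_mm <- 12

synthetic_cells <- function(dims, voxel_mm) {
  b <- synthetic_block; g <- synthetic_gap
  mid <- (dims[1] + 1L) %/% 2L
  i0 <- mid + ceiling(synthetic_min_x_mm / voxel_mm)
  ix <- seq(i0, dims[1] - b[1] + 1L, by = b[1] + g)
  jy <- seq(2L, dims[2] - b[2], by = b[2] + g)
  kz <- seq(2L, dims[3] - b[3], by = b[3] + g)
  if (length(ix) < 1L) stop("grid too small for synthetic nodes")
  expand.grid(i = ix, j = jy, k = kz, KEEP.OUT.ATTRS = FALSE)
}

#' Generate a synthetic symmetric atlas with network labels
#'
#' Plants `n_pairs` homotopic node pairs as mirror-image rectangular blocks
#' (12 voxels per side, comfortably above the 10-voxel minimum) in a
#' box-shaped "brain" mask covering the whole grid, plus a network label
#' volume partitioning the mask into `n_networks` z-slabs. Right nodes get
#' ids 1..n_pairs, their left partners n_pairs+1..2 n_pairs. Deterministic:
#' no randomness is involved.
#'
#' @param config a [sim_config()].
#' @param n_networks number of network slabs (default 5).
#' @return List: `atlas` (`symmetric_atlas`), `networks` (`volume_grid` of
#'   network ids), `mask` (logical `volume_grid`, all `TRUE`).
#' @export
generate_atlas <- function(config, n_networks = 5) {
  dims <- config$grid_shape
  cells <- synthetic_cells(dims, config$voxel_mm)
  if (config$n_pairs > nrow(cells))
    stop(sprintf("n_pairs = %d exceeds the %d available node slots",
                 config$n_pairs, nrow(cells)))
  lab <- array(0L, dims)
  b <- synthetic_block
  nx <- dims[1]
  for (p in seq_len(config$n_pairs)) {
    i <- cells$i[p]; j <- cells$j[p]; k <- cells$k[p]
    lab[i:(i + b[1] - 1L), j:(j + b[2] - 1L), k:(k + b[3] - 1L)] <- p
    im <- nx + 1L - (i:(i + b[1] - 1L))
    lab[im, j:(j + b[2] - 1L), k:(k + b[3] - 1L)] <- config$n_pairs + p
  }
  pairs <- data.frame(
    pair_id = if (config$n_pairs > 0) paste0("P", seq_len(config$n_pairs))
              else character(0),
    right_node_id = seq_len(config$n_pairs),
    left_node_id = config$n_pairs + seq_len(config$n_pairs),
    n_voxels_per_side = rep(prod(b), config$n_pairs),
    stringsAsFactors = FALSE
  )
  node_side <- c(
    stats::setNames(rep("right", config$n_pairs), seq_len(config$n_pairs)),
    stats::setNames(rep("left", config$n_pairs),
                    config$n_pairs + seq_len(config$n_pairs))
  )
  atlas <- symmetric_atlas(volume_grid(lab, config$voxel_mm), pairs, node_side)

  breaks <- round(seq(0, dims[3], length.out = n_networks + 1))
  net <- array(0L, dims)
  for (s in seq_len(n_networks))
    net[, , (breaks[s] + 1L):breaks[s + 1L]] <- s
  list(atlas = atlas,
       networks = volume_grid(net, config$voxel_mm),
       mask = volume_grid(array(TRUE, dims), config$voxel_mm))
}

#' Convenience ground-truth roster: planted and null pairs interleaved
#'
#' Odd-position pairs are planted (alternating right/left source sides) and
#' even-position pairs are null, matching the atlas pair ids `P1..Pn`.
#'
#' @param n_pairs total number of pairs.
#' @param p_source,p_spread,p_spont planted-pair probabilities (defaults
#'   0.6 / 0.9 / 0.1).
#' @param p_null marginal alteration probability of both null-pair nodes
#'   (default 0.3).
#' @return List of [ground_truth()] objects, length `n_pairs`.
#' @export
interleaved_truth <- function(n_pairs, p_source = 0.6, p_spread = 0.9,
                              p_spont = 0.1, p_null = 0.3) {
  lapply(seq_len(n_pairs), function(p) {
    if (p %% 2L == 1L) {
      ground_truth(paste0("P", p), p_source, p_spread, p_spont,
                   source_side = if ((p + 1L) %/% 2L %% 2L == 1L) "right" else "left",
                   null_pair = FALSE)
    } else {
      ground_truth(paste0("P", p), p_null, 0, p_null, null_pair = TRUE)
    }
  })
}

#' Generate a synthetic foci dataset with a known alteration oracle
#'
#' Per experiment and pair, node alteration states are drawn from the pair's
#' [ground_truth()]; each altered node receives a shifted-Poisson number of
#' foci placed uniformly at voxel centers within the node (sub-voxel jitter
#' optional). The exact binary states are returned as the oracle matrix, so
#' downstream recovery can be scored cell by cell.
#'
#' @param config a [sim_config()].
#' @param truth list of [ground_truth()], one per atlas pair (matched by
#'   `pair_id`).
#' @param atlas the `symmetric_atlas` from [generate_atlas()].
#' @return List: `foci` (Sleuth-style data.frame), `foci_list` (per
#'   experiment, including experiments with zero foci, directly consumable
#'   by [run_phac()]), `oracle` (N x 2 n_pairs binary matrix, columns named
#'   by node id), `truth`.
#' @export
generate_dataset <- function(config, truth, atlas) {
  if (length(truth) == 0L) stop("`truth` must not be empty")
  ids <- vapply(truth, function(t) t$pair_id, character(1))
  if (!setequal(ids, atlas$pairs$pair_id))
    stop("`truth` must cover exactly the atlas pairs")
  truth <- truth[match(atlas$pairs$pair_id, ids)]
  set.seed(config$seed)

  lab <- atlas$labels$data
  grid <- atlas$labels
  node_ids <- c(atlas$pairs$right_node_id, atlas$pairs$left_node_id)
  node_vox <- lapply(node_ids, function(id) {
    arrayInd(which(lab == id), dim(lab))
  })
  names(node_vox) <- node_ids

  N <- config$n_experiments
  P <- nrow(atlas$pairs)
  oracle <- matrix(0L, N, 2L * P, dimnames = list(NULL, node_ids))
  rows <- vector("list", N)
  foci_list <- vector("list", N)
  exp_ids <- sprintf("EXP%04d", seq_len(N))

  for (e in seq_len(N)) {
    a <- integer(P); b <- integer(P)   # a = right member, b = left member
    for (p in seq_len(P)) {
      tr <- truth[[p]]
      if (tr$null_pair) {
        a[p] <- stats::rbinom(1, 1, tr$p_source)
        b[p] <- stats::rbinom(1, 1, tr$p_spont)
      } else {
        src <- stats::rbinom(1, 1, tr$p_source)
        tgt <- stats::rbinom(1, 1, if (src == 1) tr$p_spread else tr$p_spont)
        if (tr$source_side == "right") { a[p] <- src; b[p] <- tgt }
        else                           { a[p] <- tgt; b[p] <- src }
      }
    }
    oracle[e, ] <- c(a, b)
    n_subj <- sample(seq(config$subjects_range[1], config$subjects_range[2]), 1)
    altered <- node_ids[c(a, b) == 1L]
    foci <- matrix(numeric(0), ncol = 3)
    for (id in altered) {
      vox <- node_vox[[as.character(id)]]
      nf <- 1L + stats::rpois(1, config$foci_per_node_mean - 1)
      pick <- vox[sample.int(nrow(vox), nf, replace = TRUE), , drop = FALSE]
      mm <- voxel_to_mm(grid, pick)
      if (config$jitter)
        mm <- mm + matrix(stats::runif(3 * nf, -config$voxel_mm / 2,
                                       config$voxel_mm / 2), ncol = 3)
      foci <- rbind(foci, mm)
    }
    foci_list[[e]] <- list(experiment_id = exp_ids[e], foci = foci,
                           n_subjects = n_subj, direction = config$direction,
                           diagnosis = "synthetic")
    if (nrow(foci) > 0)
      rows[[e]] <- data.frame(
        experiment_id = exp_ids[e], study_id = exp_ids[e],
        x_mm = foci[, 1], y_mm = foci[, 2], z_mm = foci[, 3],
        n_subjects = n_subj, direction = config$direction,
        diagnosis = "synthetic", space = "SYN",
        stringsAsFactors = FALSE)
  }
  names(foci_list) <- exp_ids
  foci_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(foci_df)) foci_df <- empty_foci_table()
  rownames(foci_df) <- NULL
  list(foci = foci_df, foci_list = foci_list, oracle = oracle, truth = truth)
}

empty_foci_table <- function() {
  data.frame(experiment_id = character(0), study_id = character(0),
             x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
             n_subjects = integer(0), direction = character(0),
             diagnosis = character(0), space = character(0),
             stringsAsFactors = FALSE)
}

#' Worst-case unilateral null scenario
#'
#' A stress fixture for false positives: every experiment's foci lie in one
#' hemisphere only — the first half of the experiments alter only the right
#' member of every pair, the second half only the left member, in the same
#' regions. The pair-wise joint alteration probability is therefore exactly
#' zero, and no homotopic edge should ever reach significance.
#'
#' @param config a [sim_config()].
#' @param atlas the `symmetric_atlas` from [generate_atlas()].
#' @return As [generate_dataset()]: `foci`, `foci_list`, `oracle`.
#' @export
unilateral_null_scenario <- function(config, atlas) {
  set.seed(config$seed)
  lab <- atlas$labels$data
  grid <- atlas$labels
  node_ids <- c(atlas$pairs$right_node_id, atlas$pairs$left_node_id)
  node_vox <- lapply(node_ids, function(id) arrayInd(which(lab == id), dim(lab)))
  names(node_vox) <- node_ids

  N <- config$n_experiments
  P <- nrow(atlas$pairs)
  oracle <- matrix(0L, N, 2L * P, dimnames = list(NULL, node_ids))
  rows <- vector("list", N)
  foci_list <- vector("list", N)
  exp_ids <- sprintf("UNI%04d", seq_len(N))
  for (e in seq_len(N)) {
    right_side <- e <= N / 2
    altered <- if (right_side) atlas$pairs$right_node_id
               else atlas$pairs$left_node_id
    oracle[e, as.character(altered)] <- 1L
    n_subj <- sample(seq(config$subjects_range[1], config$subjects_range[2]), 1)
    foci <- matrix(numeric(0), ncol = 3)
    for (id in altered) {
      vox <- node_vox[[as.character(id)]]
      nf <- 1L + stats::rpois(1, config$foci_per_node_mean - 1)
      pick <- vox[sample.int(nrow(vox), nf, replace = TRUE), , drop = FALSE]
      foci <- rbind(foci, voxel_to_mm(grid, pick))
    }
    foci_list[[e]] <- list(experiment_id = exp_ids[e], foci = foci,
                           n_subjects = n_subj, direction = config$direction,
                           diagnosis = "synthetic-unilateral")
    rows[[e]] <- data.frame(
      experiment_id = exp_ids[e], study_id = exp_ids[e],
      x_mm = foci[, 1], y_mm = foci[, 2], z_mm = foci[, 3],
      n_subjects = n_subj, direction = config$direction,
      diagnosis = "synthetic-unilateral", space = "SYN",
      stringsAsFactors = FALSE)
  }
  names(foci_list) <- exp_ids
  foci_df <- do.call(rbind, rows)
  rownames(foci_df) <- NULL
  list(foci = foci_df, foci_list = foci_list, oracle = oracle)
}
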
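# Shared fixtures: everything is generated in code at test time.

tiny_grid <- function(dims = c(11, 10, 8), fill = 0) {
  volume_grid(array(fill, dims))
}

full_mask <- function(grid) array(TRUE, dim(grid$data))

# Fast pipeline settings for fixtures: absolute MA cutoff 0.005 (the
# documented default for the synthetic geometry) and a reduced posterior
# sample count where full precision is not under test.
fast_config <- function(n_samples = 1000, seed = NULL, ...) {
  phac_config(threshold_method = "absolute", cutoff = 0.005,
              n_samples = n_samples, seed = seed, ...)
}

# A small synthetic world: atlas + networks + mask + dataset with oracle.
small_world <- function(n_experiments = 60, n_pairs = 10, seed = 5,
                        truth = interleaved_truth(n_pairs)) {
  cfg <- sim_config(n_experiments = n_experiments, n_pairs = n_pairs,
                    seed = seed)
  world <- generate_atlas(cfg)
  ds <- generate_dataset(cfg, truth, world$atlas)
  c(world, ds, list(sim = cfg))
}

# A hand-built two-node atlas whose right node has exactly n voxels.
handmade_atlas <- function(n_voxels = 10, dims = c(11, 10, 8)) {
  lab <- array(0L, dims)
  # right hemisphere: x > 0 means i > 6 on an 11-wide grid
  vox <- arrayInd(seq_len(prod(dims)), dims)
  right <- which(vox[, 1] >= 8 & vox[, 1] <= 9)[seq_len(n_voxels)]
  lab[vox[right, , drop = FALSE]] <- 1L
  grid <- volume_grid(lab)
  for (r in right) {
    ijk <- arrayInd(r, dims)
    lab[mirror_voxel(drop(ijk), grid)[1], ijk[2], ijk[3]] <- 2L
  }
  symmetric_atlas(
    volume_grid(lab),
    data.frame(pair_id = "P1", right_node_id = 1L, left_node_id = 2L,
               n_voxels_per_side = n_voxels),
    c("1" = "right", "2" = "left")
  )
}

# Binary volume with ones at the given voxel index rows.
binary_at <- function(grid, ijk) {
  arr <- array(0, dim(grid$data))
  arr[rbind(ijk)] <- 1
  volume_grid(arr, grid$voxel_mm, grid$origin)
}
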
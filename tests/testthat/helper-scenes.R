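# Small synthetic scenes shared across test files. The 256-px frame keeps
# unit tests fast; acceptance tests use the full default geometry.

small_spec <- function(seed = 42, ...) {
  args <- list(image_size = 256, n_neurons_small = 8, n_neurons_large = 4,
               n_immune = 2, n_tcells = 4, n_cd3_only = 2, n_satellite = 4,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_spec, args)
}

noiseless_spec <- function(seed = 42, ...) {
  small_spec(seed = seed, noise_sd = 0, rfx1_noise_sd = 0, ...)
}

# match truth rows (any class filter) to measured records by nearest centroid
match_truth <- function(truth, records) {
  vapply(seq_len(nrow(truth)), function(i) {
    which.min((records$centroid_row - truth$centroid_row[i])^2 +
                (records$centroid_col - truth$centroid_col[i])^2)
  }, integer(1))
}
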
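# Shared fixture builders. All fixtures are generated in code; training
# helpers run at reduced scale (32 px instances, narrow FC1) so the suite
# stays fast while exercising the full pipeline.

tiny_net_spec <- function(head = "ordinal_scalar", init_mode = "standard") {
  network_spec(input_side = 12L, conv1_filters = 3L, conv2_filters = 4L,
               fc1_units = 5L, head = head, init_mode = init_mode)
}

small_synth_cfg <- function(n_bags_per_class = 4L, seed = 42L, ...) {
  synth_config(n_bags_per_class = n_bags_per_class, seed = seed, ...)
}

# bag config matching the native 32x32 grid cells of the default image
small_bag_cfg <- function(...) {
  bag_build_config(patch_side = 32L, ...)
}

small_net_spec <- function(head = "ordinal_scalar") {
  network_spec(input_side = 32L, fc1_units = 64L, head = head)
}

make_small_bags <- function(n_per_class = 4L, seed = 42L, contrast = "default") {
  cfg <- synth_config(n_bags_per_class = n_per_class, seed = seed,
                      contrast = contrast)
  build_bags(generate_dataset(cfg), small_bag_cfg())
}

# a patch list with a chosen constant intensity per patch
constant_patches <- function(values, side = 8L) {
  lapply(values, function(v) {
    structure(list(pixels = matrix(v, side, side), grid_row = 0L, grid_col = 0L,
                   augmentation_tag = "none", hidden_label = NA_integer_),
              class = "oomil_instance")
  })
}
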
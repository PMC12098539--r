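# Shared, lazily built fixtures (generation is fast but not free; the smoke
# fit is reused by several files).

.fix <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fix$ds))
    .fix$ds <- generate_dataset(synthetic_config(
      n_images = 12L, tile_size = 32L, tumor_free_fraction = 0.25, seed = 7L))
  .fix$ds
}

tiny_model_config <- function() {
  model_config(base_width = 4L, n_levels = 3L, projection_channels = 8L,
               n_scales = 2L, dropout_p = 0.3)
}

tiny_contrastive_config <- function() {
  contrastive_config(D = 2L, beta = c(0.7, 0.3), C_out = 8L)
}

# a short semi-supervised run on 32x32 tiles, shared across tests
smoke_fit <- function() {
  if (is.null(.fix$fit)) {
    ds <- Filter(function(s) s$has_tumor, small_dataset())
    ids <- vapply(ds, function(s) s$id, character(1))
    split <- list(labeled = ids[1:2], unlabeled = ids[3:6], val = ids[7:8])
    .fix$fit <- fit_semiseg(ds, split,
                            mcfg = tiny_model_config(),
                            tcfg = train_config(epochs = 2L, T_mc = 2L, seed = 5L),
                            ccfg = tiny_contrastive_config(),
                            boundary = TRUE)
  }
  .fix$fit
}

random_mask <- function(h, w, p = 0.4) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}
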
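# Shared in-code fixtures: labeled ROI datasets from fluorescence
# phantoms and slab training groups from tomography phantoms. Everything
# is generated at test time from fixed seeds.

make_roi_dataset <- function(n_rois, seed0 = 100, n_cells = 16) {
  xs <- vector("list", 0)
  ys <- integer(0)
  s <- seed0
  params <- hough_params()
  while (length(ys) < n_rois) {
    f <- make_fluor_field(fluor_phantom_spec(n_cells = n_cells,
                                             phenotype_mix = 0.5, seed = s))
    rois <- extract_rois(list(f$green, f$red),
                         as.matrix(f$truth[, c("row", "col")]), params,
                         field_id = paste0("f", s))
    for (i in seq_along(rois)) {
      xs[[length(xs) + 1]] <- rois[[i]]$pixels
      ys <- c(ys, as.integer(f$truth$phenotype[i] == "partial"))
    }
    s <- s + 1
  }
  x <- array(0, c(64, 64, 2, n_rois))
  for (i in seq_len(n_rois)) x[, , , i] <- xs[[i]]
  list(x = x, y = ys[seq_len(n_rois)])
}

# Slab groups for segmentation training: one group per phantom tomogram,
# training slices chosen where the target annotation is most visible (as
# hand-annotated training slices would be).
make_slab_groups <- function(n_phantoms, seed0 = 500, size = 128, per = 5,
                             channel = "droplet") {
  n_cells <- if (size >= 96) 3 else if (size >= 64) 2 else 1
  groups <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    ph <- make_tomo_phantom(tomo_phantom_spec(
      volume_size = c(32, size, size), n_cells = n_cells,
      cell_axes_range = c(11, 13), vacuole_axes_range = c(6, 8),
      droplet_count_range = c(2, 2), droplet_radius_range = c(2.5, 3.5),
      seed = seed0 + i))
    vol <- quantile_normalize(ph$volume$voxels)
    mask <- ph$masks[[channel]]
    area <- apply(mask, 1, sum)
    zs <- order(-area)[seq_len(per)]
    groups[[i]] <- lapply(zs, function(z)
      list(x = assemble_slab(vol, z), y = mask[z, , ] * 1))
  }
  groups
}

# Memoized desk-scale channel models for the pipeline test.
.model_cache <- new.env(parent = emptyenv())
get_pipeline_models <- function() {
  if (!is.null(.model_cache$models)) return(.model_cache$models)
  models <- list()
  for (ch in c("cell", "vacuole", "droplet")) {
    gr <- make_slab_groups(4, seed0 = 700, size = 64, per = 4, channel = ch)
    net <- unet_build(in_ch = 5, base = 4, depth = 4, head_bias = -2,
                      seed = 11)
    models[[ch]] <- train_channel(gr, channel = ch, net = net, epochs = 60,
                                  lr = 1e-2, loss_weights = c(1, 0),
                                  augment = FALSE, seed = 12)
  }
  .model_cache$models <- models
  models
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
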
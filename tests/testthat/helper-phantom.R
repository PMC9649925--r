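# Shared fixtures: everything is generated in code at test time.

# a small cuboid mask inside a volume, for extractor tests
make_block_mask <- function(shape = c(16L, 16L, 10L), from = c(5L, 5L, 4L),
                            to = c(11L, 11L, 8L)) {
  m <- array(0L, shape)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1L
  m
}

random_volume <- function(shape = c(16L, 16L, 10L), seed = 1) {
  with_seed <- function(s, e) { set.seed(s); e }
  set.seed(seed)
  array(rnorm(prod(shape), 5, 1), shape)
}

# normalized DWI slices + masks from synthetic subjects, for U-Net tests
phantom_slices <- function(subjects) {
  out <- list()
  for (sp in subjects) {
    wl <- robust_window(sp$dwi)
    nv <- normalize_intensity(sp$dwi, wl$level, wl$width)
    zs <- which(apply(sp$mask, 3, sum) > 0)
    for (z in zs) out[[length(out) + 1L]] <- list(image = nv[, , z], mask = sp$mask[, , z])
    ez <- setdiff(seq_len(dim(sp$mask)[3]), zs)
    if (length(ez)) out[[length(out) + 1L]] <- list(image = nv[, , ez[1]],
                                                   mask = sp$mask[, , ez[1]])
  }
  out
}

draw_phantom_subject <- function(seed, volume_shape = c(24L, 24L, 16L)) {
  set.seed(seed)
  synthesize_lesion_pair(
    volume_shape = volume_shape,
    lesion_volume = runif(1, 60, 350),
    texture_scale = runif(1, 0.6, 2),
    texture_amplitude = runif(1, 0.05, 0.25),
    seed = seed
  )
}
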
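# Small, fast specs used across the suite. Artifact-free variants let the
# exactness tests compare against ground truth bit-for-bit.

tiny_spec <- function(seed = 1L, ...) {
  args <- list(shape = c(128L, 128L), pixel_size = 10, n_domains = 10L,
               seed = seed)
  do.call(monolayer_spec, utils::modifyList(args, list(...)))
}

clean_spec <- function(seed = 1L, ...) {
  tiny_spec(seed = seed, noise_sigma_h = 0, noise_sigma_v = 0,
            streak_amplitude = 0, tilt = c(0, 0), tip_blur_sigma = 0, ...)
}

# a two-level image with three 10x10 squares in a 100x100 field
squares_image <- function(extra_px = integer(0)) {
  v <- matrix(0, 100, 100)
  for (tl in list(c(10, 10), c(40, 60), c(80, 20)))
    v[tl[1]:(tl[1] + 9), tl[2]:(tl[2] + 9)] <- 1
  for (k in extra_px) v[k] <- 1
  scan_image(v, pixel_size = 1)
}
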
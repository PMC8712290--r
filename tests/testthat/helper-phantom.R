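# Shared fixtures, built in code at test time.

tiny_schedule <- function(n = 5) {
  end <- cumsum(rep(60, n))
  frame_schedule(end - 60, end)
}

# small random dynamic image + random binary mask on the same grid
random_dynamic <- function(shape = c(6, 6, 6), n_frames = 8, seed = 1) {
  set.seed(seed)
  img <- dynamic_image(array(rnorm(prod(shape) * n_frames, 10, 3),
                             c(shape, n_frames)),
                       tiny_schedule(n_frames))
  m <- array(0, shape)
  m[sample(prod(shape), max(4, prod(shape) %/% 3))] <- 1
  list(img = img, mask = mask_image(m, kind = "binary"))
}

# the default small phantom used by most pipeline tests
fast_spec <- function(noise_level = 0, seed = 42L, mixing = "none") {
  phantom_spec(noise_level = noise_level, seed = seed, mixing = mixing)
}

cached_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(noise_level = 0, seed = 42L, n = 12L, jitter = 0.05) {
    key <- paste(noise_level, seed, n, jitter, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_cohort(n, fast_spec(noise_level, seed),
                                      jitter_sdlog = jitter)
    cache[[key]]
  }
})
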
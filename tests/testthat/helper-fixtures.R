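# Shared fixtures built in code. Small phantoms are cached per option set
# so several test files can reuse them without regenerating.

.phantom_cache <- new.env(parent = emptyenv())

small_spec <- function(noise_sigma = 2, seed = 1L, breakpoint = TRUE) {
  phantom_spec(height = 64, width = 64, n_frames = 48, fps = 6,
               tube_radius_px = 3, front_speed = 20,
               noise_sigma = noise_sigma, seed = seed,
               breakpoint = if (breakpoint)
                 list(position_frac = 0.6, leak_radius_px = 6,
                      leak_fill_rate = 1.5, leak_clear_rate = 0.05,
                      spread_speed = 4) else NULL)
}

cached_phantom <- function(noise_sigma = 2, seed = 1L, breakpoint = TRUE) {
  key <- paste(noise_sigma, seed, breakpoint, sep = "|")
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(
      small_spec(noise_sigma, seed, breakpoint))
  .phantom_cache[[key]]
}

# noiseless single-pixel series drawn from the bolus model
model_series <- function(a0, a1, a2, a3, t0, fps = 6, n = 60) {
  bolus_model((0:(n - 1)) / fps, a0, a1, a2, a3, t0)
}
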
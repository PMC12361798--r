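# Shared synthetic fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_mvp_case <- function(zone = "A2", seed = 7, size = 96) {
  cached(paste("mvp", zone, seed, size, sep = "_"),
         generate_case(echo_phantom_config(
           image_size = c(size, size), n_cycles = 2, frames_per_cycle = 10,
           systole_fraction = 0.5, mvp_case = TRUE, prolapse_amplitude = 10,
           prolapse_zone = zone, seed = seed)))
}

tiny_control_case <- function(seed = 3, size = 96) {
  cached(paste("ctl", seed, size, sep = "_"),
         generate_case(echo_phantom_config(
           image_size = c(size, size), n_cycles = 3, frames_per_cycle = 10,
           seed = seed)))
}

small_dataset <- function() {
  cached("small_dataset",
         generate_dataset(6, 6, config_ranges = list(
           image_size = c(96, 96), frames_per_cycle = 8:12), seed = 42))
}
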
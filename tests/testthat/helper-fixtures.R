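# Desk-scale phantom used throughout the unit tests: big enough to carry a
# 96-column overlap plus AP/SI search windows, small enough to regenerate in
# milliseconds.

small_spec <- function(seed = 1L, ...) {
  phantom_spec(n_slices = 8, n_rows = 64, n_cols = 160, seed = seed, ...)
}

small_phantom <- function(seed = 1L, ...) generate_phantom(small_spec(seed, ...))

# config matched to the small phantom's spine insert
small_config <- function(...) stitch_config(...)
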
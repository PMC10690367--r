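# Shared fixtures: the standard acquisition grid (60 frames at 1.87 s,
# TE = 40 ms), a reference arterial bolus, and small phantom builders.

std_time_grid <- function() seq(0, by = 1.87, length.out = 60)

std_aif <- function(tg = std_time_grid()) {
  make_aif(gamma_bolus_params(amplitude = 12, t1 = 8 * 1.87, sigma1 = 2,
                              a1 = 3), tg)
}

small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(12L, 12L, 5L), ...)
}

# brute-force horizontal run enumeration for a 2D level matrix (GLRLM oracle)
brute_runs_horizontal <- function(img) {
  runs <- list()
  for (r in seq_len(nrow(img))) {
    row <- img[r, ]
    j <- 1L
    while (j <= length(row)) {
      len <- 1L
      while (j + len <= length(row) && row[j + len] == row[j]) len <- len + 1L
      runs[[length(runs) + 1L]] <- c(level = row[j], length = len)
      j <- j + len
    }
  }
  do.call(rbind, runs)
}
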
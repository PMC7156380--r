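# Shared fixtures, built once per test run and memoized.

.px_cache <- new.env(parent = emptyenv())

# Bundled global hypsometric table.
px_hyps_table <- function() {
  read.csv(system.file("extdata", "global_hypsometry.csv",
                       package = "paleoredox"), comment.char = "#")
}

# Fitted depth-area curve on the bundled table.
px_curve <- function() {
  if (is.null(.px_cache$curve)) .px_cache$curve <- fit_depth_area(px_hyps_table())
  .px_cache$curve
}

# Full-protocol ensemble (31 scenarios x 1000 runs, analytic path).
px_big_ensemble <- function() {
  if (is.null(.px_cache$ens)) {
    .px_cache$ens <- run_ensemble(px_curve(), master_seed = 1L)
  }
  .px_cache$ens
}

# A strictly linear depth-area table: z = 6000 * f.
px_linear_table <- function(n = 25) {
  f <- seq(0, 1, length.out = n)
  data.frame(depth_m = 6000 * f, cum_area_fraction = f)
}

# A mid-range parameter draw: every parameter at the center of its prior.
px_mid_draw <- function(ranges = mb_param_ranges(), f_red = 0.2) {
  draw <- lapply(ranges, function(r) mean(r))
  draw$f_red <- f_red
  as.data.frame(draw)
}
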
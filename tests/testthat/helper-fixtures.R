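# Shared fixtures, memoised so expensive phantoms are generated once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

tofts_phantom <- function(noise = 0, seed = 1L) {
  cached(sprintf("tofts_%g_%d", noise, seed),
         generate_phantom(default_tofts_spec(noise, seed)))
}

ext_phantom <- function(noise = 0, seed = 1L) {
  cached(sprintf("ext_%g_%d", noise, seed),
         generate_phantom(default_ext_tofts_spec(noise, seed)))
}

# fit every 10x10 patch mean curve of a phantom; returns the parameter_map
patch_map <- function(ph, model) {
  cached(sprintf("map_%s_%s", model, ph$series$provenance), {
    roi <- ph$tissue_roi
    roi$bin_factor <- 10L
    fit_roi(ph$series, roi, model, relax = ph$relax, aif = ph$spec$aif)
  })
}

# ground-truth plane subsampled at patch resolution (one value per patch)
truth_patches <- function(ph, param) {
  m <- ph$truth[[param]]
  m[seq(1, nrow(m), 10), seq(1, ncol(m), 10)]
}

# small uniform series for io / binning tests: X x Y constant gradient
tiny_series <- function(nx = 8, ny = 6, nt = 12, injection_frame = 4L) {
  arr <- array(0, dim = c(nx, ny, 1, nt))
  base <- outer(seq_len(nx), seq_len(ny), function(x, y) 100 + 10 * x + y)
  for (tt in seq_len(nt))
    arr[, , 1, tt] <- base * (1 + 0.05 * max(0, tt - injection_frame))
  dce_series(arr, acquisition_params("spin_echo", TR = 200,
                                     frame_interval = 2,
                                     injection_frame = injection_frame))
}
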
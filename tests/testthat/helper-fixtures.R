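# shared fixtures: grey-matter truth, clean decays, small phantoms

gm_params <- function() {
  diffusion_params(f = 0.13, d_star = 8.43e-3, d_app = 1.12e-3, k_app = 0.83)
}

clean_gm_decay <- function(scheme = trace_scheme()) {
  signal_decay(scheme, predict_signal("full", gm_params(), scheme))
}

# two-class phantom on a small grid, used by volume-level tests
two_block_config <- function(snr = 60, ...) {
  truth <- tissue_truth_table()[c(1, 4), ]  # GM and oedema
  layout <- list(
    "GM"     = list(x = 7:12, y = 7:12, z = 1:2),
    "Oedema" = list(x = 15:20, y = 7:12, z = 1:2)
  )
  phantom_config(dim = c(26, 18, 2), truth = truth, layout = layout,
                 snr = snr, ...)
}

# random interior truths for identifiability checks; k_app is drawn below the
# kurtosis validity constraint 3 / (d_app * max_b) so the noiseless signal
# decays over the whole scheme (the model is unphysical beyond that vertex)
random_interior_truths <- function(n, margin = 0.05, max_b = 3000) {
  b <- param_bounds()
  lo <- b$lower + margin * (b$upper - b$lower)
  hi <- b$upper - margin * (b$upper - b$lower)
  d_app <- stats::runif(n, lo[["d_app"]], hi[["d_app"]])
  k_hi <- pmin(hi[["k_app"]], 0.95 * 3 / (d_app * max_b))
  tibble::tibble(
    tissue = paste0("draw", seq_len(n)),
    f = stats::runif(n, lo[["f"]], hi[["f"]]),
    d_star = stats::runif(n, lo[["d_star"]], hi[["d_star"]]),
    d_app = d_app,
    k_app = lo[["k_app"]] + stats::runif(n) * (k_hi - lo[["k_app"]])
  )
}
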
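# Shared fixtures built in code.

# Small, fast field used by several suites (memoised per test file run).
small_field <- local({
  cache <- new.env()
  function(n_cells = 15, contact_pairs = 0, seed = 11, size = 192,
           illumination_gradient = 0.15, noise_sd = 0.02) {
    key <- paste(n_cells, contact_pairs, seed, size, illumination_gradient, noise_sd)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_field(field_spec(
        image_size = c(size, size), n_cells = n_cells,
        contact_pairs = contact_pairs, seed = seed,
        illumination_gradient = illumination_gradient, noise_sd = noise_sd
      ))
    }
    cache[[key]]
  }
})

# Filled disk mask centred in an n x n frame.
disk_mask <- function(r, n = 2 * r + 11) {
  cx <- (n + 1) / 2
  d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, `+`)
  matrix(as.integer(d2 <= r^2), n, n)
}

# Synthetic labelled cell records with class-dependent cytoplasm areas.
# `gap` controls separation: large gap -> separable, 0 -> identical classes.
synthetic_records <- function(n = 100, gap = 200, sd = 60, seed = 1) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  tibble::tibble(
    area_cytoplasm = c(stats::rnorm(n / 2, 400 + gap, sd),
                       stats::rnorm(n / 2, 400, sd)),
    form_factor = stats::runif(n, 0.3, 1),
    eccentricity = stats::runif(n),
    solidity = stats::runif(n, 0.6, 1),
    class = rep(c("spread", "unspread"), each = n / 2)
  )
}

# Raw well stack with known artifacts and spiked compounds (9 plates).
spiked_stack <- function(seed = 1,
                         compound_effects = c(C0005 = 0.6, C0030 = 1.5),
                         noise = 40) {
  generate_plate_stack(plate_stack_spec(
    compound_effects = compound_effects,
    row_effects = c(B = 60, C = 0, D = -60, E = 40, F = 0, G = -40),
    column_effects = stats::setNames(seq(-50, 40, by = 10), 2:11),
    stack_position_effects = seq(-80, 80, length.out = 9),
    well_noise_sd = noise,
    seed = seed
  ))
}
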
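test_that("empty field spec yields empty images and truth", {
  f <- generate_field(field_spec(n_cells = 0, seed = 1, image_size = c(64, 64)))
  expect_equal(max(f$truth$cell_mask), 0)
  expect_equal(max(f$truth$nucleus_mask), 0)
  expect_equal(nrow(f$truth$class), 0)
  expect_equal(nrow(f$truth$contact_graph), 0)
  expect_equal(dim(f$nuclear), c(64, 64))
})

test_that("generated fields are reproducible and self-consistent", {
  f1 <- small_field(n_cells = 10, contact_pairs = 2, seed = 4)
  f2 <- generate_field(field_spec(image_size = c(192, 192), n_cells = 10,
                                  contact_pairs = 2, seed = 4))
  expect_identical(f1$nuclear, f2$nuclear)
  expect_identical(f1$truth$cell_mask, f2$truth$cell_mask)

  truth <- f1$truth
  expect_equal(nrow(truth$contact_graph), 2)
  expect_true(all(truth$contact_graph$a < truth$contact_graph$b))
  # every nucleus lies fully inside its own cell
  nl <- truth$nucleus_mask
  expect_true(all(truth$cell_mask[nl > 0] == nl[nl > 0]))
  # every cell has exactly one nucleus
  expect_setequal(unique(nl[nl > 0]), seq_len(10))
  # nucleus strictly smaller than its cell
  na <- tabulate(nl[nl > 0], nbins = 10)
  ca <- tabulate(truth$cell_mask[truth$cell_mask > 0], nbins = 10)
  expect_true(all(na < ca))
})

test_that("truth contact graph matches mask adjacency exactly", {
  f <- small_field(n_cells = 12, contact_pairs = 3, seed = 9)
  stats <- measure_neighbors(f$truth$cell_mask, distance = 1)
  got <- contact_graph(stats)
  expect_equal(
    got[order(got$a, got$b), ],
    f$truth$contact_graph[order(f$truth$contact_graph$a, f$truth$contact_graph$b), ],
    ignore_attr = TRUE
  )
})

test_that("spread cells are larger than unspread cells in truth", {
  f <- generate_field(field_spec(image_size = c(448, 448), n_cells = 50,
                                 fraction_spread = 0.5, seed = 7))
  areas <- tabulate(f$truth$cell_mask[f$truth$cell_mask > 0], nbins = 50)
  cls <- f$truth$class$class
  expect_gt(mean(areas[cls == "spread"]), mean(areas[cls == "unspread"]))
})

test_that("field spec validation rejects impossible requests", {
  expect_error(field_spec(n_cells = 4, contact_pairs = 3), "contact_pairs")
  expect_error(field_spec(spread_area_range = c(-5, 10)))
  expect_error(
    generate_field(field_spec(image_size = c(64, 64), n_cells = 60, seed = 1)),
    "placement|larger"
  )
})

test_that("noiseless zero-artifact plates compose exactly from spec parameters", {
  spec <- plate_stack_spec(well_noise_sd = 0, substrate_effect = 0.5,
                           positive_control = FALSE, seed = 2)
  st <- generate_plate_stack(spec)
  ctrl <- st$wells[st$wells$substrate == "control", ]
  coat <- st$wells[st$wells$substrate == "coated", ]
  expect_true(all(ctrl$raw == spec$baseline_area))
  expect_true(all(coat$raw == 0.5 * spec$baseline_area))
})

test_that("injected additive row offsets reappear exactly in row means", {
  spec <- plate_stack_spec(
    well_noise_sd = 0, substrate_effect = 1,
    row_effects = c(B = 10, C = 0, D = -10, E = 10, F = 0, G = -10),
    positive_control = FALSE, seed = 3
  )
  st <- generate_plate_stack(spec)
  rm <- tapply(st$wells$raw, st$wells$row, mean)
  expect_equal(unname(rm["B"] - rm["C"]), 10)
  expect_equal(unname(rm["D"] - rm["C"]), -10)
})

test_that("plate stack generation is deterministic and validates effect maps", {
  s1 <- generate_plate_stack(plate_stack_spec(seed = 5))
  s2 <- generate_plate_stack(plate_stack_spec(seed = 5))
  expect_identical(s1$wells, s2$wells)
  expect_error(
    generate_plate_stack(plate_stack_spec(compound_effects = c(NOPE = 0.5), seed = 1)),
    "absent from layouts"
  )
})
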
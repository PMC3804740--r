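test_that("nucleus detection handles blank and single-disk images", {
  expect_equal(max(detect_nuclei(matrix(0, 64, 64))), 0)
  img <- disk_mask(8, 64) * 0.9
  lbl <- detect_nuclei(img)
  expect_equal(max(lbl), 1)
  # disk touching the border is excluded
  img2 <- matrix(0, 64, 64)
  img2[1:10, 30:40] <- 0.9
  expect_equal(max(detect_nuclei(img2)), 0)
  # too-small specks are excluded (below min diameter 8)
  img3 <- matrix(0, 64, 64)
  img3[30:31, 30:31] <- 0.9
  expect_equal(max(detect_nuclei(img3)), 0)
})

test_that("labelling is 8-connected and holes are filled", {
  img <- matrix(0, 40, 40)
  img[10:20, 10:20] <- 0.9
  img[21, 21] <- 0.9; img[22:26, 22:26] <- 0.9  # diagonal bridge
  lbl <- detect_nuclei(img, seg_params(nucleus_diameter_range = c(3, 40)))
  expect_equal(max(lbl), 1)
  imgh <- matrix(0, 40, 40)
  imgh[10:24, 10:24] <- 0.9
  imgh[16:18, 16:18] <- 0   # hole
  lblh <- detect_nuclei(imgh)
  expect_equal(sum(lblh > 0), 15 * 15)
})

test_that("nucleus counts and areas match ground truth on synthetic fields", {
  f <- small_field(n_cells = 15, seed = 21, size = 256)
  nuclei <- detect_nuclei(rescale_minmax(f$nuclear))
  expect_equal(max(nuclei), 15)
  got <- sort(tabulate(nuclei[nuclei > 0], nbins = 15))
  want <- sort(tabulate(f$truth$nucleus_mask[f$truth$nucleus_mask > 0], nbins = 15))
  expect_true(all(abs(got - want) / want <= 0.10))
})

test_that("propagation assigns every foreground pixel to exactly one seed", {
  img <- matrix(0.05, 60, 60)
  img[20:40, 10:50] <- 0.6          # one merged blob
  seeds <- matrix(0L, 60, 60)
  seeds[28:32, 18:22] <- 1L
  seeds[28:32, 38:42] <- 2L
  out <- propagate_cells(img, seeds)
  blob <- img >= out$threshold
  expect_true(all(out$cells[blob] > 0))                # partition: nothing unassigned
  expect_setequal(unique(out$cells[out$cells > 0]), 1:2)
  expect_true(all(out$cells[seeds == 1L] == 1L))
  expect_true(all(out$cells[seeds == 2L] == 2L))
  # empty seed map -> empty cells
  empty <- propagate_cells(img, matrix(0L, 60, 60))
  expect_equal(max(empty$cells), 0)
})

test_that("large lambda converges to the nearest-seed partition", {
  img <- matrix(0.05, 50, 50)
  img[5:45, 5:45] <- 0.5            # uniform foreground
  seeds <- matrix(0L, 50, 50)
  seeds[15, 15] <- 1L; seeds[35, 38] <- 2L
  out <- propagate_cells(img, seeds, seg_params(lambda = 1e3, border_exclusion = FALSE))
  fg <- which(img >= 0.5 & out$cells > 0, arr.ind = TRUE)
  d1 <- sqrt((fg[, 1] - 15)^2 + (fg[, 2] - 15)^2)
  d2 <- sqrt((fg[, 1] - 35)^2 + (fg[, 2] - 38)^2)
  assigned <- out$cells[fg]
  nearest <- ifelse(d1 < d2, 1L, 2L)
  margin <- abs(d1 - d2)
  # away from the equidistant ridge the assignment is exactly nearest-seed
  expect_true(all(assigned[margin > 1.5] == nearest[margin > 1.5]))
})

test_that("border cells are removed with their nuclei and labels stay matched", {
  f <- small_field(n_cells = 12, contact_pairs = 2, seed = 3)
  nuclei <- detect_nuclei(rescale_minmax(f$nuclear))
  out <- propagate_cells(f$actin, nuclei)
  expect_setequal(unique(out$cells[out$cells > 0]), unique(out$nuclei[out$nuclei > 0]))
  # every nucleus inside its own cell
  sel <- out$nuclei > 0
  expect_true(all(out$cells[sel] == out$nuclei[sel]))
  expect_equal(length(spreadscreen:::border_labels(out$cells)), 0)
})

test_that("tertiary subtraction is the exact area identity", {
  f <- small_field(n_cells = 12, seed = 13)
  nuclei <- detect_nuclei(rescale_minmax(f$nuclear))
  out <- propagate_cells(f$actin, nuclei)
  cyto <- tertiary_cytoplasm(out$cells, out$nuclei)
  n <- max(out$cells)
  expect_equal(
    tabulate(cyto[cyto > 0], nbins = n),
    tabulate(out$cells[out$cells > 0], nbins = n) -
      tabulate(out$nuclei[out$nuclei > 0], nbins = n)
  )
  # mismatched tiers are rejected
  expect_error(tertiary_cytoplasm(out$cells, out$nuclei * 0L), "mismatch")
})

test_that("full segmentation recovers truth counts and areas on clean fields", {
  f <- small_field(n_cells = 18, contact_pairs = 0, seed = 31, size = 256)
  rec <- segment_field(f$nuclear, f$actin)
  expect_equal(nrow(rec), 18)
  truth_areas <- sort(tabulate(f$truth$cell_mask[f$truth$cell_mask > 0], nbins = 18))
  expect_true(all(abs(sort(rec$area_cell) - truth_areas) / truth_areas <= 0.10))
  expect_true(all(rec$area_cell == rec$area_nucleus + rec$area_cytoplasm))
})
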
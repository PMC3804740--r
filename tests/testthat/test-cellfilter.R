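test_that("single object has no neighbours and zero contact", {
  m <- matrix(0L, 30, 30); m[10:20, 10:20] <- 1L
  st <- measure_neighbors(m)
  expect_equal(st$neighbor_count, 0L)
  expect_equal(st$percent_touching, 0)
  expect_equal(nrow(contact_graph(st)), 0)
})

test_that("abutting rectangles match the hand geometry and the brute-force oracle", {
  # two 12x10 rectangles sharing a 10-pixel edge: 40 boundary pixels each,
  # 10 of them in contact -> 25%
  m <- matrix(0L, 40, 40)
  m[11:20, 5:16] <- 1L    # 10 rows x 12 cols
  m[11:20, 17:28] <- 2L
  st <- measure_neighbors(m, distance = 1)
  expect_equal(st$neighbor_count, c(1L, 1L))
  expect_equal(st$n_boundary, c(40L, 40L))
  expect_equal(st$percent_touching, c(25, 25))
  orc <- neighbors_oracle(m, 1)
  expect_equal(st$neighbor_count, orc$neighbor_count)
  expect_equal(st$percent_touching, orc$percent_touching)
})

test_that("neighbour relation is symmetric and matches the oracle on random blobs", {
  set.seed(5)
  m <- matrix(0L, 48, 48)
  m[5:14, 5:14] <- 1L
  m[15:22, 10:18] <- 2L    # touches 1
  m[30:40, 30:38] <- 3L    # isolated
  m[5:10, 40:46] <- 4L
  for (d in c(1, 2)) {
    st <- measure_neighbors(m, distance = d)
    orc <- neighbors_oracle(m, d)
    expect_equal(st$neighbor_count, orc$neighbor_count)
    expect_equal(st$percent_touching, orc$percent_touching, tolerance = 1e-12)
    cg <- contact_graph(st)
    expect_true(all(st$percent_touching >= 0 & st$percent_touching <= 100))
    # symmetry: counts derivable from the undirected pair list
    expect_equal(st$neighbor_count,
                 tabulate(c(cg$a, cg$b), nbins = max(m)))
  }
})

test_that("separated-cell filter keeps exactly the contact-free cells", {
  f <- small_field(n_cells = 14, contact_pairs = 3, seed = 8, size = 256)
  cells <- f$truth$cell_mask
  nuclei <- f$truth$nucleus_mask
  cyto <- cells; cyto[nuclei > 0] <- 0L
  st <- measure_neighbors(cells, 1)
  filt <- filter_separated(cells, nuclei, cyto, st)
  expect_equal(max(filt$cells), 14 - 2 * 3)
  expect_setequal(unique(filt$cells[filt$cells > 0]), seq_len(8))
  # tiers filtered consistently
  expect_setequal(unique(filt$nuclei[filt$nuclei > 0]), seq_len(8))
  sel <- filt$nuclei > 0
  expect_true(all(filt$cells[sel] == filt$nuclei[sel]))
  expect_equal(sum(filt$report$retained), 8)
})

test_that("filtering is monotone in the cutoffs and identity at infinity", {
  f <- small_field(n_cells = 12, contact_pairs = 2, seed = 19)
  cells <- f$truth$cell_mask
  st <- measure_neighbors(cells, 1)
  strict <- filter_separated(cells, stats = st)
  loose <- filter_separated(cells, stats = st, max_neighbors = 1, max_percent = 100)
  all_in <- filter_separated(cells, stats = st, max_neighbors = Inf, max_percent = Inf)
  kept <- function(x) x$report$label[x$report$retained]
  expect_true(all(kept(strict) %in% kept(loose)))
  expect_equal(kept(all_in), 1:12)
  expect_identical(all_in$cells, cells)
})

test_that("marker colocalization retains exactly the marker-positive cells", {
  f <- generate_field(field_spec(image_size = c(256, 256), n_cells = 12,
                                 marker_fraction = 0.5, seed = 6))
  out <- filter_marker_positive(f$truth$cell_mask, f$marker, marker_threshold = 0.5)
  expect_equal(out$retained, f$truth$marker_positive)
  # no marker signal -> nothing retained
  none <- filter_marker_positive(f$truth$cell_mask, matrix(0, 256, 256), 0.5)
  expect_equal(max(none$cells), 0)
  # marker everywhere above threshold in every cell -> identity on labels
  blanket <- matrix(0, 256, 256)
  blanket[f$truth$nucleus_mask > 0] <- 1
  all_pos <- filter_marker_positive(f$truth$cell_mask, blanket, 0.5)
  expect_equal(all_pos$retained, 1:12)
})
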
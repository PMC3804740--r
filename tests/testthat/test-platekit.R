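test_that("library manifest reproduces the screen geometry", {
  man <- build_library_manifest(13, 80)
  expect_equal(nrow(man$stock_plates), 1040)
  expect_equal(anyDuplicated(man$stock_plates$compound), 0)
  # every compound appears exactly once across the mother rows
  comp <- man$mother_rows$content[!man$mother_rows$content %in% c("DMSO", "POSCTRL")]
  expect_equal(sort(comp), sort(man$stock_plates$compound))
  # 3 DMSO wells per mother row (plus the padded slot on short rows)
  per_row <- dplyr::count(
    dplyr::filter(man$mother_rows, .data$content == "DMSO"),
    .data$assay_plate
  )
  expect_true(all(per_row$n >= 3))
  expect_equal(length(unique(man$mother_rows$assay_plate)), 13 * 9)
})

test_that("minimal manifest and infeasible inputs behave", {
  one <- build_library_manifest(1, 9, positive_control = FALSE)
  expect_equal(nrow(one$stock_plates), 9)
  first_plate <- one$mother_rows[one$mother_rows$assay_plate == "S01_P1", ]
  expect_equal(sum(!first_plate$content %in% c("DMSO", "POSCTRL")), 9)
  expect_error(build_library_manifest(1, 82), "grouped|at most")
})

test_that("assay layout satisfies every plate invariant", {
  lay <- build_assay_layout(sprintf("C%02d", 1:9))
  expect_equal(nrow(lay), 96)
  expect_equal(sum(lay$role == "empty"), 36)
  expect_true(all(lay$role[lay$row %in% c("A", "H") | lay$col %in% c(1, 12)] == "empty"))
  expect_equal(sum(lay$role == "compound"), 54)
  expect_equal(sum(lay$role == "dmso_control"), 6)
  expect_equal(lay$role[lay$well == "A01"], "empty")
  expect_equal(unique(lay$substrate[lay$row == "E"]), "coated")
  expect_equal(unique(lay$substrate[lay$row == "C"]), "control")
  # each compound occupies one column across all six inner rows
  for (cc in unique(stats::na.omit(lay$compound))) {
    expect_equal(length(unique(lay$col[!is.na(lay$compound) & lay$compound == cc])), 1)
    expect_equal(sum(lay$compound == cc, na.rm = TRUE), 6)
  }
})

test_that("positive-control column is pinned and unique", {
  lay <- build_assay_layout(c(sprintf("C%02d", 1:8), "POSCTRL"),
                            positive_control_column = 10)
  expect_equal(unique(lay$col[lay$role == "positive_control"]), 10)
  expect_equal(sum(lay$role == "positive_control"), 6)
  expect_equal(sum(lay$role == "compound"), 48)
  expect_equal(sum(lay$role == "dmso_control"), 6)
  expect_error(build_assay_layout(sprintf("C%02d", 1:5)), "9 treatment")
})

test_that("site layout is annular, deterministic and has the default count", {
  s <- site_layout()
  expect_equal(nrow(s), 24)
  r <- sqrt(s$x^2 + s$y^2)
  expect_true(all(r > 0.15 & r < 0.40))
  expect_identical(s, site_layout())
  one <- site_layout(1)
  expect_equal(nrow(one), 1)
  expect_gt(sqrt(one$x^2 + one$y^2), 0)   # off-centre
  expect_error(site_layout(0), ">= 1")
  for (n in c(5, 12, 24, 36)) expect_equal(nrow(site_layout(n)), n)
})

test_that("filename tagging round-trips layout metadata", {
  lay <- build_assay_layout(c(sprintf("C%02d", 1:8), "POSCTRL"),
                            plate_id = "P3", stack_position = 3,
                            positive_control_column = 10)
  tagged <- tag_filename("B02_s01_w1.tif", lay)
  meta <- parse_tags(tagged)
  expect_equal(meta$plate_id, "P3")
  expect_equal(meta$well, "B02")
  expect_equal(meta$channel, "nuclear")
  expect_equal(meta$substrate, "control")
  expect_equal(meta$compound, "C01")
  expect_equal(parse_tags(tag_filename("E10_s24_w2.tif", lay))$role, "positive_control")
  expect_equal(parse_tags(tag_filename("C05_s03_w3.tif", lay))$channel, "marker")
  expect_error(tag_filename("oops.tif", lay), "unparseable")
  # bulk round-trip across all inner wells and sites
  wells <- lay$well[lay$role != "empty"]
  for (w in wells[seq(1, length(wells), by = 7)]) {
    raw <- sprintf("%s_s%02d_w1.tif", w, 5)
    expect_equal(parse_tags(tag_filename(raw, lay))$well, w)
  }
})

test_that("well aggregation equals brute-force recomputation", {
  f <- small_field(n_cells = 14, contact_pairs = 2, seed = 23, size = 256)
  rec <- segment_field(f$nuclear, f$actin, plate_id = "P1", well = "B03", site = 1)
  agg <- aggregate_well(rec)
  expect_equal(agg$n_separated, nrow(rec))
  expect_equal(agg$mean_area_cytoplasm, sum(rec$area_cytoplasm) / nrow(rec))
  simple <- tibble::tibble(
    plate_id = "P", well = "B02",
    area_cytoplasm = c(100, 200, 300), separated = TRUE, class = "unlabeled"
  )
  expect_equal(aggregate_well(simple)$mean_area_cytoplasm, 200)
  none <- dplyr::mutate(simple, separated = FALSE)
  out <- aggregate_well(none)
  expect_true(out$flagged)
  expect_true(is.na(out$mean_area_cytoplasm))
  expect_error(aggregate_well(dplyr::mutate(simple, well = c("B02", "B02", "B03"))),
               "more than one well")
})

test_that("area binning sums to 100% with a monotone cumulative curve", {
  single <- tibble::tibble(area_cytoplasm = 500)
  b1 <- bin_areas(single)
  expect_equal(sum(b1$pct), 100)
  expect_equal(max(b1$pct), 100)
  set.seed(12)
  unif <- tibble::tibble(area_cytoplasm = runif(10000))
  b <- bin_areas(unif, 0.10)
  expect_equal(nrow(b), 10)
  expect_true(all(abs(b$pct - 10) < 2))
  expect_equal(b$cum_pct[10], 100)
  expect_true(all(diff(b$cum_pct) >= 0))
})
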
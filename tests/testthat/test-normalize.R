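test_that("POC normalization: controls average 100, scale invariance, coated effect", {
  st <- generate_plate_stack(plate_stack_spec(well_noise_sd = 10, seed = 4))
  p <- poc_normalize(st$wells)
  ctrl <- p[p$role == "dmso_control" & p$substrate == "control", ]
  means <- tapply(ctrl$poc, ctrl$plate_id, mean)
  expect_equal(as.numeric(means), rep(100, 9), tolerance = 1e-10)
  doubled <- st$wells
  doubled$raw <- doubled$raw * 2
  expect_equal(poc_normalize(doubled)$poc, p$poc, tolerance = 1e-12)

  noiseless <- generate_plate_stack(plate_stack_spec(well_noise_sd = 0,
                                                     substrate_effect = 0.5, seed = 1))
  pn <- poc_normalize(noiseless$wells)
  expect_equal(unique(pn$poc[pn$role == "dmso_control" & pn$substrate == "coated"]), 50)
})

test_that("plates without valid controls are flagged, not silently skipped", {
  st <- generate_plate_stack(plate_stack_spec(seed = 2))
  broken <- st$wells
  broken$raw[broken$plate_id == "P1" & broken$role == "dmso_control" &
               broken$substrate == "control"] <- NA
  expect_warning(out <- poc_normalize(broken), "P1")
  expect_true(all(is.na(out$poc[out$plate_id == "P1"])))
  expect_false(anyNA(out$poc[out$plate_id == "P2"]))
})

test_that("virtual row shuffling is a cyclic bijection preserving row positions", {
  st <- generate_plate_stack(plate_stack_spec(seed = 3))
  p <- poc_normalize(st$wells)
  vw <- shuffle_rows(p, "control", group_size = 3)
  # bijection: every control-substrate source well appears exactly once
  src <- paste(vw$source_plate, vw$source_well)
  expect_equal(anyDuplicated(src), 0)
  expect_equal(nrow(vw), sum(p$substrate == "control" & p$role != "empty"))
  # cyclic rule for group 1: virtual plate 1 takes B of P1, C of P2, D of P3
  v1 <- vw[vw$virtual_plate == "control_g1_v1", ]
  expect_equal(unique(v1$source_plate[v1$row == "B"]), "P1")
  expect_equal(unique(v1$source_plate[v1$row == "C"]), "P2")
  expect_equal(unique(v1$source_plate[v1$row == "D"]), "P3")
  # rows keep their plate position and compounds occur once per virtual plate
  for (vp in unique(vw$virtual_plate)) {
    block <- vw[vw$virtual_plate == vp, ]
    expect_setequal(unique(block$row), c("B", "C", "D"))
    comp <- block$compound[!is.na(block$compound) & block$role == "compound"]
    expect_equal(anyDuplicated(comp), 0)
  }
  # only comparable stack positions are mixed
  g1 <- unique(vw$source_plate[vw$stack_group == 1])
  expect_setequal(g1, c("P1", "P2", "P3"))
  expect_error(shuffle_rows(p, "control", group_size = 2), "divisible|replicate rows")
})

test_that("reverse shuffle is the exact inverse of shuffling", {
  st <- generate_plate_stack(plate_stack_spec(seed = 6))
  p <- poc_normalize(st$wells)
  for (s in c("control", "coated")) {
    vw <- shuffle_rows(p, s, group_size = 3)
    back <- reverse_shuffle(vw, cols = "poc")
    orig <- p[p$substrate == s & p$role != "empty", c("plate_id", "well", "poc")]
    orig <- dplyr::arrange(orig, .data$plate_id, .data$well)
    expect_equal(back, tibble::as_tibble(orig))
  }
})

test_that("median polish matches stats::medpolish and its contracts", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, byrow = TRUE)
  mine <- median_polish(m, max_iter = 100, tol = 1e-10)
  orac <- stats::medpolish(m, maxiter = 100, eps = 1e-10, trace.iter = FALSE)
  expect_equal(mine$residuals, orac$residuals, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(mine$overall, orac$overall, tolerance = 1e-8)
  expect_equal(mine$row, orac$row, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(mine$col, orac$col, ignore_attr = TRUE, tolerance = 1e-8)
  # reconstruction identity
  rec <- mine$overall + outer(mine$row, mine$col, `+`) + mine$residuals
  expect_equal(rec, m, ignore_attr = TRUE, tolerance = 1e-12)

  # purely additive matrix -> zero residuals
  add <- 5 + outer(c(1, 2, 3, 4), c(-2, 0, 2, 5), `+`)
  fit <- median_polish(add)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  expect_true(fit$converged)

  # idempotence at convergence: polishing the residuals changes nothing
  again <- median_polish(fit$residuals, max_iter = 50)
  expect_lt(max(abs(again$residuals - fit$residuals)), 1e-9)

  # random matrices against the oracle
  set.seed(13)
  for (i in 1:4) {
    r <- matrix(rnorm(48), 6, 8)
    a <- median_polish(r, max_iter = 200, tol = 1e-9)
    b <- stats::medpolish(r, maxiter = 200, eps = 1e-9, trace.iter = FALSE)
    expect_equal(a$residuals, b$residuals, ignore_attr = TRUE, tolerance = 1e-6)
  }

  # missing cells allowed; all-missing rows rejected
  mm <- matrix(rnorm(20), 4, 5); mm[2, 3] <- NA
  fitna <- median_polish(mm)
  expect_true(is.na(fitna$residuals[2, 3]))
  mm2 <- mm; mm2[2, ] <- NA
  expect_error(median_polish(mm2), "entirely missing")
  expect_error(median_polish(matrix(1, 1, 5)), "2x2")
})

test_that("B-scores: additive plate gives zeros, spike ranks top, location invariant", {
  add <- 5 + outer(1:4, c(0, 3, 6, 9, 12), `+`)
  sc0 <- bscore(median_polish(add))
  expect_true(attr(sc0, "degenerate"))
  expect_true(all(sc0 == 0))

  set.seed(14)
  noisy <- add + matrix(rnorm(20, 0, 0.5), 4, 5)
  spiked <- noisy; spiked[2, 3] <- spiked[2, 3] + 10 * 0.5 * 10
  sc <- bscore(median_polish(spiked, max_iter = 50))
  expect_equal(which.max(abs(sc)), which(row(sc) == 2 & col(sc) == 3))
  expect_gt(abs(sc[2, 3]), 5)

  shifted <- bscore(median_polish(spiked + 100, max_iter = 50))
  expect_equal(sc, shifted, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("full stack normalization removes injected artifacts and keeps spikes", {
  st <- spiked_stack(seed = 1)
  norm <- normalize_stack(st$wells)
  spiked <- c("C0005", "C0030")
  inactive <- norm[norm$role == "compound" & !norm$compound %in% spiked, ]
  expect_lt(abs(mean(inactive$bscore, na.rm = TRUE)), 0.1)
  # row/column structure of inactive scores is flattened
  rowm <- tapply(inactive$bscore, inactive$row, mean, na.rm = TRUE)
  expect_lt(max(abs(rowm)), 1)
  # spiked compounds carry the top-ranked |B-scores|
  per_comp <- tapply(abs(norm$bscore[norm$role == "compound"]),
                     norm$compound[norm$role == "compound"], mean, na.rm = TRUE)
  expect_true(all(names(sort(per_comp, decreasing = TRUE))[1:2] %in% spiked))
  # positive-control wells excluded from the polish carry NA scores
  expect_true(all(is.na(norm$bscore[norm$role == "positive_control"])))
  # group size 1: identity shuffle, each plate polished as its own block
  small <- generate_plate_stack(plate_stack_spec(n_plates_per_stack = 3, seed = 5))
  n1 <- normalize_stack(small$wells, group_size = 1)
  expect_false(anyNA(n1$bscore[n1$role == "compound"]))
  pid <- poc_normalize(small$wells)
  vw1 <- shuffle_rows(pid, "control", group_size = 1)
  expect_equal(sort(paste(vw1$source_plate, vw1$source_well)),
               sort(paste(pid$plate_id, pid$well)[pid$substrate == "control" &
                                                    pid$role != "empty"]))
})
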
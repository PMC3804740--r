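#' Build the compound-library manifest
#'
#' Models the logistics of a multi-channel-pipette screen: compounds arrive on
#' 96-well stock plates (80 compounds each, inner columns 2-11), are
#' transferred row-to-row into 384-well "mother" plates whose logical rows
#' each hold 9 compound slots plus DMSO control wells, and every mother row
#' then feeds exactly one 96-well assay plate. One stock plate therefore maps
#' to one sub-experiment of nine assay plates (81 slots); when a positive
#' control is enabled it occupies the spare slot of the last row, otherwise
#' that slot holds an extra DMSO well.
#'
#' @param n_stock_plates Number of 96-well stock plates.
#' @param compounds_per_plate Compounds per stock plate (<= 80, and must fit
#'   the nine 9-slot rows of a sub-experiment).
#' @param dmso_per_row DMSO control wells per mother row.
#' @param positive_control Logical; reserve one slot per sub-experiment for
#'   the positive-control compound (`"POSCTRL"`).
#' @return A `library_manifest`: list with tibbles `stock_plates` (one row per
#'   compound: `compound`, `stock_plate`, `stock_well`) and `mother_rows` (one
#'   row per mother-row slot: `sub_experiment`, `mother_plate`, `mother_row`,
#'   `assay_plate`, `slot`, `content`).
#' @export
build_library_manifest <- function(n_stock_plates = 13L,
                                   compounds_per_plate = 80L,
                                   dmso_per_row = 3L,
                                   positive_control = TRUE) {
  stopifnot(n_stock_plates >= 1, compounds_per_plate >= 1, dmso_per_row >= 1)
  rows_per_sub <- 9L
  slots_per_row <- 9L
  capacity <- rows_per_sub * slots_per_row - as.integer(positive_control)
  if (compounds_per_plate > capacity) {
    rlang::abort(sprintf(
      "compounds_per_plate = %d cannot be grouped into %d rows of %d compound slots%s",
      compounds_per_plate, rows_per_sub, slots_per_row,
      if (positive_control) " (one slot reserved for the positive control)" else ""
    ))
  }
  if (compounds_per_plate > 80L) {
    rlang::abort("a 96-well stock plate holds at most 80 compounds (inner columns 2-11)")
  }

  n_total <- n_stock_plates * compounds_per_plate
  compound <- sprintf("C%04d", seq_len(n_total))

  stock_well <- well_name(
    rep(plate_row_letters(), each = 10L),
    rep(2:11, times = 8L)
  )[seq_len(compounds_per_plate)]
  stock <- tibble::tibble(
    compound = compound,
    stock_plate = rep(sprintf("SP%02d", seq_len(n_stock_plates)), each = compounds_per_plate),
    stock_well = rep(stock_well, times = n_stock_plates)
  )

  rows_list <- lapply(seq_len(n_stock_plates), function(sub) {
    ids <- compound[((sub - 1L) * compounds_per_plate + 1L):(sub * compounds_per_plate)]
    slots <- rep(NA_character_, rows_per_sub * slots_per_row)
    slots[seq_along(ids)] <- ids
    if (positive_control) slots[length(slots)] <- "POSCTRL"
    slots[is.na(slots)] <- "DMSO"
    per_row <- matrix(slots, nrow = rows_per_sub, byrow = TRUE)
    purrr::map_dfr(seq_len(rows_per_sub), function(r) {
      content <- c(per_row[r, ], rep("DMSO", dmso_per_row))
      tibble::tibble(
        sub_experiment = sub,
        row_in_sub = r,
        assay_plate = sprintf("S%02d_P%d", sub, r),
        slot = seq_along(content),
        content = content
      )
    })
  })
  mother_rows <- dplyr::bind_rows(rows_list)
  # sequential packing of logical rows onto 16-row 384-well mother plates
  global_row <- seq_len(n_stock_plates * rows_per_sub)
  mother_rows$mother_plate <- sprintf("MP%02d", ceiling(
    global_row[(mother_rows$sub_experiment - 1L) * rows_per_sub + mother_rows$row_in_sub] / 16
  ))
  mother_rows$mother_row <- LETTERS[
    ((mother_rows$sub_experiment - 1L) * rows_per_sub + mother_rows$row_in_sub - 1L) %% 16L + 1L
  ]
  mother_rows <- mother_rows[, c("sub_experiment", "mother_plate", "mother_row",
                                 "row_in_sub", "assay_plate", "slot", "content")]
  structure(
    list(stock_plates = stock, mother_rows = mother_rows),
    class = "library_manifest"
  )
}

#' @export
print.library_manifest <- function(x, ...) {
  n_comp <- nrow(x$stock_plates)
  n_plates <- length(unique(x$mother_rows$assay_plate))
  cat(sprintf(
    "<library_manifest> %d compounds on %d stock plates; %d assay plates\n",
    n_comp, length(unique(x$stock_plates$stock_plate)), n_plates
  ))
  invisible(x)
}

#' Build one 96-well assay-plate layout
#'
#' Lays out a spreading-assay plate: the outer ring (rows A and H, columns 1
#' and 12; 36 wells) is empty, rows B-D carry the control substrate, rows E-G
#' the coated (inhibitory) substrate, and each of the ten inner columns holds
#' the same treatment in all six inner rows, so every compound is measured in
#' triplicate on both substrates. Without a positive control the nine
#' treatments fill columns 2-10 and DMSO column 11; with one, the ninth
#' treatment is the positive control pinned to `positive_control_column`
#' (default 10), eight compounds fill columns 2-9 and DMSO stays in 11.
#'
#' @param treatments Character vector of exactly 9 treatment ids. When
#'   `positive_control_column` is given, the *last* id is taken as the
#'   positive control.
#' @param plate_id Plate identifier.
#' @param stack_position Position of the plate in its incubator stack (1 =
#'   bottom).
#' @param sub_experiment Sub-experiment (stack) identifier.
#' @param positive_control_column Inner column reserved for the positive
#'   control, or `NULL` for none.
#' @return A tibble (one row per well) with columns `plate_id`,
#'   `stack_position`, `sub_experiment`, `well`, `row`, `col`, `role`
#'   (`empty`, `dmso_control`, `compound`, `positive_control`), `compound`
#'   and `substrate` (`control`, `coated`, or `NA` for empty rows).
#' @export
build_assay_layout <- function(treatments,
                               plate_id = "P1",
                               stack_position = 1L,
                               sub_experiment = 1L,
                               positive_control_column = NULL) {
  if (length(treatments) != 9L) {
    rlang::abort("exactly 9 treatment ids are required (one per non-DMSO inner column)")
  }
  if (!is.null(positive_control_column) &&
      !(positive_control_column %in% 2:11)) {
    rlang::abort("positive_control_column must be an inner column (2-11)")
  }
  grid <- tidyr::expand_grid(row = plate_row_letters(), col = 1:12)
  grid$well <- well_name(grid$row, grid$col)
  outer_ring <- grid$row %in% c("A", "H") | grid$col %in% c(1L, 12L)

  dmso_col <- 11L
  if (is.null(positive_control_column)) {
    compound_cols <- 2:10
    col_assign <- stats::setNames(treatments, compound_cols)
    pc_col <- NA_integer_
  } else {
    pc_col <- as.integer(positive_control_column)
    if (pc_col == dmso_col) rlang::abort("positive control cannot share the DMSO column")
    compound_cols <- setdiff(2:11, c(dmso_col, pc_col))
    col_assign <- stats::setNames(treatments[-9L], compound_cols)
    col_assign[as.character(pc_col)] <- treatments[9L]
  }

  grid$role <- "empty"
  grid$compound <- NA_character_
  inner <- !outer_ring
  grid$role[inner & grid$col == dmso_col] <- "dmso_control"
  comp_idx <- inner & as.character(grid$col) %in% names(col_assign)
  grid$role[comp_idx] <- "compound"
  grid$compound[comp_idx] <- col_assign[as.character(grid$col[comp_idx])]
  if (!is.na(pc_col)) {
    idx <- inner & grid$col == pc_col
    grid$role[idx] <- "positive_control"
  }
  grid$substrate <- dplyr::case_when(
    grid$row %in% c("B", "C", "D") ~ "control",
    grid$row %in% c("E", "F", "G") ~ "coated",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    plate_id = plate_id,
    stack_position = as.integer(stack_position),
    sub_experiment = as.integer(sub_experiment),
    grid[, c("well", "row", "col", "role", "compound", "substrate")]
  )
}

#' Imaging-site layout within a well
#'
#' Places `n_sites` field positions on an annular set of concentric rings in
#' well-normalised coordinates (well centre at the origin, well radius 0.5):
#' no field at the well centre, none within the border margin. Counts are
#' distributed over rings in proportion to ring circumference; the layout is
#' fully deterministic.
#'
#' @param n_sites Number of imaging fields per well (default 24).
#' @param r_inner,r_outer Inner/outer radial bounds of the annulus.
#' @return A tibble with columns `site` (1-based), `x`, `y`, `ring`, `radius`.
#' @export
site_layout <- function(n_sites = 24L, r_inner = 0.15, r_outer = 0.40) {
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) rlang::abort("n_sites must be >= 1")
  stopifnot(r_inner > 0, r_outer > r_inner, r_outer < 0.5)
  n_rings <- max(1L, as.integer(round(sqrt(n_sites / 6))))
  radii <- r_inner + (seq_len(n_rings) - 0.5) / n_rings * (r_outer - r_inner)
  raw <- radii / sum(radii) * n_sites
  counts <- floor(raw)
  rem <- n_sites - sum(counts)
  if (rem > 0) {
    counts[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  out <- purrr::map_dfr(seq_len(n_rings), function(k) {
    m <- counts[k]
    if (m == 0) return(NULL)
    ang <- 2 * pi * (seq_len(m) - 1L) / m + (k - 1L) * pi / max(1L, m)
    tibble::tibble(ring = k, radius = radii[k], x = radii[k] * cos(ang), y = radii[k] * sin(ang))
  })
  out$site <- seq_len(nrow(out))
  out[, c("site", "x", "y", "ring", "radius")]
}

# Filename meta-tagging -------------------------------------------------------

channel_names <- c(w1 = "nuclear", w2 = "actin", w3 = "marker")

#' Pad a raw microscope filename with layout meta-tags
#'
#' Turns a raw acquisition name such as `"B02_s01_w1.tif"` into a
#' self-describing name embedding plate, well, site, channel and treatment
#' metadata as underscore-delimited `key=value` tags, taken from the plate
#' layout. [parse_tags()] is the exact inverse.
#'
#' @param raw Raw filename carrying well, site (`s<k>`) and wavelength
#'   (`w1` = nuclear/DAPI, `w2` = actin/phalloidin, `w3` = marker)
#'   identifiers.
#' @param layout A plate layout from [build_assay_layout()].
#' @return The meta-tagged filename (character scalar).
#' @export
tag_filename <- function(raw, layout) {
  m <- regmatches(raw, regexec("^([A-H][0-9]{2})_s([0-9]+)_w([0-9])\\.(tif|tiff|png)$", raw))[[1]]
  if (length(m) == 0) rlang::abort(sprintf("unparseable raw filename: %s", raw))
  well <- m[2]; site <- as.integer(m[3]); chan <- paste0("w", m[4])
  if (!chan %in% names(channel_names)) rlang::abort(sprintf("unknown wavelength %s", chan))
  info <- layout[layout$well == well, ]
  if (nrow(info) != 1) rlang::abort(sprintf("well %s not found in layout", well))
  sprintf(
    "%s_%s_s%02d_%s_sub=%d_substrate=%s_role=%s_compound=%s.%s",
    info$plate_id, well, site, chan, info$sub_experiment,
    ifelse(is.na(info$substrate), "NA", info$substrate), info$role,
    ifelse(is.na(info$compound), "none", info$compound), m[5]
  )
}

#' Parse a meta-tagged filename back into metadata
#'
#' @param name A filename produced by [tag_filename()].
#' @return A one-row tibble: `plate_id`, `well`, `site`, `channel`,
#'   `sub_experiment`, `substrate`, `role`, `compound`.
#' @export
parse_tags <- function(name) {
  pat <- paste0(
    "^(.+)_([A-H][0-9]{2})_s([0-9]+)_(w[0-9])",
    "_sub=([0-9]+)_substrate=([a-zA-Z]+)_role=([a-z_]+)_compound=([^.]+)\\.(tif|tiff|png)$"
  )
  m <- regmatches(name, regexec(pat, name))[[1]]
  if (length(m) == 0) rlang::abort(sprintf("unparseable tagged filename: %s", name))
  tibble::tibble(
    plate_id = m[2],
    well = m[3],
    site = as.integer(m[4]),
    channel = unname(channel_names[m[5]]),
    sub_experiment = as.integer(m[6]),
    substrate = ifelse(m[7] == "NA", NA_character_, m[7]),
    role = m[8],
    compound = ifelse(m[9] == "none", NA_character_, m[9])
  )
}

# Well aggregation ------------------------------------------------------------

#' Aggregate per-cell records into per-well measurements
#'
#' Groups cell records by `(plate_id, well)` and summarises them into the
#' well-level quantities used by normalization: total cell count, separated
#' count, spread count and the arithmetic mean cytoplasm area over separated
#' cells. Wells with no separated cells get an `NA` mean and are flagged so
#' that normalization can treat them as missing.
#'
#' @param records A tibble of cell records (see [measure_field()]) with at
#'   least `plate_id`, `well`, `area_cytoplasm`, `separated` and (optionally)
#'   `class` columns.
#' @return A tibble, one row per `(plate_id, well)`: `n_cells_total`,
#'   `n_separated`, `n_spread`, `mean_area_cytoplasm`, `flagged`.
#' @export
aggregate_wells <- function(records) {
  stopifnot(all(c("plate_id", "well", "area_cytoplasm", "separated") %in% names(records)))
  has_class <- "class" %in% names(records)
  records |>
    dplyr::group_by(.data$plate_id, .data$well) |>
    dplyr::summarise(
      n_cells_total = dplyr::n(),
      n_separated = sum(.data$separated),
      n_spread = if (has_class) sum(.data$class == "spread" & .data$separated, na.rm = TRUE) else NA_integer_,
      mean_area_cytoplasm = if (any(.data$separated)) {
        mean(.data$area_cytoplasm[.data$separated])
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$n_separated == 0L)
}

#' @rdname aggregate_wells
#' @details `aggregate_well()` is the single-well form and errors on
#'   mixed-well input.
#' @export
aggregate_well <- function(records) {
  key <- unique(records[, c("plate_id", "well")])
  if (nrow(key) != 1) rlang::abort("aggregate_well() received records from more than one well")
  aggregate_wells(records)
}

#' Bin cytoplasm areas into relative-frequency bins
#'
#' Categorises per-cell cytoplasm areas into bins of width
#' `bin_width * max(area)` (10% intervals by default) and returns relative
#' frequencies plus the cumulative distribution, the object-based analysis
#' used alongside well means.
#'
#' @param records Tibble with an `area_cytoplasm` column.
#' @param bin_width Bin width as a fraction of the maximum area.
#' @return A tibble: `bin`, `lower`, `upper`, `n`, `pct`, `cum_pct`. `pct`
#'   sums to 100 and `cum_pct` is monotone, ending at 100.
#' @export
bin_areas <- function(records, bin_width = 0.10) {
  stopifnot(bin_width > 0, bin_width <= 1)
  x <- records$area_cytoplasm
  x <- x[!is.na(x)]
  if (length(x) == 0) rlang::abort("bin_areas() needs at least one record")
  top <- max(x)
  if (top <= 0) top <- 1
  n_bins <- ceiling(1 / bin_width - 1e-9)
  breaks <- seq(0, by = bin_width * top, length.out = n_bins + 1L)
  breaks[n_bins + 1L] <- max(breaks[n_bins + 1L], top)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  pct <- 100 * counts / length(x)
  tibble::tibble(
    bin = seq_len(n_bins),
    lower = breaks[-(n_bins + 1L)],
    upper = breaks[-1L],
    n = counts,
    pct = pct,
    cum_pct = cumsum(pct)
  )
}
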
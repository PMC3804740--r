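# Stage orchestration with file handoffs, mirroring an acquisition ->
# object detection -> normalization -> reporting chain. Each stage is
# independently invokable; every run writes a manifest sufficient to
# reproduce it (config + seed + package version).

default_run_config <- function() {
  list(
    seed = 1L,
    fields = list(n_fields = 2L, n_cells = 25L, contact_pairs = 2L),
    plate = list(),
    segmentation = list(),
    filter = list(distance = 1L, max_neighbors = 0L, max_percent = 0),
    normalization = list(group_size = 3L, exclude_positive_control = TRUE),
    hits = list(bscore_cutoff = 5, min_replicates_agreeing = 3L)
  )
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config %||% list())
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

write_manifest <- function(out_dir, stage, cfg, extra = list()) {
  manifest <- c(
    list(
      stage = stage,
      seed = cfg$seed,
      config = cfg,
      config_hash = rlang::hash(cfg),
      package_version = as.character(utils::packageVersion("spreadscreen"))
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a synthetic screening dataset on disk
#'
#' Writes a synthetic plate stack (layouts + raw well table as CSV), and
#' optionally a few ground-truthed image fields (16-bit TIFF channels plus
#' truth label maps and truth CSV), together with a JSON manifest recording
#' the seed and configuration hash.
#'
#' @param config A configuration list or path to a YAML file; omitted
#'   entries fall back to package defaults. Recognised blocks: `seed`,
#'   `fields` (`n_fields`, plus [field_spec()] arguments), `plate`
#'   ([plate_stack_spec()] arguments).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the written paths.
#' @export
run_simulate <- function(config = list(), out_dir = "simulated") {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plate_args <- cfg$plate
  plate_args$seed <- plate_args$seed %||% cfg$seed
  spec <- do.call(plate_stack_spec, plate_args)
  stack <- generate_plate_stack(spec)
  readr::write_csv(stack$layouts, file.path(out_dir, "layouts.csv"))
  readr::write_csv(stack$wells, file.path(out_dir, "wells_raw.csv"))

  n_fields <- cfg$fields$n_fields %||% 0L
  field_paths <- character(0)
  if (n_fields > 0) {
    fdir <- file.path(out_dir, "fields")
    dir.create(fdir, showWarnings = FALSE)
    fargs <- cfg$fields[setdiff(names(cfg$fields), "n_fields")]
    for (i in seq_len(n_fields)) {
      fargs$seed <- cfg$seed + i
      fs <- do.call(field_spec, fargs)
      fld <- generate_field(fs)
      base <- sprintf("field%02d", i)
      EBImage::writeImage(fld$nuclear, file.path(fdir, paste0(base, "_w1.tif")),
                          type = "tiff", bits.per.sample = 16L)
      EBImage::writeImage(fld$actin, file.path(fdir, paste0(base, "_w2.tif")),
                          type = "tiff", bits.per.sample = 16L)
      truth <- fld$truth$class
      truth$area_cell <- tabulate(fld$truth$cell_mask[fld$truth$cell_mask > 0],
                                  nbins = nrow(truth))
      readr::write_csv(truth, file.path(fdir, paste0(base, "_truth.csv")))
      field_paths <- c(field_paths, file.path(fdir, base))
    }
  }
  write_manifest(out_dir, "simulate", cfg, list(n_fields = n_fields))
  invisible(list(out_dir = out_dir, wells = file.path(out_dir, "wells_raw.csv"),
                 fields = field_paths))
}

#' Segment one synthetic or loaded field end to end
#'
#' Composes the imaging stages on a single field: illumination correction
#' (gain supplied or estimated), nuclear-channel rescale, nucleus detection,
#' seeded cell propagation, cytoplasm subtraction, neighbour analysis,
#' separated-cell filtering and feature extraction. The per-stage object
#' counts are attached as attribute `"filter_log"`, a tibble whose counts
#' are monotone non-increasing along the filter chain.
#'
#' @param nuclear,actin Channel matrices.
#' @param illumination Optional [estimate_illumination()] field applied to
#'   both channels.
#' @param params [seg_params()].
#' @param distance,max_neighbors,max_percent Filter settings.
#' @param ... Identifier columns passed to [measure_field()].
#' @return The separated-cell feature tibble; label maps are attached as
#'   attribute `"maps"`.
#' @export
segment_field <- function(nuclear, actin, illumination = NULL,
                          params = seg_params(), distance = 1L,
                          max_neighbors = 0L, max_percent = 0, ...) {
  if (!is.null(illumination)) {
    nuclear <- correct_illumination(nuclear, illumination)
    actin <- correct_illumination(actin, illumination)
  }
  nuclei <- detect_nuclei(rescale_minmax(nuclear), params)
  n_nuclei <- max(nuclei)
  prop <- propagate_cells(actin, nuclei, params)
  n_cells <- max(prop$cells)
  cyto <- tertiary_cytoplasm(prop$cells, prop$nuclei)
  stats <- measure_neighbors(prop$cells, distance = distance)
  filt <- filter_separated(prop$cells, prop$nuclei, cyto, stats,
                           max_neighbors = max_neighbors, max_percent = max_percent)
  sep_stats <- measure_neighbors(filt$cells, distance = distance)
  records <- measure_field(filt$cells, filt$nuclei, filt$cytoplasm,
                           stats = sep_stats, ...)
  attr(records, "filter_log") <- tibble::tibble(
    stage = c("nuclei_detected", "cells_after_border", "separated_retained"),
    n = c(n_nuclei, n_cells, max(filt$cells))
  )
  attr(records, "maps") <- filt
  records
}

#' Run the segmentation stage over simulated fields
#'
#' Reads the TIFF fields written by [run_simulate()], estimates the
#' illumination gain from the ensemble of actin images, and writes the
#' per-object feature CSV plus a structured filter-count log.
#'
#' @param config Configuration list or YAML path (uses the `segmentation`
#'   and `filter` blocks).
#' @param in_dir Directory holding `fields/` from [run_simulate()].
#' @param out_dir Output directory.
#' @return Invisibly, the objects tibble.
#' @export
run_segment <- function(config = list(), in_dir = "simulated", out_dir = "segmented") {
  cfg <- read_run_config(config)
  fdir <- file.path(in_dir, "fields")
  w1 <- sort(list.files(fdir, pattern = "_w1\\.tif$", full.names = TRUE))
  if (length(w1) == 0) {
    rlang::abort(sprintf("no nuclear-channel images found under %s; run_simulate() first", fdir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  actin_imgs <- lapply(sub("_w1\\.tif$", "_w2.tif", w1), function(p) {
    as_image_matrix(EBImage::readImage(p))
  })
  illum <- estimate_illumination(actin_imgs)
  params <- do.call(seg_params, cfg$segmentation)
  logs <- list()
  objects <- purrr::map_dfr(seq_along(w1), function(i) {
    nuc <- as_image_matrix(EBImage::readImage(w1[i]))
    rec <- segment_field(
      nuc, actin_imgs[[i]], illumination = illum, params = params,
      distance = cfg$filter$distance, max_neighbors = cfg$filter$max_neighbors,
      max_percent = cfg$filter$max_percent,
      plate_id = "P1", well = "B02", site = i
    )
    logs[[i]] <<- dplyr::mutate(attr(rec, "filter_log"), site = i)
    rec
  })
  readr::write_csv(objects, file.path(out_dir, "objects.csv"))
  readr::write_csv(dplyr::bind_rows(logs), file.path(out_dir, "filter_log.csv"))
  write_manifest(out_dir, "segment", cfg, list(n_fields = length(w1)))
  invisible(objects)
}

#' Run the normalization stage
#'
#' Reads the raw well table, applies POC + virtual-row-shuffling B-score
#' normalization and writes the normalized long table plus per-plate
#' heatmap matrices (raw, POC, B-score) as CSV.
#'
#' @param config Configuration list or YAML path (`normalization` block).
#' @param in_dir Directory containing `wells_raw.csv`.
#' @param out_dir Output directory.
#' @return Invisibly, the normalized well tibble.
#' @export
run_normalize <- function(config = list(), in_dir = "simulated", out_dir = "normalized") {
  cfg <- read_run_config(config)
  path <- file.path(in_dir, "wells_raw.csv")
  if (!file.exists(path)) {
    rlang::abort(sprintf("missing input %s; run_simulate() first", path))
  }
  wells <- readr::read_csv(path, show_col_types = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  norm <- normalize_stack(
    wells,
    group_size = cfg$normalization$group_size,
    exclude_positive_control = cfg$normalization$exclude_positive_control
  )
  readr::write_csv(norm, file.path(out_dir, "wells_normalized.csv"))
  for (val in c("raw", "poc", "bscore")) {
    hm <- norm |>
      dplyr::filter(!is.na(.data[[val]])) |>
      dplyr::select("plate_id", "row", "col", dplyr::all_of(val)) |>
      tidyr::pivot_wider(names_from = "col", values_from = dplyr::all_of(val))
    readr::write_csv(hm, file.path(out_dir, sprintf("heatmap_%s.csv", val)))
  }
  write_manifest(out_dir, "normalize", cfg)
  invisible(norm)
}

#' Run the reporting stage: SSMD, hit selection, export
#'
#' Reads the normalized well table, computes the SSMD between the
#' positive-control and DMSO wells (per substrate, on POC values), selects
#' hits with the configured rule and exports the long table, pivot and hit
#' list.
#'
#' @param config Configuration list or YAML path (`hits` block).
#' @param in_dir Directory containing `wells_normalized.csv`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `hits`, `ssmd` (tibble per substrate) and
#'   the exported paths.
#' @export
run_report <- function(config = list(), in_dir = "normalized", out_dir = "report") {
  cfg <- read_run_config(config)
  path <- file.path(in_dir, "wells_normalized.csv")
  if (!file.exists(path)) {
    rlang::abort(sprintf("missing input %s; run_normalize() first", path))
  }
  norm <- readr::read_csv(path, show_col_types = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ssmd_tbl <- NULL
  if (any(norm$role == "positive_control")) {
    ssmd_tbl <- purrr::map_dfr(intersect(c("control", "coated"), unique(norm$substrate)), function(s) {
      pos <- norm$poc[norm$role == "positive_control" & norm$substrate == s]
      neg <- norm$poc[norm$role == "dmso_control" & norm$substrate == s]
      dplyr::mutate(glance(ssmd(pos, neg)), substrate = s, .before = 1)
    })
    jsonlite::write_json(ssmd_tbl, file.path(out_dir, "ssmd.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  hits <- select_hits(
    norm,
    bscore_cutoff = cfg$hits$bscore_cutoff,
    min_replicates_agreeing = cfg$hits$min_replicates_agreeing
  )
  paths <- export_results(norm, hits, dir = out_dir)
  write_manifest(out_dir, "report", cfg)
  invisible(list(hits = hits, ssmd = ssmd_tbl, paths = paths))
}
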
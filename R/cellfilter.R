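#' Neighbour analysis of segmented cells
#'
#' Measures, for every cell, the number of contacting neighbours and the
#' fraction of its boundary in contact with other cells. Two objects are
#' neighbours iff any pixel of one lies within Chebyshev distance `distance`
#' of a pixel of the other (default 1: strict 8-connected touching).
#' `percent_touching` is `100 x` (boundary pixels with a foreign object
#' within `distance`) / (total boundary pixels), where a boundary pixel is an
#' object pixel with a non-object pixel (or the image edge) among its 8
#' neighbours.
#'
#' @param cells Cell label map.
#' @param distance Contact distance in pixels (Chebyshev metric, matching
#'   8-connectivity); `0` means nothing is ever in contact.
#' @return A tibble with one row per label: `label`, `neighbor_count`,
#'   `percent_touching`, `n_boundary`. The symmetric contact graph is
#'   attached as attribute `"contact_pairs"` (tibble `a`, `b` with `a < b`)
#'   and can be read with [contact_graph()].
#' @export
measure_neighbors <- function(cells, distance = 1L) {
  stopifnot(distance >= 0)
  cells <- as_label_matrix(cells)
  n <- max(cells)
  empty <- tibble::tibble(
    label = integer(0), neighbor_count = integer(0),
    percent_touching = numeric(0), n_boundary = integer(0)
  )
  if (n == 0) {
    attr(empty, "contact_pairs") <- tibble::tibble(a = integer(0), b = integer(0))
    return(empty)
  }

  # boundary pixels: any 8-neighbour (image edge counts as background) differs
  boundary <- matrix(FALSE, nrow(cells), ncol(cells))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    boundary <- boundary | (shift_matrix(cells, dr, dc, 0L) != cells)
  }
  boundary <- boundary & cells > 0L

  contact <- matrix(FALSE, nrow(cells), ncol(cells))
  pairs <- NULL
  d <- as.integer(distance)
  if (d >= 1) {
    for (dr in -d:d) for (dc in -d:d) {
      if (dr == 0 && dc == 0) next
      sh <- shift_matrix(cells, dr, dc, 0L)
      sel <- cells > 0L & sh > 0L & sh != cells
      if (any(sel)) {
        contact <- contact | sel
        pairs <- rbind(pairs, unique(cbind(cells[sel], sh[sel])))
      }
    }
  }

  pair_tbl <- if (is.null(pairs)) {
    tibble::tibble(a = integer(0), b = integer(0))
  } else {
    u <- unique(cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))
    tibble::tibble(a = u[, 1], b = u[, 2]) |> dplyr::arrange(.data$a, .data$b)
  }

  n_boundary <- tabulate(cells[boundary], nbins = n)
  n_touch <- tabulate(cells[boundary & contact], nbins = n)
  counts <- tabulate(c(pair_tbl$a, pair_tbl$b), nbins = n)

  out <- tibble::tibble(
    label = seq_len(n),
    neighbor_count = counts,
    percent_touching = ifelse(n_boundary > 0, 100 * n_touch / n_boundary, 0),
    n_boundary = n_boundary
  )
  attr(out, "contact_pairs") <- pair_tbl
  out
}

#' Contact graph of a neighbour analysis
#'
#' @param stats A [measure_neighbors()] result.
#' @return Tibble of unordered touching pairs (`a < b`).
#' @export
contact_graph <- function(stats) {
  attr(stats, "contact_pairs") %||% tibble::tibble(a = integer(0), b = integer(0))
}

#' Filter separated cells
#'
#' Keeps exactly the cells with `neighbor_count <= max_neighbors` and
#' `percent_touching <= max_percent` (both 0 by default: only fully single
#' cells are analysed, since aggregation distorts the spreading phenotype)
#' and filters all three object tiers consistently, relabelling survivors
#' `1..N`.
#'
#' @param cells,nuclei,cytoplasm Matched label maps (`nuclei`/`cytoplasm` may
#'   be `NULL`).
#' @param stats Neighbour statistics from [measure_neighbors()], aligned to
#'   the labels of `cells`.
#' @param max_neighbors,max_percent Inclusive cutoffs.
#' @return A list with the filtered `cells`, `nuclei`, `cytoplasm` maps and
#'   `report`, a tibble (label, neighbor_count, percent_touching, retained,
#'   reason).
#' @export
filter_separated <- function(cells, nuclei = NULL, cytoplasm = NULL, stats,
                             max_neighbors = 0L, max_percent = 0) {
  cells <- as_label_matrix(cells)
  n <- max(cells)
  if (nrow(stats) != n) rlang::abort("neighbour stats not aligned to cell labels")
  retained <- stats$neighbor_count <= max_neighbors & stats$percent_touching <= max_percent
  keep <- stats$label[retained]
  report <- tibble::tibble(
    label = stats$label,
    neighbor_count = stats$neighbor_count,
    percent_touching = stats$percent_touching,
    retained = retained,
    reason = dplyr::case_when(
      retained ~ "separated",
      stats$neighbor_count > max_neighbors ~ "touching_neighbors",
      TRUE ~ "membrane_contact"
    )
  )
  list(
    cells = relabel_map(cells, keep),
    nuclei = if (!is.null(nuclei)) relabel_map(as_label_matrix(nuclei), keep),
    cytoplasm = if (!is.null(cytoplasm)) relabel_map(as_label_matrix(cytoplasm), keep),
    report = report
  )
}

#' Filter cells colocalised with a transfection marker
#'
#' For marker-based (e.g. siRNA) adaptations: detects marker objects as
#' 8-connected components of `marker >= marker_threshold` with area at least
#' `min_marker_area` (small punctate background is excluded), and retains a
#' cell iff at least one marker-object centroid falls inside it.
#'
#' @param cells Cell label map.
#' @param marker Marker-channel matrix.
#' @param marker_threshold Manual intensity threshold.
#' @param min_marker_area Minimum marker-object area in pixels.
#' @param nuclei,cytoplasm Optional matched maps filtered alongside.
#' @return A list with filtered `cells`, `nuclei`, `cytoplasm`, the retained
#'   original labels (`retained`), and the marker label map (`marker_objects`).
#' @export
filter_marker_positive <- function(cells, marker, marker_threshold,
                                   min_marker_area = 9L,
                                   nuclei = NULL, cytoplasm = NULL) {
  cells <- as_label_matrix(cells)
  marker <- as_image_matrix(marker)
  if (!all(dim(cells) == dim(marker))) rlang::abort("cells and marker shapes differ")
  mlab <- label_components(marker >= marker_threshold)
  if (max(mlab) > 0) {
    areas <- label_areas(mlab)
    mlab <- relabel_map(mlab, areas$label[areas$area >= min_marker_area])
  }
  keep <- integer(0)
  if (max(mlab) > 0) {
    for (m in seq_len(max(mlab))) {
      px <- which(mlab == m, arr.ind = TRUE)
      cy <- round(mean(px[, 1])); cx <- round(mean(px[, 2]))
      lab <- cells[cy, cx]
      if (lab > 0L) keep <- c(keep, lab)
    }
    keep <- sort(unique(keep))
  }
  list(
    cells = relabel_map(cells, keep),
    nuclei = if (!is.null(nuclei)) relabel_map(as_label_matrix(nuclei), keep),
    cytoplasm = if (!is.null(cytoplasm)) relabel_map(as_label_matrix(cytoplasm), keep),
    retained = keep,
    marker_objects = mlab
  )
}
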
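#' Segmentation parameters
#'
#' Parameters of the three-tier object recognition. The nuclear channel is
#' thresholded at a fixed fraction of its rescaled `[0, 1]` range; the actin
#' channel by default with the log-domain Otsu threshold. Nuclei outside the
#' typical diameter range (mostly staining artifacts) and objects touching
#' the image border are excluded.
#'
#' @param nucleus_threshold Fixed threshold on the rescaled nuclear channel,
#'   in `[0, 1]` (default 0.2).
#' @param nucleus_diameter_range Allowed equivalent-diameter range for nuclei
#'   in pixels (default 8-40).
#' @param lambda Regularisation of the seeded propagation (weight of spatial
#'   distance against intensity difference in the propagation cost; 0 =
#'   purely intensity-driven, large = nearest-seed/Voronoi).
#' @param actin_threshold_method `"otsu_log"` (default) or `"fixed"`.
#' @param actin_threshold Fixed actin threshold when `actin_threshold_method
#'   = "fixed"`.
#' @param border_exclusion Drop objects touching any image edge (with their
#'   matched objects in the other tiers).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(nucleus_threshold = 0.2,
                       nucleus_diameter_range = c(8, 40),
                       lambda = 0.05,
                       actin_threshold_method = c("otsu_log", "fixed"),
                       actin_threshold = NULL,
                       border_exclusion = TRUE) {
  actin_threshold_method <- match.arg(actin_threshold_method)
  stopifnot(
    nucleus_threshold > 0, nucleus_threshold < 1,
    length(nucleus_diameter_range) == 2,
    nucleus_diameter_range[1] > 0,
    nucleus_diameter_range[1] < nucleus_diameter_range[2],
    lambda >= 0
  )
  if (actin_threshold_method == "fixed" && is.null(actin_threshold)) {
    rlang::abort("actin_threshold required when actin_threshold_method = 'fixed'")
  }
  structure(
    list(
      nucleus_threshold = nucleus_threshold,
      nucleus_diameter_range = nucleus_diameter_range,
      lambda = lambda,
      actin_threshold_method = actin_threshold_method,
      actin_threshold = actin_threshold,
      border_exclusion = border_exclusion
    ),
    class = "seg_params"
  )
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged afterwards via union-find on the label
# adjacency pairs.
label_components <- function(mask) {
  mask <- mask > 0
  lbl <- as_label_matrix(EBImage::bwlabel(mask))
  n <- max(lbl)
  if (n <= 1) return(lbl)
  pairs <- NULL
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    sh <- shift_matrix(lbl, off[1], off[2], 0L)
    sel <- lbl > 0L & sh > 0L & lbl != sh
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(lbl[sel], sh[sel])))
  }
  if (is.null(pairs)) return(lbl)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  lut <- match(root, sort(unique(root)))
  out <- lbl
  out[out > 0L] <- lut[out[out > 0L]]
  storage.mode(out) <- "integer"
  out
}

#' Detect nuclei as primary objects
#'
#' Thresholds the rescaled nuclear channel at the fixed nuclear threshold,
#' labels 8-connected components, fills holes, and removes components whose
#' equivalent diameter (`2 * sqrt(area / pi)`) lies outside the typical
#' nucleus range as well as components touching the image border. Survivors
#' are relabelled `1..N` in scan order. No declumping is applied; clumped
#' nuclei are handled downstream by the separated-cell filter.
#'
#' @param image Rescaled nuclear-channel matrix with values in `[0, 1]`.
#' @param params A [seg_params()].
#' @return An integer label map (0 = background). An empty map is a valid
#'   result.
#' @export
detect_nuclei <- function(image, params = seg_params()) {
  image <- as_image_matrix(image)
  if (min(image) < 0 || max(image) > 1) {
    rlang::abort("nuclear image must be rescaled to [0, 1]; see rescale_minmax()")
  }
  lbl <- label_components(image >= params$nucleus_threshold)
  if (max(lbl) == 0) return(lbl)
  lbl <- as_label_matrix(EBImage::fillHull(lbl))
  areas <- label_areas(lbl)
  diam <- 2 * sqrt(areas$area / pi)
  keep <- areas$label[
    diam >= params$nucleus_diameter_range[1] & diam <= params$nucleus_diameter_range[2]
  ]
  if (params$border_exclusion) keep <- setdiff(keep, border_labels(lbl))
  relabel_map(lbl, keep)
}

#' Grow whole cells from nuclear seeds (secondary objects)
#'
#' Thresholds the actin channel (log-domain Otsu by default) to obtain the
#' cell foreground and assigns every foreground pixel to a nucleus by seeded
#' propagation: each pixel takes the label of the seed with the cheapest
#' path, where the path cost mixes local intensity differences with
#' Euclidean step length weighted by `lambda` (the CellProfiler propagation
#' semantics, via `EBImage::propagate()`). Nuclei pixels always belong to
#' their own cell; foreground blobs containing several nuclei are
#' partitioned between them. Cells touching the image border are removed
#' together with their nuclei and both tiers are relabelled consistently
#' (cell `k` contains nucleus `k`).
#'
#' @param image Corrected actin-channel matrix.
#' @param nuclei Primary-object label map from [detect_nuclei()].
#' @param params A [seg_params()].
#' @return A list with `cells` and `nuclei` label maps (matched labels) and
#'   `threshold`, the actin foreground threshold used.
#' @export
propagate_cells <- function(image, nuclei, params = seg_params()) {
  image <- as_image_matrix(image)
  nuclei <- as_label_matrix(nuclei)
  if (!all(dim(image) == dim(nuclei))) rlang::abort("image and nuclei shapes differ")
  if (max(nuclei) == 0) {
    return(list(cells = nuclei, nuclei = nuclei, threshold = NA_real_))
  }
  thr <- switch(params$actin_threshold_method,
    otsu_log = otsu_log_threshold(image),
    fixed = params$actin_threshold
  )
  mask <- image >= thr | nuclei > 0L   # seeds always belong to the foreground
  cells <- as_label_matrix(EBImage::propagate(image, seeds = nuclei, mask = mask,
                                              lambda = params$lambda))
  keep <- sort(unique(cells[cells > 0L]))
  if (params$border_exclusion) keep <- setdiff(keep, border_labels(cells))
  cells <- relabel_map(cells, keep)
  nuclei <- relabel_map(nuclei, keep)
  list(cells = cells, nuclei = nuclei, threshold = thr)
}

#' Derive cytoplasm (tertiary objects) by subtraction
#'
#' The cytoplasm of cell `k` is the set of its pixels not covered by nucleus
#' `k`, so `area(cytoplasm) = area(cell) - area(nucleus)` holds exactly for
#' every object. A degenerate object whose nucleus fills the whole cell keeps
#' its label with zero cytoplasm area.
#'
#' @param cells,nuclei Matched label maps (cell `k` contains nucleus `k`).
#' @return The cytoplasm label map.
#' @export
tertiary_cytoplasm <- function(cells, nuclei) {
  cells <- as_label_matrix(cells)
  nuclei <- as_label_matrix(nuclei)
  if (!all(dim(cells) == dim(nuclei))) rlang::abort("label map shapes differ")
  nl <- sort(unique(nuclei[nuclei > 0L]))
  cl <- sort(unique(cells[cells > 0L]))
  if (!setequal(nl, cl)) rlang::abort("label mismatch between primary and secondary tiers")
  inside <- nuclei > 0L
  if (any(cells[inside] != nuclei[inside])) {
    rlang::abort("label mismatch: some nucleus pixels lie outside their matched cell")
  }
  cyto <- cells
  cyto[inside] <- 0L
  cyto
}
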
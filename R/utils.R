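# Internal helpers shared across modules.

# Shift a matrix by (dr, dc), padding exposed cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rsrc <- seq_len(nr) - dr
  csrc <- seq_len(nc) - dc
  rok <- rsrc >= 1L & rsrc <= nr
  cok <- csrc >= 1L & csrc <= nc
  out[rok, cok] <- m[rsrc[rok], csrc[cok]]
  out
}

# Relabel a label map so the surviving labels become 1..N (order preserved).
# `keep` is the integer vector of labels to retain.
relabel_map <- function(labels, keep = NULL) {
  labels <- as_label_matrix(labels)
  present <- sort(unique(labels[labels > 0L]))
  if (is.null(keep)) keep <- present
  keep <- sort(intersect(keep, present))
  lut <- integer(max(c(labels, 1L)))
  lut[keep] <- seq_along(keep)
  out <- labels
  out[out > 0L] <- lut[out[out > 0L]]
  storage.mode(out) <- "integer"
  out
}

# Coerce EBImage Image or numeric matrix to a plain integer matrix.
as_label_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  m
}

as_image_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

# Labels whose pixels touch any image edge.
border_labels <- function(labels) {
  labels <- as_label_matrix(labels)
  edge <- c(labels[1, ], labels[nrow(labels), ], labels[, 1], labels[, ncol(labels)])
  sort(unique(edge[edge > 0L]))
}

label_areas <- function(labels) {
  labels <- as_label_matrix(labels)
  tab <- tabulate(labels[labels > 0L])
  tibble::tibble(label = seq_along(tab), area = tab)
}

# Standard 96-well helpers ----------------------------------------------------

plate_row_letters <- function() LETTERS[1:8]

#' Format a well name
#'
#' Combines a row letter and a column number into the zero-padded microplate
#' convention (`"B02"`).
#'
#' @param row Row letter(s), `"A"`-`"H"`.
#' @param col Column number(s), 1-12.
#' @return Character vector of well names.
#' @export
well_name <- function(row, col) sprintf("%s%02d", row, as.integer(col))

#' Split well names into row and column
#'
#' @param well Character vector of well names such as `"B02"`.
#' @return A tibble with columns `well`, `row` (letter) and `col` (integer).
#' @export
well_parts <- function(well) {
  stopifnot(all(grepl("^[A-P][0-9]{2}$", well)))
  tibble::tibble(
    well = well,
    row = substr(well, 1, 1),
    col = as.integer(substr(well, 2, 3))
  )
}
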
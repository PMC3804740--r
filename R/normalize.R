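#' Percentage-of-control normalization
#'
#' Normalises every measured well of each plate to the mean of that plate's
#' DMSO control wells on the uncoated (control) substrate:
#' `poc = 100 * raw / mean(raw of control-substrate DMSO wells)`. Applied to
#' all non-empty wells, including the coated rows, so on a noiseless plate
#' the coated DMSO wells read `100 x substrate effect`.
#'
#' @param wells Well tibble with columns `plate_id`, `role`, `substrate` and
#'   a raw value column.
#' @param value Name of the raw value column (default `"raw"`;
#'   `"mean_area_cytoplasm"` for aggregated records).
#' @return `wells` with a `poc` column. Plates without any valid control
#'   well are flagged with `NA` POC and a warning naming them; they must not
#'   silently pass into B-scoring.
#' @export
poc_normalize <- function(wells, value = "raw") {
  stopifnot(all(c("plate_id", "role", "substrate", value) %in% names(wells)))
  ctrl <- wells |>
    dplyr::filter(.data$role == "dmso_control", .data$substrate == "control",
                  !is.na(.data[[value]])) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(.ctrl_mean = mean(.data[[value]]), .groups = "drop")
  bad <- setdiff(unique(wells$plate_id), ctrl$plate_id)
  if (length(bad) > 0) {
    rlang::warn(sprintf(
      "plates without valid control wells flagged (POC = NA): %s",
      paste(bad, collapse = ", ")
    ))
  }
  wells |>
    dplyr::left_join(ctrl, by = "plate_id") |>
    dplyr::mutate(poc = 100 * .data[[value]] / .data$.ctrl_mean) |>
    dplyr::select(-".ctrl_mean")
}

substrate_rows <- function(substrate) {
  switch(substrate, control = c("B", "C", "D"), coated = c("E", "F", "G"),
         rlang::abort(sprintf("unknown substrate: %s", substrate)))
}

#' Virtual row shuffling
#'
#' Reassembles the replicate rows of one substrate from the plates of each
#' stack group into single-substrate, replicate-free virtual plates so that
#' the B-score's inactive-majority assumption holds. Virtual plate `v` of a
#' group of `g` plates takes replicate row `r` from plate `(v + r - 2) mod g
#' + 1` (a cyclic Latin square), so each row keeps its original row position,
#' each compound occurs exactly once per virtual plate, and only plates in
#' comparable stack positions are mixed. The assignment is a bijection onto
#' the source wells and is exactly invertible with [reverse_shuffle()].
#'
#' @param wells POC-normalised well tibble (columns `plate_id`,
#'   `stack_position`, `row`, `col`, `substrate`, `role`, `compound`, `poc`).
#' @param substrate `"control"` or `"coated"`.
#' @param group_size Plates per stack group; must equal the number of
#'   replicate rows per substrate (3).
#' @return A tibble of virtual wells: `virtual_plate`, `stack_group`, `row`
#'   (original row position), `col`, `role`, `compound`, `poc`, plus the
#'   shuffle map columns `source_plate`, `source_well`.
#' @export
shuffle_rows <- function(wells, substrate = c("control", "coated"), group_size = 3L) {
  substrate <- match.arg(substrate)
  rows <- substrate_rows(substrate)
  group_size <- as.integer(group_size)
  w <- wells[wells$substrate == substrate & wells$role != "empty", ]
  plates <- w |>
    dplyr::distinct(.data$plate_id, .data$stack_position) |>
    dplyr::arrange(.data$stack_position)
  if (nrow(plates) %% group_size != 0) {
    rlang::abort("number of plates is not divisible by group_size")
  }
  if (group_size == 1L) {
    # degenerate identity shuffle: each plate is its own virtual plate,
    # keeping its whole substrate block (replicates included)
    out <- tibble::tibble(
      virtual_plate = sprintf("%s_g%d_v1", substrate, match(w$plate_id, plates$plate_id)),
      stack_group = match(w$plate_id, plates$plate_id),
      substrate = substrate,
      row = w$row, col = w$col, role = w$role, compound = w$compound,
      poc = w$poc, source_plate = w$plate_id, source_well = w$well
    )
    return(dplyr::arrange(out, .data$stack_group, .data$row, .data$col))
  }
  if (group_size != length(rows)) {
    rlang::abort(sprintf(
      "group_size (%d) must equal the replicate rows per substrate (%d)",
      group_size, length(rows)
    ))
  }
  plates$group <- ceiling(seq_len(nrow(plates)) / group_size)
  plates$idx_in_group <- (seq_len(nrow(plates)) - 1L) %% group_size + 1L

  out <- purrr::map_dfr(unique(plates$group), function(gr) {
    gp <- plates[plates$group == gr, ]
    purrr::map_dfr(seq_len(group_size), function(v) {
      purrr::map_dfr(seq_len(group_size), function(r) {
        src_idx <- (v + r - 2L) %% group_size + 1L
        src_plate <- gp$plate_id[gp$idx_in_group == src_idx]
        block <- w[w$plate_id == src_plate & w$row == rows[r], ]
        tibble::tibble(
          virtual_plate = sprintf("%s_g%d_v%d", substrate, gr, v),
          stack_group = gr,
          substrate = substrate,
          row = block$row, col = block$col,
          role = block$role, compound = block$compound,
          poc = block$poc,
          source_plate = block$plate_id,
          source_well = block$well
        )
      })
    })
  })
  # audit: the shuffle must be a bijection onto the source wells
  src <- paste(out$source_plate, out$source_well)
  if (anyDuplicated(src) || length(src) != nrow(w)) {
    rlang::abort("internal error: shuffle is not a bijection onto source wells")
  }
  out
}

#' Reverse the virtual row shuffle
#'
#' Returns normalized scores to their original `(plate, well)` coordinates
#' using the shuffle map carried by the virtual wells;
#' `reverse_shuffle(shuffle_rows(x))` is the identity on well coordinates
#' and every source well receives exactly one score.
#'
#' @param virtual_wells A [shuffle_rows()] tibble, typically with a `bscore`
#'   column added.
#' @param cols Score columns to carry back (default those present among
#'   `poc`, `bscore`).
#' @return Tibble: `plate_id`, `well`, score columns.
#' @export
reverse_shuffle <- function(virtual_wells, cols = intersect(c("poc", "bscore"), names(virtual_wells))) {
  stopifnot(all(c("source_plate", "source_well") %in% names(virtual_wells)))
  src <- paste(virtual_wells$source_plate, virtual_wells$source_well)
  if (anyDuplicated(src)) rlang::abort("virtual wells map twice to one source well")
  out <- tibble::tibble(
    plate_id = virtual_wells$source_plate,
    well = virtual_wells$source_well
  )
  for (cl in cols) out[[cl]] <- virtual_wells[[cl]]
  dplyr::arrange(out, .data$plate_id, .data$well)
}

#' Tukey median polish
#'
#' Iteratively sweeps row and column medians out of a matrix, decomposing it
#' into `overall + row effect + column effect + residual`. Missing cells are
#' allowed (medians are taken over present cells) and stay missing in the
#' residuals. The reconstruction identity
#' `input = overall + row + col + residual` holds exactly by construction.
#'
#' @param mat Numeric matrix, at least 2x2; `NA` marks flagged/empty wells.
#' @param max_iter Maximum sweep iterations.
#' @param tol Convergence tolerance: stop when no row or column median
#'   adjustment exceeds `tol`.
#' @return An object of class `median_polish`: list with `overall`, `row`,
#'   `col`, `residuals`, `iterations`, `converged`.
#' @export
median_polish <- function(mat, max_iter = 20L, tol = 1e-6) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) rlang::abort("median_polish() needs at least a 2x2 matrix")
  if (any(rowSums(!is.na(mat)) == 0) || any(colSums(!is.na(mat)) == 0)) {
    rlang::abort("median_polish(): a row or column is entirely missing")
  }
  res <- mat
  r <- rep(0, nrow(mat)); cl <- rep(0, ncol(mat)); overall <- 0
  converged <- FALSE
  iter <- 0L
  oldsum <- 0
  while (iter < max_iter) {
    iter <- iter + 1L
    rdelta <- apply(res, 1, stats::median, na.rm = TRUE)
    res <- sweep(res, 1, rdelta)
    r <- r + rdelta
    delta <- stats::median(cl)
    cl <- cl - delta; overall <- overall + delta
    cdelta <- apply(res, 2, stats::median, na.rm = TRUE)
    res <- sweep(res, 2, cdelta)
    cl <- cl + cdelta
    delta <- stats::median(r)
    r <- r - delta; overall <- overall + delta
    # stop on vanishing adjustments, or when the total absolute residual
    # stagnates (the sweeps can cycle without improving the decomposition)
    newsum <- sum(abs(res), na.rm = TRUE)
    if ((max(abs(rdelta)) < tol && max(abs(cdelta)) < tol) ||
        newsum == 0 || abs(newsum - oldsum) < tol * newsum) {
      converged <- TRUE
      break
    }
    oldsum <- newsum
  }
  structure(
    list(overall = overall, row = r, col = cl, residuals = res,
         iterations = iter, converged = converged),
    class = "median_polish"
  )
}

#' @export
print.median_polish <- function(x, ...) {
  cat(sprintf(
    "<median_polish> %dx%d, overall %.4g, %d iterations, converged: %s\n",
    nrow(x$residuals), ncol(x$residuals), x$overall, x$iterations, x$converged
  ))
  invisible(x)
}

#' B-scores from median-polish residuals
#'
#' Scales the polish residuals by the median absolute deviation of all
#' residuals (`MAD = 1.4826 * median(|residual|)`, the Gaussian-consistent
#' constant), giving a robust plate-normalised score in which row and column
#' effects have been removed. Adding a constant to the whole plate leaves
#' B-scores unchanged. If the MAD is zero (a perfectly additive plate) all
#' scores are defined as 0 and the result is flagged degenerate.
#'
#' @param polish A [median_polish()] result.
#' @param mad_constant Scale constant (default 1.4826).
#' @param mad Optional externally supplied scale (e.g. a MAD pooled over the
#'   virtual plates of one substrate and stack group, which is steadier than
#'   the per-plate MAD when a virtual plate has only three rows).
#' @return Matrix of B-scores with attributes `mad` and `degenerate`.
#' @export
bscore <- function(polish, mad_constant = 1.4826, mad = NULL) {
  stopifnot(inherits(polish, "median_polish"))
  res <- polish$residuals
  mad <- mad %||% (mad_constant * stats::median(abs(res), na.rm = TRUE))
  degenerate <- !is.na(mad) && mad == 0
  scores <- if (degenerate) {
    out <- res; out[!is.na(out)] <- 0; out
  } else {
    res / mad
  }
  attr(scores, "mad") <- mad
  attr(scores, "degenerate") <- degenerate
  scores
}

virtual_matrix <- function(vp) {
  rows <- sort(unique(vp$row))
  cols <- sort(unique(vp$col))
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(vp$row, rows), match(vp$col, cols))] <- vp$poc
  m
}

#' Full two-step plate-stack normalization
#'
#' Runs the complete normalization of one experimental stack: POC per plate,
#' virtual row shuffling per substrate and stack group, median polish and
#' B-scoring of every virtual plate, and reverse shuffling of the scores to
#' the original layout.
#'
#' @param wells Raw well tibble (see [generate_plate_stack()] or
#'   [aggregate_wells()] joined to a layout).
#' @param value Raw value column name.
#' @param group_size Plates per stack group (default 3).
#' @param exclude_positive_control Exclude the positive-control column from
#'   the polish (recommended: a whole active column of strong effect distorts
#'   the row/column fits); its wells then carry `NA` B-scores.
#' @param max_iter,tol Passed to [median_polish()].
#' @return `wells` with `poc` and `bscore` columns added.
#' @export
normalize_stack <- function(wells, value = "raw", group_size = 3L,
                            exclude_positive_control = TRUE,
                            max_iter = 20L, tol = 1e-6) {
  wells <- poc_normalize(wells, value = value)
  measured <- wells[wells$role != "empty" & !is.na(wells$poc), ]
  scored <- purrr::map_dfr(c("control", "coated"), function(substr) {
    vw <- shuffle_rows(measured, substrate = substr, group_size = group_size)
    purrr::map_dfr(unique(vw$stack_group), function(gr) {
      grp <- vw[vw$stack_group == gr, ]
      # fit every virtual plate of the group first, then scale all residuals
      # by the MAD pooled over the group: a single 3-row virtual plate leaves
      # too few residual degrees of freedom for a stable per-plate MAD
      fits <- lapply(unique(grp$virtual_plate), function(vpid) {
        vp <- grp[grp$virtual_plate == vpid, ]
        vp_fit <- vp
        if (exclude_positive_control) {
          vp_fit$poc[vp_fit$role == "positive_control"] <- NA_real_
        }
        m <- virtual_matrix(vp_fit)
        # a column excluded as a whole (the positive control) cannot be
        # polished; drop it so its wells carry NA B-scores
        m <- m[, colSums(!is.na(m)) > 0, drop = FALSE]
        list(vp = vp, mp = median_polish(m, max_iter = max_iter, tol = tol))
      })
      pooled <- unlist(lapply(fits, function(f) f$mp$residuals))
      mad_pooled <- 1.4826 * stats::median(abs(pooled), na.rm = TRUE)
      purrr::map_dfr(fits, function(f) {
        sc <- bscore(f$mp, mad = if (mad_pooled > 0) mad_pooled else NULL)
        vp <- f$vp
        vp$bscore <- sc[cbind(match(vp$row, rownames(sc)), match(vp$col, colnames(sc)))]
        vp
      })
    })
  })
  back <- reverse_shuffle(scored, cols = "bscore")
  dplyr::left_join(wells, back, by = c("plate_id", "well"))
}
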
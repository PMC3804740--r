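#' Strictly standardized mean difference (SSMD)
#'
#' Assay-quality metric between two control groups:
#' `beta = (mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2)` with sample
#' standard deviations (method-of-moments estimator). A value above 7
#' against a strong positive control indicates excellent assay quality.
#'
#' @param pos,neg Numeric vectors of positive- and negative-control well
#'   values (each `n >= 2`).
#' @return An object of class `ssmd_result`: `beta`, `n_pos`, `n_neg`,
#'   `mean_pos`, `mean_neg`, `sd_pos`, `sd_neg`, `infinite` (flag set when
#'   both group variances are zero; `beta` is then signed infinity, never
#'   `NaN`).
#' @export
ssmd <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) < 2 || length(neg) < 2) {
    rlang::abort("ssmd() requires at least 2 values per group")
  }
  dm <- mean(pos) - mean(neg)
  denom <- sqrt(stats::var(pos) + stats::var(neg))
  infinite <- denom == 0
  beta <- if (infinite) {
    if (dm == 0) 0 else sign(dm) * Inf
  } else {
    dm / denom
  }
  structure(
    list(
      beta = beta, n_pos = length(pos), n_neg = length(neg),
      mean_pos = mean(pos), mean_neg = mean(neg),
      sd_pos = stats::sd(pos), sd_neg = stats::sd(neg),
      infinite = infinite
    ),
    class = "ssmd_result"
  )
}

#' @export
print.ssmd_result <- function(x, ...) {
  cat(sprintf(
    "<ssmd_result> beta = %.3f  (pos: n=%d, %.2f +- %.2f; neg: n=%d, %.2f +- %.2f)\n",
    x$beta, x$n_pos, x$mean_pos, x$sd_pos, x$n_neg, x$mean_neg, x$sd_neg
  ))
  invisible(x)
}

#' @rdname ssmd
#' @param x An `ssmd_result`.
#' @param ... Unused.
#' @export
glance.ssmd_result <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, n_pos = x$n_pos, n_neg = x$n_neg,
    mean_pos = x$mean_pos, mean_neg = x$mean_neg,
    sd_pos = x$sd_pos, sd_neg = x$sd_neg
  )
}

#' Select hit compounds from normalized well scores
#'
#' Replaces interactive scatter-plot picking with an explicit, reproducible
#' rule. Per compound and substrate the mean B-score over the replicate
#' wells is computed; in `"threshold"` mode a compound is selected iff
#' `|mean| >= bscore_cutoff` and at least `min_replicates_agreeing`
#' replicates share the sign of the mean; in `"rank"` mode the `top_k`
#' compounds by `|mean|` (that also satisfy the replicate-agreement rule)
#' are selected. Negative hits reduce spreading, positive hits increase it.
#'
#' @param wells Normalized wells (see [normalize_stack()]) with `role`,
#'   `compound`, `substrate`, `bscore` columns.
#' @param bscore_cutoff Absolute mean B-score threshold (threshold mode).
#' @param min_replicates_agreeing Minimum replicates whose B-score shares
#'   the sign of the mean.
#' @param method `"threshold"` or `"rank"`.
#' @param top_k Number of hits per substrate in rank mode.
#' @param substrates Substrate scope (default both).
#' @return A `hit_table` tibble ordered by `|mean_score|` descending:
#'   `compound`, `substrate`, `mean_score`, `replicate_scores` (list),
#'   `n_replicates`, `n_agreeing`, `direction`, `selected`, `rule`.
#' @export
select_hits <- function(wells, bscore_cutoff = 5, min_replicates_agreeing = 3L,
                        method = c("threshold", "rank"), top_k = 10L,
                        substrates = c("control", "coated")) {
  method <- match.arg(method)
  missing_sub <- setdiff(substrates, unique(wells$substrate))
  if (length(missing_sub) > 0) {
    rlang::abort(sprintf("substrate(s) absent from scores: %s",
                         paste(missing_sub, collapse = ", ")))
  }
  if (method == "threshold" && bscore_cutoff <= 0) {
    rlang::warn("bscore_cutoff <= 0 selects every compound (degenerate rule)")
  }
  scores <- wells |>
    dplyr::filter(.data$role == "compound", .data$substrate %in% substrates,
                  !is.na(.data$bscore)) |>
    dplyr::group_by(.data$compound, .data$substrate) |>
    dplyr::summarise(
      mean_score = mean(.data$bscore),
      replicate_scores = list(.data$bscore),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_agreeing = purrr::map2_int(.data$replicate_scores, .data$mean_score,
                                   ~ sum(sign(.x) == sign(.y))),
      direction = ifelse(.data$mean_score < 0, "negative", "positive")
    )
  rule_txt <- if (method == "threshold") {
    sprintf("|mean B| >= %g & >= %d replicates agreeing", bscore_cutoff, min_replicates_agreeing)
  } else {
    sprintf("top %d by |mean B| & >= %d replicates agreeing", top_k, min_replicates_agreeing)
  }
  scores <- dplyr::arrange(scores, dplyr::desc(abs(.data$mean_score)))
  agree <- scores$n_agreeing >= min_replicates_agreeing
  scores$selected <- if (method == "threshold") {
    abs(scores$mean_score) >= bscore_cutoff & agree
  } else {
    sel <- rep(FALSE, nrow(scores))
    for (s in unique(scores$substrate)) {
      idx <- which(scores$substrate == s & agree)
      sel[utils::head(idx, top_k)] <- TRUE
    }
    sel
  }
  scores$rule <- rule_txt
  class(scores) <- c("hit_table", class(scores))
  scores
}

#' Export normalized results and hit lists to CSV
#'
#' Writes three files into `dir`: `wells_long.csv` (the long-format
#' normalized table; re-importing it with [readr::read_csv()] reproduces
#' the in-memory table), `pivot.csv` (compounds x substrates with replicate
#' B-score columns, mean and SEM) and `hits.csv` (the hit table without the
#' list column).
#'
#' @param wells Normalized well tibble.
#' @param hits A [select_hits()] table (optional).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
export_results <- function(wells, hits = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(long = file.path(dir, "wells_long.csv"),
             pivot = file.path(dir, "pivot.csv"))
  readr::write_csv(wells, paths["long"])
  pivot <- wells |>
    dplyr::filter(.data$role == "compound", !is.na(.data$bscore)) |>
    dplyr::group_by(.data$compound, .data$substrate) |>
    dplyr::arrange(.data$row, .by_group = TRUE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$bscore),
      sem = stats::sd(.data$bscore) / sqrt(dplyr::n()),
      reps = list(stats::setNames(.data$bscore, paste0("rep", seq_along(.data$bscore)))),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("reps") |>
    dplyr::relocate(dplyr::starts_with("rep"), .after = "substrate")
  readr::write_csv(pivot, paths["pivot"])
  if (!is.null(hits)) {
    paths["hits"] <- file.path(dir, "hits.csv")
    flat <- dplyr::select(tibble::as_tibble(hits), -"replicate_scores")
    readr::write_csv(flat, paths["hits"])
  }
  invisible(paths)
}
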
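#' Train a capped rule-based (boosted-stump) phenotype classifier
#'
#' Fits an ensemble of single-feature threshold rules by gentle boosting:
#' each round selects the feature/threshold stump minimising the weighted
#' squared error of the per-class vote targets, assigns each side of the
#' split the weighted mean target per class (the rule's vote weights), and
#' reweights examples multiplicatively. Training stops at `max_rules` rules
#' or at zero training error. Candidate thresholds are the midpoints of
#' sorted unique feature values, and ties are broken by feature name and
#' then by threshold, so training is fully deterministic and invariant to
#' record order.
#'
#' @param records A data frame of labelled cell records; the class column
#'   must contain at least 2 classes with at least 2 examples each.
#' @param max_rules Maximum number of rules (default 20).
#' @param features Character vector of feature columns; defaults to all
#'   numeric columns except identifiers.
#' @param class_col Name of the class column.
#' @param seed Unused for fitting (training is deterministic); accepted for
#'   interface symmetry with the resampling helpers.
#' @return An object of class `rule_model`: list with `rules` (tibble:
#'   `feature`, `threshold`, plus one vote column per class for each side of
#'   the split), `classes`, `features`, `max_rules`, `train_error`.
#' @export
train_rules <- function(records, max_rules = 20L, features = NULL,
                        class_col = "class", seed = NULL) {
  stopifnot(max_rules >= 1)
  if (nrow(records) == 0) rlang::abort("empty training set")
  y_raw <- as.character(records[[class_col]])
  classes <- sort(unique(y_raw))
  if (length(classes) < 2) rlang::abort("training requires at least 2 classes")
  if (any(table(y_raw) < 2)) rlang::abort("every class needs at least 2 examples")
  features <- features %||% default_feature_columns(records, class_col)
  if (length(features) == 0) rlang::abort("no feature columns found")
  features <- sort(features)
  X <- as.matrix(records[, features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); K <- length(classes)
  Y <- matrix(-1, n, K)
  Y[cbind(seq_len(n), match(y_raw, classes))] <- 1

  W <- matrix(1 / (n * K), n, K)
  FF <- matrix(0, n, K)
  rules <- list()

  for (round in seq_len(max_rules)) {
    best <- NULL
    for (j in seq_along(features)) {
      cand <- best_stump_for_feature(X[, j], Y, W)
      if (is.null(cand)) next
      if (is.null(best) || cand$gain > best$gain + 1e-12) {
        # features scanned in sorted-name order: earlier name wins exact ties;
        # within a feature, which.max picks the smallest tying threshold
        cand$feature <- features[j]
        best <- cand
      }
    }
    if (is.null(best)) break
    gt <- X[, best$feature] > best$threshold
    H <- matrix(rep(best$vote_le, each = n), n, K)
    H[gt, ] <- matrix(rep(best$vote_gt, each = sum(gt)), sum(gt), K)
    FF <- FF + H
    W <- W * exp(-Y * H)
    W <- W / sum(W)
    rules[[length(rules) + 1L]] <- tibble::tibble(
      rule = length(rules) + 1L,
      feature = best$feature,
      threshold = best$threshold,
      side = c("gt", "le"),
      votes = list(stats::setNames(best$vote_gt, classes), stats::setNames(best$vote_le, classes))
    )
    pred <- classes[max.col(FF, ties.method = "first")]
    if (all(pred == y_raw)) break
  }

  pred <- classes[max.col(FF, ties.method = "first")]
  structure(
    list(
      rules = dplyr::bind_rows(rules),
      classes = classes,
      features = features,
      max_rules = as.integer(max_rules),
      train_error = mean(pred != y_raw)
    ),
    class = "rule_model"
  )
}

default_feature_columns <- function(records, class_col) {
  skip <- c(class_col, "plate_id", "well", "site", "label", "separated")
  nm <- setdiff(names(records), skip)
  nm[vapply(records[nm], is.numeric, logical(1))]
}

# Best threshold for one feature under gentle-boost weighted least squares.
# Maximised gain = sum_k [ S_le^2/W_le + S_gt^2/W_gt ] with S = sum(w*y),
# W = sum(w) per side (the constant term sum(w*y^2) is side-independent).
best_stump_for_feature <- function(x, Y, W) {
  ord <- order(x)
  xs <- x[ord]
  distinct <- which(diff(xs) > 0)
  if (length(distinct) == 0) return(NULL)
  WY <- W * Y
  cs_wy <- apply(WY[ord, , drop = FALSE], 2, cumsum)     # n x K
  cs_w <- apply(W[ord, , drop = FALSE], 2, cumsum)
  tot_wy <- cs_wy[nrow(cs_wy), ]
  tot_w <- cs_w[nrow(cs_w), ]
  le_wy <- cs_wy[distinct, , drop = FALSE]
  le_w <- cs_w[distinct, , drop = FALSE]
  gt_wy <- matrix(tot_wy, length(distinct), ncol(Y), byrow = TRUE) - le_wy
  gt_w <- matrix(tot_w, length(distinct), ncol(Y), byrow = TRUE) - le_w
  gain <- rowSums(ifelse(le_w > 0, le_wy^2 / le_w, 0)) +
    rowSums(ifelse(gt_w > 0, gt_wy^2 / gt_w, 0))
  i <- which.max(gain)  # earliest (= smallest threshold) among exact ties
  thr <- (xs[distinct[i]] + xs[distinct[i] + 1L]) / 2
  list(
    gain = gain[i],
    threshold = thr,
    vote_le = ifelse(le_w[i, ] > 0, le_wy[i, ] / le_w[i, ], 0),
    vote_gt = ifelse(gt_w[i, ] > 0, gt_wy[i, ] / gt_w[i, ], 0)
  )
}

rule_votes <- function(model, records) {
  X <- as.matrix(records[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); K <- length(model$classes)
  FF <- matrix(0, n, K, dimnames = list(NULL, model$classes))
  if (n == 0 || nrow(model$rules) == 0) return(FF)
  per_rule <- split(model$rules, model$rules$rule)
  for (r in per_rule) {
    gt <- X[, r$feature[1]] > r$threshold[1]
    v_gt <- r$votes[[which(r$side == "gt")]]
    v_le <- r$votes[[which(r$side == "le")]]
    FF <- FF + outer(as.numeric(gt), v_gt[model$classes]) +
      outer(as.numeric(!gt), v_le[model$classes])
  }
  FF
}

#' Predict phenotype classes with a rule model
#'
#' @param object A [train_rules()] model.
#' @param newdata Data frame of records carrying the model's feature columns.
#' @param type `"class"` (default) or `"votes"` (the per-class summed vote
#'   matrix).
#' @param ... Unused.
#' @return Character vector of classes, or the vote matrix. Vote ties go to
#'   the first class in `object$classes`.
#' @export
predict.rule_model <- function(object, newdata, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    rlang::abort(sprintf("missing feature columns: %s", paste(missing, collapse = ", ")))
  }
  FF <- rule_votes(object, newdata)
  if (type == "votes") return(FF)
  if (nrow(FF) == 0) return(character(0))
  object$classes[max.col(FF, ties.method = "first")]
}

#' Classify cell records
#'
#' Pipe-friendly wrapper: returns the records with the `class` column filled
#' from the model's prediction.
#'
#' @param records Data frame of cell records.
#' @param model A [train_rules()] model.
#' @return `records` with an updated `class` column.
#' @export
classify_cells <- function(records, model) {
  records$class <- predict(model, records)
  records
}

#' Stratified cross-validated accuracy
#'
#' Splits the labelled records into `folds` stratified folds (per-class
#' round-robin after a seeded shuffle), trains on each complement and
#' returns the pooled held-out accuracy. With `folds = nrow(records)` this
#' is leave-one-out.
#'
#' @param records Labelled records.
#' @param folds Number of folds (>= 2); every class must have at least
#'   `folds` members or at least 2 in the LOO case.
#' @param max_rules,features,class_col Passed to [train_rules()].
#' @param seed Seed for the fold shuffle.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
crossval_accuracy <- function(records, folds = 5L, max_rules = 20L,
                              features = NULL, class_col = "class", seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2) rlang::abort("folds must be >= 2")
  y <- as.character(records[[class_col]])
  counts <- table(y)
  if (any(counts < 2) || (folds < nrow(records) && any(counts < folds))) {
    rlang::abort("too few examples per class for the requested folds")
  }
  fold_id <- integer(nrow(records))
  with_local_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  correct <- logical(nrow(records))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (!any(test)) next
    if (length(unique(y[!test])) < 2) {
      correct[test] <- FALSE
      next
    }
    model <- train_rules(records[!test, , drop = FALSE], max_rules = max_rules,
                         features = features, class_col = class_col)
    correct[test] <- predict(model, records[test, , drop = FALSE]) == y[test]
  }
  mean(correct)
}

#' @export
print.rule_model <- function(x, ...) {
  cat(sprintf(
    "<rule_model> %d rules (cap %d), classes: %s, training error %.3f\n",
    max(c(0L, x$rules$rule)), x$max_rules,
    paste(x$classes, collapse = "/"), x$train_error
  ))
  invisible(x)
}

#' Tidy a rule model
#'
#' One row per rule and split side, with the vote weight for each class in
#' its own column (broom convention).
#'
#' @param x A `rule_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rule_model <- function(x, ...) {
  if (nrow(x$rules) == 0) {
    return(tibble::tibble(rule = integer(0), feature = character(0),
                          threshold = numeric(0), side = character(0)))
  }
  votes <- purrr::map_dfr(x$rules$votes, ~ tibble::as_tibble(as.list(.x)))
  dplyr::bind_cols(x$rules[, c("rule", "feature", "threshold", "side")], votes)
}

#' Glance at a rule model
#'
#' @param x A `rule_model`.
#' @param ... Unused.
#' @return One-row tibble: `n_rules`, `max_rules`, `n_classes`,
#'   `train_error`.
#' @export
glance.rule_model <- function(x, ...) {
  tibble::tibble(
    n_rules = max(c(0L, x$rules$rule)),
    max_rules = x$max_rules,
    n_classes = length(x$classes),
    train_error = x$train_error
  )
}

#' Persist / restore a rule model as human-readable JSON
#'
#' @param model A `rule_model`.
#' @param path File path.
#' @return `write_rule_model()` returns `path` invisibly;
#'   `read_rule_model()` returns the restored `rule_model`.
#' @export
write_rule_model <- function(model, path) {
  obj <- list(
    classes = model$classes,
    features = model$features,
    max_rules = model$max_rules,
    train_error = model$train_error,
    rules = tidy(model)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_model
#' @export
read_rule_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- tibble::as_tibble(obj$rules)
  vote_cols <- setdiff(names(rules), c("rule", "feature", "threshold", "side"))
  votes <- lapply(seq_len(nrow(rules)), function(i) {
    stats::setNames(as.numeric(unlist(rules[i, vote_cols])), vote_cols)
  })
  structure(
    list(
      rules = tibble::tibble(
        rule = as.integer(rules$rule), feature = rules$feature,
        threshold = rules$threshold, side = rules$side, votes = votes
      ),
      classes = obj$classes,
      features = obj$features,
      max_rules = as.integer(obj$max_rules),
      train_error = obj$train_error
    ),
    class = "rule_model"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
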
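#' Specification for a synthetic assay-plate stack
#'
#' Parametrises the well-level generator that emulates one sub-experiment: a
#' stack of 96-well assay plates (9 by default, plate 1 at the bottom), each
#' testing 9 treatments in triplicate on two substrates. Raw well values are
#' composed as
#' `baseline x substrate x compound x positive-control multipliers + row +
#' column + stack-position additive biases + Gaussian noise`, so that
#' zero-noise, zero-artifact plates are an exact composition of the
#' parameters. Separated-cell counts are drawn around `cells_per_well_mean`.
#'
#' Defaults mirror the screen's study conditions: 9 plates per stack, a
#' coated-substrate effect halving spreading, 2500 plated cells yielding
#' about 350 separated cells per well, and a positive control that enhances
#' spreading.
#'
#' @param n_plates_per_stack Plates per experimental stack (default 9); must
#'   be divisible by `group_size` used downstream (3-plate shuffle groups).
#' @param baseline_area Mean cytoplasm area (square micrometres) of
#'   control-substrate DMSO wells.
#' @param substrate_effect Multiplicative effect of the coated substrate on
#'   spreading (0.5 = halved area).
#' @param compound_effects Named numeric vector mapping compound ids to
#'   multiplicative effects (unlisted compounds are inactive, factor 1).
#' @param positive_control_effect Multiplicative effect of the positive
#'   control.
#' @param row_effects Named numeric vector of additive biases per inner row
#'   (`B`-`G`), or a single 0.
#' @param column_effects Additive biases per inner column (named by column
#'   number), or 0.
#' @param stack_position_effects Additive biases per stack position (length
#'   `n_plates_per_stack`), or 0.
#' @param well_noise_sd SD of additive Gaussian well noise (square
#'   micrometres).
#' @param cells_per_well_mean Mean separated-cell count per well.
#' @param n_cells_plated Cells plated per well (bookkeeping for counts).
#' @param positive_control Logical; include the positive control (pinned to
#'   column 10) on every plate.
#' @param seed Integer seed.
#' @return An object of class `plate_stack_spec`.
#' @seealso [generate_plate_stack()]
#' @export
plate_stack_spec <- function(n_plates_per_stack = 9L,
                             baseline_area = 1500,
                             substrate_effect = 0.5,
                             compound_effects = NULL,
                             positive_control_effect = 1.5,
                             row_effects = 0,
                             column_effects = 0,
                             stack_position_effects = 0,
                             well_noise_sd = 40,
                             cells_per_well_mean = 350,
                             n_cells_plated = 2500L,
                             positive_control = TRUE,
                             seed = 1L) {
  # YAML configs deliver effect maps as lists; flatten to named vectors
  if (is.list(compound_effects)) compound_effects <- unlist(compound_effects)
  if (is.list(row_effects)) row_effects <- unlist(row_effects)
  if (is.list(column_effects)) column_effects <- unlist(column_effects)
  if (is.list(stack_position_effects)) stack_position_effects <- unlist(stack_position_effects)
  spec <- list(
    n_plates_per_stack = as.integer(n_plates_per_stack),
    baseline_area = baseline_area,
    substrate_effect = substrate_effect,
    compound_effects = compound_effects,
    positive_control_effect = positive_control_effect,
    row_effects = row_effects,
    column_effects = column_effects,
    stack_position_effects = stack_position_effects,
    well_noise_sd = well_noise_sd,
    cells_per_well_mean = cells_per_well_mean,
    n_cells_plated = as.integer(n_cells_plated),
    positive_control = positive_control,
    seed = as.integer(seed)
  )
  stopifnot(
    spec$n_plates_per_stack >= 1,
    spec$baseline_area > 0,
    is.finite(spec$substrate_effect),
    all(is.finite(spec$row_effects)), all(is.finite(spec$column_effects)),
    all(is.finite(spec$stack_position_effects)),
    spec$well_noise_sd >= 0, spec$cells_per_well_mean > 0
  )
  if (!is.null(spec$compound_effects)) {
    stopifnot(all(is.finite(spec$compound_effects)), !is.null(names(spec$compound_effects)))
  }
  structure(spec, class = "plate_stack_spec")
}

effect_lookup <- function(map, keys, default = 0) {
  if (is.null(names(map))) {
    if (length(map) == 1) return(rep(unname(map), length(keys)))
    if (is.numeric(keys)) {
      # positional: entry k applies to key value k (e.g. stack positions)
      out <- map[as.integer(keys)]
      out[is.na(out)] <- default
      return(unname(out))
    }
    if (all(keys %in% c("B", "C", "D", "E", "F", "G")) && length(map) == 6) {
      names(map) <- c("B", "C", "D", "E", "F", "G")
    } else {
      rlang::abort("effect vectors must be named (or scalar)")
    }
  }
  out <- map[as.character(keys)]
  out[is.na(out)] <- default
  unname(out)
}

#' Generate a synthetic plate stack with known artifacts
#'
#' Builds the layouts of one experimental stack (via [build_assay_layout()],
#' 9 distinct compounds per plate, or 8 plus the positive control) and draws
#' raw per-well measurements according to the composition rule of
#' [plate_stack_spec()]. Only non-empty wells are measured; the empty outer
#' ring carries no cells.
#'
#' @param spec A [plate_stack_spec()].
#' @return A list with `layouts` (tibble of all wells of all plates) and
#'   `wells` (tibble of measured wells: layout columns plus
#'   `n_cells_total`, `n_separated`, `raw`).
#' @details If `compound_effects` names a compound absent from the generated
#'   layouts an error is raised (layout/effect-map key mismatch).
#' @export
generate_plate_stack <- function(spec) {
  stopifnot(inherits(spec, "plate_stack_spec"))
  with_local_seed(spec$seed, generate_plate_stack_impl(spec))
}

generate_plate_stack_impl <- function(spec) {
  g <- spec$n_plates_per_stack
  n_treat <- if (spec$positive_control) 8L else 9L
  layouts <- purrr::map_dfr(seq_len(g), function(p) {
    ids <- sprintf("C%04d", (p - 1L) * n_treat + seq_len(n_treat))
    treatments <- if (spec$positive_control) c(ids, "POSCTRL") else ids
    build_assay_layout(
      treatments,
      plate_id = sprintf("P%d", p),
      stack_position = p,
      sub_experiment = 1L,
      positive_control_column = if (spec$positive_control) 10L else NULL
    )
  })

  if (!is.null(spec$compound_effects)) {
    missing <- setdiff(names(spec$compound_effects), stats::na.omit(unique(layouts$compound)))
    if (length(missing) > 0) {
      rlang::abort(sprintf(
        "compound_effects names absent from layouts: %s", paste(missing, collapse = ", ")
      ))
    }
  }

  wells <- layouts[layouts$role != "empty", ]
  mult <- rep(1, nrow(wells))
  mult[wells$substrate == "coated"] <- spec$substrate_effect
  if (!is.null(spec$compound_effects)) {
    ce <- effect_lookup(c(spec$compound_effects), wells$compound, default = 1)
    ce[is.na(wells$compound)] <- 1
    mult <- mult * ce
  }
  mult[wells$role == "positive_control"] <- mult[wells$role == "positive_control"] *
    spec$positive_control_effect

  add <- effect_lookup(spec$row_effects, wells$row) +
    effect_lookup(spec$column_effects, wells$col) +
    effect_lookup(spec$stack_position_effects, wells$stack_position)

  noise <- if (spec$well_noise_sd > 0) stats::rnorm(nrow(wells), 0, spec$well_noise_sd) else 0
  wells$raw <- spec$baseline_area * mult + add + noise
  wells$n_separated <- stats::rpois(nrow(wells), spec$cells_per_well_mean)
  wells$n_cells_total <- spec$n_cells_plated

  list(layouts = layouts, wells = tibble::as_tibble(wells))
}
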
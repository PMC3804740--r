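#' Specification for a synthetic microscopy field
#'
#' Describes a two-channel (nuclear + F-actin, optionally a transfection
#' marker) fluorescence field populated with ground-truthed cells. Cells are
#' drawn as radially perturbed ellipses: spread cells are large and irregular,
#' unspread cells small and round, mimicking the two phenotypes of a
#' spreading assay. A multiplicative radial illumination falloff and additive
#' Gaussian noise emulate shading and camera noise.
#'
#' @param image_size Integer vector `c(height, width)` in pixels.
#' @param n_cells Number of cells to place.
#' @param fraction_spread Proportion of cells drawn from the spread phenotype,
#'   in `[0, 1]`.
#' @param spread_area_range,unspread_area_range Cell area intervals (pixel^2)
#'   for the two phenotypes.
#' @param nucleus_area_range Nucleus area interval (pixel^2); every nucleus is
#'   drawn strictly inside its cell, so realised nuclear areas may be smaller
#'   than requested for small cells.
#' @param contact_pairs Number of deliberately touching cell pairs; must not
#'   exceed `n_cells / 2`. All remaining cells are guaranteed separated.
#' @param illumination_gradient Amplitude of the multiplicative radial
#'   falloff (0 = flat field; 0.15 means the corners are ~15% dimmer).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param marker_fraction Fraction of cells carrying a transfection-marker
#'   spot (third channel); 0 disables the marker channel.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `field_spec` (a named list).
#' @seealso [generate_field()]
#' @export
field_spec <- function(image_size = c(256L, 256L),
                       n_cells = 30L,
                       fraction_spread = 0.5,
                       spread_area_range = c(600, 1500),
                       unspread_area_range = c(200, 450),
                       nucleus_area_range = c(60, 150),
                       contact_pairs = 0L,
                       illumination_gradient = 0.15,
                       noise_sd = 0.02,
                       marker_fraction = 0,
                       seed = 1L) {
  spec <- list(
    image_size = as.integer(image_size),
    n_cells = as.integer(n_cells),
    fraction_spread = fraction_spread,
    spread_area_range = spread_area_range,
    unspread_area_range = unspread_area_range,
    nucleus_area_range = nucleus_area_range,
    contact_pairs = as.integer(contact_pairs),
    illumination_gradient = illumination_gradient,
    noise_sd = noise_sd,
    marker_fraction = marker_fraction,
    seed = as.integer(seed)
  )
  validate_field_spec(spec)
  structure(spec, class = "field_spec")
}

validate_field_spec <- function(spec) {
  stopifnot(
    length(spec$image_size) == 2, all(spec$image_size >= 32),
    spec$n_cells >= 0,
    spec$fraction_spread >= 0, spec$fraction_spread <= 1,
    all(spec$spread_area_range > 0), all(spec$unspread_area_range > 0),
    all(spec$nucleus_area_range > 0),
    diff(spec$spread_area_range) >= 0, diff(spec$unspread_area_range) >= 0,
    spec$noise_sd >= 0, spec$illumination_gradient >= 0,
    spec$marker_fraction >= 0, spec$marker_fraction <= 1
  )
  if (spec$contact_pairs * 2 > spec$n_cells) {
    rlang::abort("contact_pairs must not exceed n_cells / 2")
  }
  invisible(spec)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rasterise one radially perturbed cell as a local logical mask.
# Returns list(mask, half) where `half` is the half-width of the square mask.
rasterise_cell <- function(area, irregularity) {
  r0 <- sqrt(area / pi)
  k <- 2:5
  w <- abs(stats::rnorm(length(k)))
  w <- w / max(sum(w), 1e-9)
  a <- irregularity * w * sample(c(-1, 1), length(k), replace = TRUE)
  phi <- stats::runif(length(k), 0, 2 * pi)
  half <- ceiling(r0 * (1 + irregularity)) + 2L
  n <- 2L * half + 1L
  dy <- matrix(rep(-half:half, n), n, n)
  dx <- t(dy)
  theta <- atan2(dy, dx)
  rad <- r0 * (1 + Reduce(`+`, lapply(seq_along(k), function(i) {
    a[i] * cos(k[i] * theta + phi[i])
  })))
  list(mask = sqrt(dx^2 + dy^2) <= rad, half = half)
}

dilate_chebyshev <- function(mask, d) {
  out <- mask
  for (dr in -d:d) for (dc in -d:d) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_matrix(mask, dr, dc, FALSE)
  }
  out
}

# Stamp a local mask onto the canvas at centre (cy, cx); returns pixel indices.
stamp_indices <- function(dim_hw, local, cy, cx) {
  half <- local$half
  rows <- (cy - half):(cy + half)
  cols <- (cx - half):(cx + half)
  ok <- local$mask & outer(rows >= 1 & rows <= dim_hw[1], cols >= 1 & cols <= dim_hw[2], `&`)
  idx <- which(ok, arr.ind = TRUE)
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}

#' Generate a ground-truthed synthetic field
#'
#' Draws the field described by a [field_spec()]: a nuclear channel (bright
#' nuclei on dim background), an actin channel (whole-cell blobs), an optional
#' marker channel, and the exact ground truth (label maps, per-cell phenotype,
#' contact graph, marker-positive set). Non-pair cells are placed with a
#' guard margin so that they touch neither each other nor the image border;
#' contact-pair partners are slid inwards until their masks just touch.
#'
#' @param spec A [field_spec()].
#' @return A list of class `synthetic_field` with elements `nuclear`, `actin`,
#'   `marker` (matrix or `NULL`), and `truth`; `truth` holds `nucleus_mask`,
#'   `cell_mask` (integer label maps sharing labels), `class` (tibble:
#'   `label`, `class`), `contact_graph` (tibble `a`, `b` with `a < b`, one row
#'   per unordered touching pair) and `marker_positive` (integer labels).
#' @details Placement is by bounded rejection sampling; if the requested cell
#'   density is infeasible an error is raised rather than returning a partial
#'   field.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  validate_field_spec(spec)
  with_local_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  cell_lab <- matrix(0L, H, W)
  nuc_lab <- matrix(0L, H, W)
  n <- spec$n_cells

  n_spread <- round(spec$fraction_spread * n)
  classes <- rep(c("spread", "unspread"), c(n_spread, n - n_spread))
  if (n > 1) classes <- sample(classes)

  pair_members <- if (spec$contact_pairs > 0) {
    matrix(seq_len(2L * spec$contact_pairs), ncol = 2, byrow = TRUE)
  } else {
    matrix(integer(0), ncol = 2)
  }
  is_partner <- rep(FALSE, n)
  if (nrow(pair_members) > 0) is_partner[pair_members[, 2]] <- TRUE

  centres <- matrix(NA_real_, n, 2)
  pixels <- vector("list", n)

  draw_local <- function(class) {
    area <- stats::runif(
      1,
      min = if (class == "spread") spec$spread_area_range[1] else spec$unspread_area_range[1],
      max = if (class == "spread") spec$spread_area_range[2] else spec$unspread_area_range[2]
    )
    irr <- if (class == "spread") stats::runif(1, 0.15, 0.30) else stats::runif(1, 0, 0.08)
    rasterise_cell(area, irr)
  }

  occupied_near <- function(px, guard) {
    # TRUE if any already-placed pixel lies within Chebyshev `guard` of px
    for (g_r in seq_len(nrow(px))) {
      r <- px[g_r, 1]; c <- px[g_r, 2]
      rr <- max(1, r - guard):min(H, r + guard)
      cc <- max(1, c - guard):min(W, c + guard)
      if (any(cell_lab[rr, cc] > 0L)) return(TRUE)
    }
    FALSE
  }

  place_single <- function(label, local, guard = 2L) {
    half <- local$half
    if (2 * half + 6 >= min(H, W)) {
      rlang::abort("cell larger than field; reduce area ranges or enlarge image")
    }
    for (try in 1:200) {
      cy <- sample((half + 2L):(H - half - 1L), 1)
      cx <- sample((half + 2L):(W - half - 1L), 1)
      px <- stamp_indices(c(H, W), local, cy, cx)
      if (!occupied_near(px, guard)) {
        cell_lab[px] <<- label
        centres[label, ] <<- c(cy, cx)
        pixels[[label]] <<- px
        return(TRUE)
      }
    }
    rlang::abort("cell placement failed after bounded retries; density infeasible")
  }

  place_partner <- function(label, local, anchor_label) {
    half <- local$half
    a_cy <- centres[anchor_label, 1]; a_cx <- centres[anchor_label, 2]
    anchor_px <- pixels[[anchor_label]]
    anchor_set <- (anchor_px[, 1] - 1) * W + anchor_px[, 2]
    for (try in 1:100) {
      ang <- stats::runif(1, 0, 2 * pi)
      dmax <- half + max(abs(anchor_px[, 1] - a_cy), abs(anchor_px[, 2] - a_cx)) + 3L
      placed <- FALSE
      for (d in 1:dmax) {
        cy <- round(a_cy + d * sin(ang)); cx <- round(a_cx + d * cos(ang))
        # still out of bounds at this offset: keep sliding (an inward-pointing
        # angle from a near-border anchor only enters the frame at larger d)
        if (cy - half < 2 || cy + half > H - 1 || cx - half < 2 || cx + half > W - 1) next
        px <- stamp_indices(c(H, W), local, cy, cx)
        key <- (px[, 1] - 1) * W + px[, 2]
        if (any(key %in% anchor_set)) next   # still overlapping: slide outwards
        # first offset with no overlap: masks are adjacent (touching)
        other <- cell_lab[px]
        if (any(other > 0L & other != anchor_label)) break  # collided elsewhere
        # ensure the pair touches nothing else within guard 2
        lab_wo <- cell_lab
        lab_wo[lab_wo == anchor_label] <- 0L
        ok <- TRUE
        for (g_r in seq_len(nrow(px))) {
          r <- px[g_r, 1]; c <- px[g_r, 2]
          rr <- max(1, r - 2L):min(H, r + 2L)
          cc <- max(1, c - 2L):min(W, c + 2L)
          if (any(lab_wo[rr, cc] > 0L)) { ok <- FALSE; break }
        }
        if (!ok) break
        # confirm adjacency at Chebyshev distance 1
        touch <- FALSE
        for (g_r in seq_len(nrow(px))) {
          r <- px[g_r, 1]; c <- px[g_r, 2]
          rr <- max(1, r - 1L):min(H, r + 1L)
          cc <- max(1, c - 1L):min(W, c + 1L)
          if (any(cell_lab[rr, cc] == anchor_label)) { touch <- TRUE; break }
        }
        if (!touch) break
        cell_lab[px] <<- label
        centres[label, ] <<- c(cy, cx)
        pixels[[label]] <<- px
        placed <- TRUE
        break
      }
      if (placed) return(TRUE)
    }
    rlang::abort("contact-pair placement failed after bounded retries")
  }

  if (n > 0) {
    for (i in seq_len(n)) {
      local <- draw_local(classes[i])
      if (is_partner[i]) {
        anchor <- pair_members[match(i, pair_members[, 2]), 1]
        place_partner(i, local, anchor)
      } else {
        place_single(i, local)
      }
    }
  }

  # nuclei: circles shrunk until fully inside their cell
  for (i in seq_len(n)) {
    px <- pixels[[i]]
    cy <- round(mean(px[, 1])); cx <- round(mean(px[, 2]))
    if (cell_lab[cy, cx] != i) {
      # centroid fell outside (very irregular cell): use an interior pixel
      j <- which.min((px[, 1] - cy)^2 + (px[, 2] - cx)^2)
      cy <- px[j, 1]; cx <- px[j, 2]
    }
    an <- stats::runif(1, spec$nucleus_area_range[1], spec$nucleus_area_range[2])
    rn <- sqrt(an / pi)
    repeat {
      half <- ceiling(rn) + 1L
      dy <- matrix(rep(-half:half, 2 * half + 1), 2 * half + 1)
      dx <- t(dy)
      loc <- list(mask = sqrt(dx^2 + dy^2) <= rn, half = half)
      npx <- stamp_indices(c(H, W), loc, cy, cx)
      if (nrow(npx) > 0 && all(cell_lab[npx] == i) && nrow(npx) < length(cell_lab[cell_lab == i])) {
        nuc_lab[npx] <- i
        break
      }
      rn <- rn * 0.85
      if (rn < 1.5) {
        nuc_lab[cy, cx] <- i  # degenerate minimum: single-pixel nucleus
        break
      }
    }
  }

  # render channels
  bg <- 0.05
  nuclear <- matrix(bg, H, W)
  actin <- matrix(bg, H, W)
  if (n > 0) {
    jn <- stats::runif(n, 0.75, 0.85)
    ja <- stats::runif(n, 0.45, 0.55)
    nuclear[nuc_lab > 0L] <- jn[nuc_lab[nuc_lab > 0L]]
    actin[cell_lab > 0L] <- ja[cell_lab[cell_lab > 0L]]
  }

  marker_positive <- integer(0)
  marker <- NULL
  if (spec$marker_fraction > 0 && n > 0) {
    n_pos <- round(spec$marker_fraction * n)
    marker_positive <- sort(sample(seq_len(n), n_pos))
    marker <- matrix(0.03, H, W)
    for (i in marker_positive) {
      npx <- which(nuc_lab == i, arr.ind = TRUE)
      cy <- round(mean(npx[, 1])); cx <- round(mean(npx[, 2]))
      half <- 3L
      dy <- matrix(rep(-half:half, 2 * half + 1), 2 * half + 1)
      dx <- t(dy)
      loc <- list(mask = sqrt(dx^2 + dy^2) <= 3, half = half)
      mpx <- stamp_indices(c(H, W), loc, cy, cx)
      marker[mpx] <- 0.9
    }
  }

  # multiplicative illumination and additive noise
  if (spec$illumination_gradient > 0) {
    gain <- illumination_gain(H, W, spec$illumination_gradient)
    nuclear <- nuclear * gain
    actin <- actin * gain
    if (!is.null(marker)) marker <- marker * gain
  }
  if (spec$noise_sd > 0) {
    nuclear <- pmax(nuclear + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
    actin <- pmax(actin + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
    if (!is.null(marker)) {
      marker <- pmax(marker + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W), 0)
    }
  }

  contact_graph <- tibble::tibble(
    a = if (nrow(pair_members)) pair_members[, 1] else integer(0),
    b = if (nrow(pair_members)) pair_members[, 2] else integer(0)
  )

  truth <- list(
    nucleus_mask = nuc_lab,
    cell_mask = cell_lab,
    class = tibble::tibble(label = seq_len(n), class = classes),
    contact_graph = contact_graph,
    marker_positive = marker_positive
  )
  structure(
    list(nuclear = nuclear, actin = actin, marker = marker, truth = truth, spec = spec),
    class = "synthetic_field"
  )
}

# The multiplicative radial falloff used by the generator (corners dimmest).
illumination_gain <- function(H, W, amplitude) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r2 <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`)
  1 - amplitude * r2 / max(r2)
}
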
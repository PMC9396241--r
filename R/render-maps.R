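#' Construct an en-face map set
#'
#' Container for one eye-visit stack of the five biomarker thickness maps
#' (um) on a fovea-centered grid of fixed 6 x 6 mm extent. Validates that
#' all five biomarkers are present with non-negative, finite values.
#'
#' @param eye_id Eye identifier.
#' @param visit Visit label (`"M0"` or `"M1"`).
#' @param maps Named list of numeric matrices `irf`, `srf`, `ped`, `hrf`,
#'   `pr`, all of identical dimensions.
#' @param extent_mm Physical extent, fixed at `c(6, 6)`.
#' @return An object of class `enface_maps`.
#' @export
enface_maps <- function(eye_id, visit, maps, extent_mm = c(6, 6)) {
  if (!setequal(names(maps), biomarkers_all())) {
    stop_contract("`maps` must contain exactly irf, srf, ped, hrf, pr")
  }
  dims <- unique(lapply(maps, dim))
  if (length(dims) != 1) stop_contract("all maps must share dimensions")
  for (bm in names(maps)) {
    if (any(!is.finite(maps[[bm]])) || any(maps[[bm]] < 0)) {
      stop_contract("map `%s` must be non-negative and finite", bm)
    }
  }
  if (!identical(as.numeric(extent_mm), c(6, 6))) {
    stop_contract("`extent_mm` is fixed at 6 x 6 mm")
  }
  structure(
    list(eye_id = eye_id, visit = visit,
         grid_rows = nrow(maps[[1]]), grid_cols = ncol(maps[[1]]),
         extent_mm = as.numeric(extent_mm), maps = maps[biomarkers_all()]),
    class = "enface_maps"
  )
}

#' @export
print.enface_maps <- function(x, ...) {
  cat(sprintf("<enface_maps> eye %s, visit %s, %d x %d px over %g x %g mm\n",
              x$eye_id, x$visit, x$grid_rows, x$grid_cols,
              x$extent_mm[1], x$extent_mm[2]))
  invisible(x)
}

grid_dims <- function(grid) {
  switch(grid,
    grid_49x768 = c(49L, 768L),
    grid_128x512 = c(128L, 512L),
    stop_contract("unknown grid type `%s`", grid)
  )
}

# Smooth non-negative base field for one biomarker: Gaussian bumps centered
# in each ETDRS zone, weighted by the zone's target share. Bump azimuths
# are offset by a hash of the eye id so maps differ across eyes while
# remaining fully deterministic.
bump_field <- function(rows, cols, extent_mm, eye_id) {
  y <- (seq_len(rows) - 0.5) * extent_mm[1] / rows - extent_mm[1] / 2
  x <- (seq_len(cols) - 0.5) * extent_mm[2] / cols - extent_mm[2] / 2
  off <- (eye_seed(0, eye_id) %% 360) * pi / 180
  gauss <- function(cy, cx, sigma) {
    exp(-outer((y - cy)^2, (x - cx)^2, `+`) / (2 * sigma^2))
  }
  central <- gauss(0, 0, 0.35)
  para <- 0
  for (a in off + 2 * pi * (0:2) / 3) {
    para <- para + gauss(sin(a), cos(a), 0.45) / 3
  }
  peri <- 0
  for (a in off + pi / 4 + 2 * pi * (0:3) / 4) {
    peri <- peri + gauss(2.0 * sin(a), 2.0 * cos(a), 0.50) / 4
  }
  list(central = central, para = para, peri = peri)
}

#' Render en-face thickness maps for one eye-visit
#'
#' Renders each fluid biomarker as a smooth sum of 2D Gaussian bumps and
#' rescales it zone-by-zone so that the zonal volumes computed by the
#' feature extractor match the simulated target volumes exactly on the
#' native grid (pixels beyond the 3 mm radius are zeroed, so the full-grid
#' volume equals the zonal total). The photoreceptor layer is rendered as
#' a thickness field around the eye's baseline with a shallow foveal
#' depression. All maps are non-negative.
#'
#' @param eye One-row eye tibble (see [generate_cohort()]).
#' @param volumes Named target volumes in nl for `irf`, `srf`, `ped`,
#'   `hrf` (e.g. one visit row of [simulate_fluid_course()]).
#' @param visit Visit label.
#' @param grid `"grid_49x768"` or `"grid_128x512"`.
#' @param config A [cohort_config()] (supplies the zonal shares).
#' @return An [enface_maps()] object.
#' @export
render_maps <- function(eye, volumes, visit, grid, config) {
  dims <- grid_dims(grid)
  rows <- dims[1]; cols <- dims[2]
  extent <- c(6, 6)
  if (any(volumes[biomarkers_fluid()] < 0, na.rm = TRUE)) {
    stop_contract("target volumes must be non-negative")
  }
  masks <- etdrs_zone_masks(rows, cols, extent)
  px_area <- prod(extent) / (rows * cols)
  outside <- !(masks$central | masks$para | masks$peri)

  groups <- bump_field(rows, cols, extent, eye$eye_id)
  # zonal integrals of each bump group, including cross-zone spill
  M <- vapply(groups, function(gf) {
    vapply(zones_all(), function(z) zonal_volume(gf, masks[[z]], px_area),
           numeric(1))
  }, numeric(3))

  maps <- lapply(biomarkers_fluid(), function(bm) {
    total <- as.numeric(volumes[[bm]])
    if (total == 0) return(matrix(0, rows, cols))
    target <- total * config$zone_shares[bm, ]
    # smooth field whose zonal integrals hit the targets: solve for the
    # three bump-group amplitudes, then a final exact (and, because the
    # solve already lands on target, near-unity) per-zone rescale
    a <- tryCatch(solve(M, target), error = function(e) rep(-1, 3))
    if (any(a < 0)) a <- target / diag(M)  # clamped fallback
    m <- a[1] * groups$central + a[2] * groups$para + a[3] * groups$peri
    m[m < 0] <- 0
    m[outside] <- 0
    for (z in zones_all()) {
      cur <- zonal_volume(m, masks[[z]], px_area)
      m[masks[[z]]] <- if (cur > 0) m[masks[[z]]] * target[[z]] / cur else 0
    }
    m
  })
  names(maps) <- biomarkers_fluid()

  y <- (seq_len(rows) - 0.5) * extent[1] / rows - extent[1] / 2
  x <- (seq_len(cols) - 0.5) * extent[2] / cols - extent[2] / 2
  d2 <- outer(y^2, x^2, `+`)
  maps$pr <- pmax(eye$pr_0 * (1 - 0.15 * exp(-d2 / (2 * 0.5^2))), 0)

  enface_maps(eye$eye_id, visit, maps, extent)
}
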
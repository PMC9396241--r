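#' Bilinear resampling of an en-face thickness map
#'
#' Resamples a 2D thickness map to a new pixel grid spanning the same
#' physical extent, interpolating bilinearly between pixel centers: pixel
#' `i` of `n` covering an extent `E` has its center at `(i - 0.5) * E / n`.
#' Target centers falling outside the source center range are clamped to
#' the edge value. Constant fields are preserved exactly and resampling to
#' the identical shape is the identity.
#'
#' @param map Numeric matrix (thickness in um).
#' @param target_rows,target_cols Output dimensions.
#' @return Numeric matrix of size `target_rows` x `target_cols`.
#' @export
resample_map <- function(map, target_rows, target_cols) {
  if (!is.matrix(map) || nrow(map) < 2 || ncol(map) < 2) {
    stop_contract("`map` must be a matrix of at least 2 x 2")
  }
  if (target_rows < 1 || target_cols < 1) {
    stop_contract("target dimensions must be positive")
  }
  if (target_rows == nrow(map) && target_cols == ncol(map)) {
    return(map)
  }
  weights <- function(n_src, n_tgt) {
    # fractional source index of each target pixel center
    pos <- ((seq_len(n_tgt) - 0.5) / n_tgt) * n_src + 0.5
    pos <- pmin(pmax(pos, 1), n_src)
    i0 <- pmin(floor(pos), n_src - 1)
    frac <- pos - i0
    w <- matrix(0, n_tgt, n_src)
    w[cbind(seq_len(n_tgt), i0)] <- 1 - frac
    w[cbind(seq_len(n_tgt), i0 + 1)] <- w[cbind(seq_len(n_tgt), i0 + 1)] + frac
    w
  }
  wr <- weights(nrow(map), target_rows)
  wc <- weights(ncol(map), target_cols)
  wr %*% map %*% t(wc)
}

#' ETDRS zone masks on a pixel grid
#'
#' Partitions a fovea-centered grid into the three ETDRS regions by the
#' Euclidean distance `d` (mm) of each pixel center from the grid center:
#' central disc `d < 0.5`, parafoveal ring `0.5 <= d < 1.5`, perifoveal
#' ring `1.5 <= d < 3.0`. The masks are pairwise disjoint and pixels with
#' `d >= 3` belong to no zone.
#'
#' @param rows,cols Grid dimensions (at least 8 each).
#' @param extent_mm Physical extent `(height, width)` in mm, default 6 x 6.
#' @return Named list of logical matrices `central`, `para`, `peri`.
#' @export
etdrs_zone_masks <- function(rows, cols, extent_mm = c(6, 6)) {
  if (any(extent_mm <= 0)) stop_contract("`extent_mm` must be positive")
  if (rows < 8 || cols < 8) stop_contract("grid must be at least 8 x 8")
  y <- (seq_len(rows) - 0.5) * extent_mm[1] / rows - extent_mm[1] / 2
  x <- (seq_len(cols) - 0.5) * extent_mm[2] / cols - extent_mm[2] / 2
  d <- sqrt(outer(y^2, x^2, `+`))
  list(
    central = d < 0.5,
    para = d >= 0.5 & d < 1.5,
    peri = d >= 1.5 & d < 3.0
  )
}

#' Zonal volume of a thickness map
#'
#' Integrates thickness over a zone:
#' `sum(thickness_um) * pixel_area_mm2` is numerically the volume in
#' nanoliters, since `1 um * 1 mm^2 = 1e-3 mm^3 = 1 nl`. A uniform 100 um
#' field over the full 6 x 6 mm grid is 3600 nl.
#'
#' @param map Thickness matrix (um).
#' @param mask Logical matrix of the same shape.
#' @param pixel_area_mm2 Area of one pixel in mm^2.
#' @return Volume in nl.
#' @export
zonal_volume <- function(map, mask, pixel_area_mm2) {
  if (!identical(dim(map), dim(mask))) {
    stop_contract("`map` and `mask` must have the same shape")
  }
  sum(map[mask]) * pixel_area_mm2
}

#' Zonal mean thickness
#'
#' Arithmetic mean of the masked pixels (um); used for the photoreceptor
#' layer, which is summarized as a thickness rather than a volume.
#'
#' @inheritParams zonal_volume
#' @return Mean thickness in um.
#' @export
zonal_mean_thickness <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) {
    stop_contract("`map` and `mask` must have the same shape")
  }
  if (!any(mask)) stop_contract("`mask` must contain at least one pixel")
  mean(map[mask])
}

#' Zonal biomarker features of one map set
#'
#' Resamples all five biomarker maps to the canonical isotropic analysis
#' grid (default 128 x 128 over 6 x 6 mm) and reduces each to three zonal
#' values: volumes in nl for IRF, SRF, PED and HRF, mean thickness in um
#' for the photoreceptor layer.
#'
#' @param mapset An [enface_maps()] object.
#' @param canonical Canonical analysis grid side length in pixels.
#' @return Tibble `(eye_id, visit, biomarker, zone, value, unit)` with
#'   exactly 15 rows.
#' @export
zonal_features <- function(mapset, canonical = 128L) {
  stopifnot(inherits(mapset, "enface_maps"))
  masks <- etdrs_zone_masks(canonical, canonical, mapset$extent_mm)
  px_area <- prod(mapset$extent_mm) / canonical^2
  purrr::map_dfr(biomarkers_all(), function(bm) {
    m <- resample_map(mapset$maps[[bm]], canonical, canonical)
    vals <- purrr::map_dbl(masks, function(msk) {
      if (bm == "pr") zonal_mean_thickness(m, msk) else zonal_volume(m, msk, px_area)
    })
    tibble::tibble(
      eye_id = mapset$eye_id, visit = mapset$visit,
      biomarker = bm, zone = zones_all(),
      value = unname(vals),
      unit = if (bm == "pr") "um" else "nl"
    )
  })
}

#' Baseline-to-follow-up change features
#'
#' Element-wise difference `M1 - M0` of zonal features. Because the zonal
#' reduction is linear, differencing the zonal aggregates equals
#' aggregating the pixel-wise difference maps.
#'
#' @param m0,m1 Zonal feature tibbles (visits `M0` and `M1`) for the same
#'   eyes.
#' @return Zonal feature tibble with `visit = "change"`.
#' @export
change_features <- function(m0, m1) {
  if (!setequal(m0$eye_id, m1$eye_id)) {
    stop_contract("`m0` and `m1` must cover the same eyes")
  }
  key <- c("eye_id", "biomarker", "zone")
  joined <- dplyr::inner_join(
    dplyr::select(m0, dplyr::all_of(key), v0 = "value", unit = "unit"),
    dplyr::select(m1, dplyr::all_of(key), v1 = "value"),
    by = key
  )
  if (nrow(joined) != nrow(m0)) {
    stop_contract("`m0` and `m1` rows do not align on (eye, biomarker, zone)")
  }
  dplyr::transmute(
    joined,
    eye_id = .data$eye_id, visit = "change",
    biomarker = .data$biomarker, zone = .data$zone,
    value = .data$v1 - .data$v0, unit = .data$unit
  )
}

#' Canonical predictor names
#'
#' The fixed 50-element feature ordering: three time blocks (`m0`, `m1`,
#' `change`), each biomarker-major and zone-minor over the 15
#' biomarker-zone pairs, followed by `bcva_m0`, `bcva_m1`, `bcva_change`,
#' `age`, `sex`.
#'
#' @return Character vector of length 50.
#' @export
feature_names <- function() {
  imaging <- as.vector(vapply(
    c("m0", "m1", "change"),
    function(tm) {
      as.vector(vapply(biomarkers_all(), function(bm) {
        paste(bm, zones_all(), tm, sep = "_")
      }, character(3)))
    },
    character(15)
  ))
  c(imaging, "bcva_m0", "bcva_m1", "bcva_change", "age", "sex")
}

#' Columns belonging to a predictor subset
#'
#' `all` is the full 50-feature vector; `baseline_only` keeps the 15
#' baseline imaging features plus baseline BCVA, age and sex (18);
#' `imaging_only` keeps the 45 imaging features.
#'
#' @param feature_set One of `"all"`, `"baseline_only"`, `"imaging_only"`.
#' @return Character vector of column names.
#' @export
feature_set_columns <- function(feature_set = c("all", "baseline_only", "imaging_only")) {
  feature_set <- match.arg(feature_set)
  nms <- feature_names()
  switch(feature_set,
    all = nms,
    baseline_only = c(grep("_m0$", nms[1:45], value = TRUE),
                      "bcva_m0", "age", "sex"),
    imaging_only = nms[1:45]
  )
}

#' Assemble per-eye predictor vectors
#'
#' Joins the three zonal feature blocks with the clinical/demographic
#' block into one wide row per eye, columns in the canonical
#' [feature_names()] order. `bcva_change` is `bcva_m1 - bcva_m0` and sex is
#' encoded female = 1, male = 0 (the choice is inert for tree-based
#' models). Any missing imaging or clinical entry raises a missing-data
#' error — eyes without both visits must be excluded upstream, never
#' imputed.
#'
#' @param zonal Long tibble of zonal features with visits `M0`, `M1` and
#'   `change` (see [zonal_features()] and [change_features()]; visit labels
#'   are matched case-insensitively).
#' @param clinical Tibble `(eye_id, bcva_m0, bcva_m1, age, sex)`.
#' @return Wide tibble: `eye_id` plus 50 predictor columns.
#' @export
assemble_features <- function(zonal, clinical) {
  z <- dplyr::mutate(
    zonal,
    name = paste(.data$biomarker, .data$zone, tolower(.data$visit), sep = "_")
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(z, "eye_id", "name", "value"),
    names_from = "name", values_from = "value"
  )
  need <- c("eye_id", "bcva_m0", "bcva_m1", "age", "sex")
  if (!all(need %in% names(clinical))) {
    stop_missing_data("`clinical` must contain %s", paste(need, collapse = ", "))
  }
  cl <- dplyr::mutate(
    clinical,
    bcva_change = .data$bcva_m1 - .data$bcva_m0,
    sex = if (is.numeric(clinical$sex)) .data$sex else as.numeric(.data$sex == "female")
  )
  out <- dplyr::inner_join(wide, cl, by = "eye_id")
  nms <- feature_names()
  missing_cols <- setdiff(nms, names(out))
  if (length(missing_cols) > 0) {
    stop_missing_data("missing feature entries: %s",
                      paste(head(missing_cols, 5), collapse = ", "))
  }
  if (nrow(out) < nrow(wide)) {
    stop_missing_data("clinical data missing for %d eye(s)", nrow(wide) - nrow(out))
  }
  vals <- as.matrix(out[nms])
  if (any(!is.finite(vals))) {
    bad <- out$eye_id[rowSums(!is.finite(vals)) > 0]
    stop_missing_data("non-finite feature values for eye(s): %s",
                      paste(head(bad, 5), collapse = ", "))
  }
  dplyr::select(out, "eye_id", dplyr::all_of(nms))
}
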
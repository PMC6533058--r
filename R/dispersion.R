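# Cargo-dispersion quantification: per-cell radial intensity profiles over
# normalized center-to-edge distance, cross-cell aggregation, per-bin
# condition comparison, peripheral/perinuclear intensity fractions.

#' Construct a cell image for dispersion analysis
#'
#' @param intensity nonnegative numeric matrix (cargo channel, arbitrary
#'   units), row/column indexed.
#' @param cell_mask logical matrix of the same shape delimiting the cell.
#' @param center_mask optional logical matrix (nucleus); its centroid
#'   defines the radial center. If absent, `center` or the cell-mask
#'   centroid is used.
#' @param center optional explicit `(row, col)` center.
#' @param pixel_size_um pixel size (um/pixel), kept for reporting.
#' @param cell_id,condition identifiers carried through the analysis.
#' @return an object of class `cell_image`.
#' @export
cell_image <- function(intensity, cell_mask, center_mask = NULL,
                       center = NULL, pixel_size_um = 1,
                       cell_id = "cell", condition = "condition") {
  intensity <- as.matrix(intensity)
  cell_mask <- as.matrix(cell_mask) > 0
  if (!all(dim(cell_mask) == dim(intensity)))
    abort("`cell_mask` must match the intensity grid shape")
  if (any(intensity < 0)) abort("intensity must be nonnegative")
  if (!is.null(center_mask)) {
    center_mask <- as.matrix(center_mask) > 0
    if (!all(dim(center_mask) == dim(intensity)))
      abort("`center_mask` must match the intensity grid shape")
    idx <- which(center_mask, arr.ind = TRUE)
    if (nrow(idx) == 0) abort("empty center mask")
    center <- colMeans(idx)
  }
  if (is.null(center)) {
    idx <- which(cell_mask, arr.ind = TRUE)
    center <- colMeans(idx)
  }
  cr <- round(center)
  if (!cell_mask[cr[1], cr[2]]) abort("center lies outside the cell mask")
  structure(
    list(
      intensity = intensity, cell_mask = cell_mask,
      center = as.numeric(center), pixel_size_um = pixel_size_um,
      cell_id = cell_id, condition = condition
    ),
    class = "cell_image"
  )
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf(
    "<cell_image> %s (%s): %d x %d px, %d in-mask px, center (%.1f, %.1f)\n",
    x$cell_id, x$condition, nrow(x$intensity), ncol(x$intensity),
    sum(x$cell_mask), x$center[1], x$center[2]
  ))
  invisible(x)
}

#' Read a numeric grid from TSV (intensity or mask)
#' @param path TSV file of numbers, one image row per line, no header.
#' @return numeric matrix.
#' @export
read_grid_tsv <- function(path) {
  as.matrix(readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE))
}

# per-pixel normalized distance: pixel radius / boundary radius along the
# same ray from the center. Rays are marched in 0.25 px steps; the boundary
# is the farthest in-mask sample along the ray (handles re-entry on mildly
# concave masks). Pixels whose ray normalization fails fall back to
# radius / max in-mask radius; their count is recorded.
normalized_radius_map <- function(cell_mask, center, step = 0.25) {
  idx <- which(cell_mask, arr.ind = TRUE)
  dr <- idx[, 1] - center[1]
  dc <- idx[, 2] - center[2]
  r <- sqrt(dr^2 + dc^2)
  u_r <- ifelse(r > 0, dr / r, 0)
  u_c <- ifelse(r > 0, dc / r, 0)
  t_max <- sqrt(nrow(cell_mask)^2 + ncol(cell_mask)^2)
  boundary <- numeric(nrow(idx))
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  for (t in seq(0, t_max, by = step)) {
    pr <- round(center[1] + t * u_r)
    pc <- round(center[2] + t * u_c)
    ok <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
    if (!any(ok)) break
    inside <- ok
    inside[ok] <- cell_mask[cbind(pr[ok], pc[ok])]
    boundary[inside] <- t
  }
  fallback <- boundary < r | boundary == 0
  rel <- numeric(nrow(idx))
  rel[!fallback] <- r[!fallback] / boundary[!fallback]
  if (any(fallback)) rel[fallback] <- r[fallback] / max(r)
  rel[r == 0] <- 0
  list(
    idx = idx,
    rel = pmin(rel, 1),
    n_fallback = sum(fallback & r > 0)
  )
}

#' Radial intensity profile of one cell
#'
#' Each in-mask pixel is assigned a normalized center-to-edge distance: its
#' distance from the center divided by the distance from the center to the
#' cell boundary along the same ray. Intensity is summed into equal-width
#' bins over \[0, 1\] and normalized by the total in-mask intensity, so the
#' per-bin fractions sum to 1 and are invariant to global intensity scaling.
#'
#' @param img a [cell_image()].
#' @param n_bins number of equal-width distance bins (default 25).
#' @return tibble of class `radial_profile`: `cell_id`, `condition`, `bin`,
#'   `r_lo`, `r_hi`, `r_mid`, `fraction`. The number of pixels that needed
#'   the concave-mask fallback normalization is in attribute `n_fallback`.
#' @export
radial_profile <- function(img, n_bins = 25L) {
  if (!inherits(img, "cell_image")) abort("`img` must be a cell_image")
  if (n_bins < 1) abort("`n_bins` must be >= 1")
  map <- normalized_radius_map(img$cell_mask, img$center)
  vals <- img$intensity[map$idx]
  total <- sum(vals)
  if (total <= 0) abort("zero total in-mask intensity")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(map$rel, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  frac <- vapply(seq_len(n_bins), function(b) sum(vals[bin == b]), numeric(1))
  frac <- frac / total
  out <- tibble::tibble(
    cell_id = img$cell_id, condition = img$condition,
    bin = seq_len(n_bins),
    r_lo = edges[-length(edges)], r_hi = edges[-1],
    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
    fraction = frac
  )
  attr(out, "n_fallback") <- map$n_fallback
  class(out) <- c("radial_profile", class(out))
  out
}

check_shared_bins <- function(profiles) {
  by_cell <- split(profiles$bin, profiles$cell_id)
  lens <- lengths(by_cell)
  if (length(unique(lens)) != 1)
    abort("profiles do not share a common binning")
  invisible(TRUE)
}

#' Aggregate per-cell radial profiles within a condition
#'
#' @param profiles a tibble of stacked [radial_profile()] rows (any number
#'   of cells; may span several conditions).
#' @return tibble: `condition`, `bin`, `r_mid`, `mean_fraction`, `sem`
#'   (sd/sqrt(n_cells)), `n_cells`.
#' @export
aggregate_condition <- function(profiles) {
  check_shared_bins(profiles)
  profiles |>
    dplyr::group_by(.data$condition, .data$bin, .data$r_mid) |>
    dplyr::summarise(
      mean_fraction = mean(.data$fraction),
      sem = if (dplyr::n() > 1) sd(.data$fraction) / sqrt(dplyr::n()) else 0,
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-bin comparison of two conditions
#'
#' At each binned distance, the per-cell intensity fractions of the two
#' conditions are compared with a two-tailed unpaired Student's t test. No
#' multiple-testing correction is applied by default (set
#' `p_adjust = "BH"` to add Benjamini-Hochberg).
#'
#' @param profiles stacked per-cell [radial_profile()] rows.
#' @param condition_a,condition_b the two condition labels to compare.
#' @param var_equal pooled-variance t test if `TRUE` (default).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return tibble: `bin`, `r_mid`, `mean_a`, `mean_b`, `p_value`.
#' @export
compare_conditions <- function(profiles, condition_a, condition_b,
                               var_equal = TRUE,
                               p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  a <- profiles[profiles$condition == condition_a, ]
  b <- profiles[profiles$condition == condition_b, ]
  if (length(unique(a$cell_id)) < 2 || length(unique(b$cell_id)) < 2)
    abort("each condition needs at least 2 cells")
  check_shared_bins(dplyr::bind_rows(a, b))
  bins <- sort(unique(a$bin))
  out <- purrr::map_dfr(bins, function(bb) {
    xa <- a$fraction[a$bin == bb]
    xb <- b$fraction[b$bin == bb]
    p <- if (sd(xa) == 0 && sd(xb) == 0) {
      if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else {
      t.test(xa, xb, var.equal = var_equal)$p.value
    }
    tibble::tibble(
      bin = bb, r_mid = a$r_mid[a$bin == bb][1],
      mean_a = mean(xa), mean_b = mean(xb), p_value = p
    )
  })
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Peripheral or perinuclear intensity fraction
#'
#' Sum of bin fractions at normalized distance at or beyond the threshold
#' (`"peripheral"`) or at or below it (`"perinuclear"`). Bins straddling the
#' threshold contribute proportionally to the overlap, so at a bin edge the
#' two regions partition the total exactly.
#'
#' @param profile one cell's [radial_profile()] tibble (or any tibble with
#'   `r_lo`, `r_hi`, `fraction` for a single cell).
#' @param region `"peripheral"` or `"perinuclear"`.
#' @param threshold normalized radius in (0, 1); defaults: 0.8 peripheral,
#'   0.2 perinuclear.
#' @return the intensity fraction (scalar in \[0, 1\]).
#' @export
intensity_fraction <- function(profile, region = c("peripheral", "perinuclear"),
                               threshold = NULL) {
  region <- match.arg(region)
  threshold <- threshold %||% if (region == "peripheral") 0.8 else 0.2
  if (!(threshold > 0 && threshold < 1)) abort("`threshold` must be in (0, 1)")
  w <- (pmin(profile$r_hi, 1) - pmax(profile$r_lo, threshold)) /
    (profile$r_hi - profile$r_lo)
  w <- pmin(pmax(w, 0), 1)
  peripheral <- sum(profile$fraction * w)
  if (region == "peripheral") peripheral
  else sum(profile$fraction) - peripheral
}

#' Combined dispersion report across conditions
#'
#' One tidy table per analysis run: per-condition per-bin mean fractions and
#' SEMs, plus (when a reference condition is given) per-bin p-values of each
#' condition against the reference.
#'
#' @param profiles stacked per-cell [radial_profile()] rows.
#' @param reference optional reference condition label for pairwise tests.
#' @return tibble: condition, bin, r_mid, mean_fraction, sem, n_cells and,
#'   with a reference, `p_vs_ref`.
#' @export
dispersion_report <- function(profiles, reference = NULL) {
  agg <- aggregate_condition(profiles)
  if (is.null(reference)) return(agg)
  if (!reference %in% profiles$condition)
    abort(sprintf("reference condition '%s' not present", reference))
  others <- setdiff(unique(profiles$condition), reference)
  pvals <- purrr::map_dfr(others, function(cc) {
    cmp <- compare_conditions(profiles, cc, reference)
    tibble::tibble(condition = cc, bin = cmp$bin, p_vs_ref = cmp$p_value)
  })
  dplyr::left_join(agg, pvals, by = c("condition", "bin"))
}

#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$r_mid, .data$fraction,
                               colour = .data$condition,
                               group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "normalized distance from center",
                  y = "intensity fraction",
                  title = "Radial cargo intensity profile") +
    ggplot2::theme_minimal()
}

#' Plot aggregated condition profiles (mean +/- SEM)
#' @param condition_profiles output of [aggregate_condition()].
#' @return a ggplot object.
#' @export
plot_condition_profiles <- function(condition_profiles) {
  ggplot2::ggplot(condition_profiles,
                  ggplot2::aes(.data$r_mid, .data$mean_fraction,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_fraction - .data$sem,
                   ymax = .data$mean_fraction + .data$sem),
      size = 0.2
    ) +
    ggplot2::labs(x = "normalized distance from center",
                  y = "mean intensity fraction (± SEM)",
                  title = "Cargo dispersion by condition") +
    ggplot2::theme_minimal()
}
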
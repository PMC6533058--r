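# Masked ensemble difference distance matrix (eDDM): residue-pair minimum
# heavy-atom distances per frame, smooth distance masking, and rank-based
# two-state comparison with significance filtering.

#' Smoothly mask long residue-pair distances
#'
#' Distances up to `c1` pass through unchanged; between `c1` and `c2` the
#' value follows a quarter-cosine ramp; beyond `c2` it saturates at
#' `c1 + 2 (c2 - c1) / pi`. The function is continuous with a continuous
#' first derivative at both break points, monotone nondecreasing, and
#' 1-Lipschitz, so differences between short (contact-range) distances are
#' kept intact while differences between long distances are suppressed.
#'
#' @param x nonnegative distance(s), Angstrom.
#' @param c1 lower break point (Angstrom, default 4).
#' @param c2 upper break point (Angstrom, default 8); requires `0 < c1 < c2`.
#' @return masked distance(s), same length as `x`.
#' @examples
#' mask_distance(c(3, 6, 8, 12))
#' @export
mask_distance <- function(x, c1 = 4, c2 = 8) {
  if (!(c1 > 0 && c2 > c1)) abort("mask parameters need 0 < c1 < c2")
  if (any(!is.finite(x)) || any(x < 0)) abort("distances must be finite and >= 0")
  cap <- c1 + 2 * (c2 - c1) / pi
  mid <- c1 + (2 * (c2 - c1) / pi) * cos((pi / 2) * (c2 - x) / (c2 - c1))
  out <- ifelse(x <= c1, x, ifelse(x <= c2, mid, cap))
  out
}

residue_atom_index <- function(conf_or_ens, heavy_only = TRUE) {
  atoms <- conf_or_ens$atoms
  idx <- seq_len(nrow(atoms))
  if (heavy_only) idx <- idx[atoms$is_heavy]
  split(idx, atoms$residue[idx])
}

#' Minimum heavy-atom distance between two residues
#'
#' The residue-pair distance used throughout the eDDM analysis: the minimum
#' over all heavy-atom pairs of the Euclidean distance, symmetric in (i, j).
#'
#' @param conf a [conformation()].
#' @param i,j residue ordinals, `i != j`.
#' @return distance in Angstrom.
#' @export
min_residue_distance <- function(conf, i, j) {
  if (i == j) abort("`i` and `j` must differ")
  by_res <- residue_atom_index(conf)
  ai <- by_res[[as.character(i)]]
  aj <- by_res[[as.character(j)]]
  if (is.null(ai) || is.null(aj) || length(ai) == 0 || length(aj) == 0)
    abort("residue with zero heavy atoms")
  xi <- conf$xyz[ai, , drop = FALSE]
  xj <- conf$xyz[aj, , drop = FALSE]
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * tcrossprod(xi, xj)
  sqrt(max(min(d2), 0))
}

all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(i = idx[, "row"], j = idx[, "col"])
}

# per-frame n_res x n_res minimum heavy-atom distance matrix
frame_min_distance_matrix <- function(xyz, by_res) {
  heavy <- unlist(by_res, use.names = FALSE)
  sub <- xyz[heavy, , drop = FALSE]
  g <- rep(seq_along(by_res), lengths(by_res))
  dm <- as.matrix(dist(sub))
  nres <- length(by_res)
  rmin <- matrix(0, nres, ncol(dm))
  for (r in seq_len(nres))
    rmin[r, ] <- col_mins(dm[g == r, , drop = FALSE])
  out <- matrix(0, nres, nres)
  for (r in seq_len(nres))
    out[, r] <- col_mins(t(rmin[, g == r, drop = FALSE]))
  out
}

#' Per-frame residue-pair distances for an ensemble
#'
#' Builds the distance ensemble underlying the eDDM: one minimum heavy-atom
#' distance per (residue pair, conformation). `pairs = "all"` enumerates
#' every unordered pair `i < j`, sequence neighbours included.
#'
#' @param ensemble a [conf_ensemble()].
#' @param pairs `"all"` or a two-column data frame / tibble of residue
#'   ordinals (`i`, `j`).
#' @return an object of class `distance_ensemble`: list with `pairs`
#'   (tibble `i`, `j`, author labels), `d` (matrix `n_pairs x n_frames`,
#'   Angstrom), `state` and `n_conformations`.
#' @export
distance_tensor <- function(ensemble, pairs = "all") {
  nf <- n_frames(ensemble)
  if (nf == 0) abort("ensemble is empty")
  nres <- n_residues(ensemble)
  if (identical(pairs, "all")) {
    pr <- all_pairs(nres)
  } else {
    pr <- tibble::as_tibble(as.data.frame(pairs))
    names(pr)[1:2] <- c("i", "j")
    if (nrow(pr) == 0) abort("empty pair set")
    swap <- pr$i > pr$j
    tmp <- pr$i[swap]; pr$i[swap] <- pr$j[swap]; pr$j[swap] <- tmp
    if (any(pr$i == pr$j)) abort("pairs must have i != j")
    if (any(pr$j > nres)) abort("pair ordinal exceeds residue count")
    pr <- pr[!duplicated(pr[, c("i", "j")]), c("i", "j")]
  }
  by_res <- residue_atom_index(ensemble)
  if (length(by_res) != nres) abort("residue with zero heavy atoms")
  d <- matrix(NA_real_, nrow(pr), nf)
  ij <- cbind(pr$i, pr$j)
  for (f in seq_len(nf)) {
    dm <- frame_min_distance_matrix(ensemble$xyz[, , f], by_res)
    d[, f] <- dm[ij]
  }
  lab <- with(ensemble$residues, paste0(resname, resno))
  structure(
    list(
      pairs = tibble::tibble(
        i = pr$i, j = pr$j, label_i = lab[pr$i], label_j = lab[pr$j]
      ),
      d = d,
      state = unique(ensemble$frames$state)[1],
      n_conformations = nf
    ),
    class = "distance_ensemble"
  )
}

#' @export
print.distance_ensemble <- function(x, ...) {
  cat(sprintf(
    "<distance_ensemble> state '%s': %d pairs x %d conformations\n",
    x$state, nrow(x$pairs), x$n_conformations
  ))
  invisible(x)
}

#' Read / write a distance ensemble as TSV
#'
#' Long format: `pair_i`, `pair_j`, `frame`, `distance`.
#'
#' @param path TSV path.
#' @param state_label state label to attach on read.
#' @return `read_distance_tsv()` returns a `distance_ensemble`;
#'   `write_distance_tsv()` returns `path` invisibly.
#' @export
read_distance_tsv <- function(path, state_label = "state") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("pair_i", "pair_j", "frame", "distance")
  if (!all(need %in% names(tab)))
    abort(sprintf("distance TSV needs columns: %s", paste(need, collapse = ", ")))
  tab <- tab[order(tab$pair_i, tab$pair_j, tab$frame), ]
  key <- paste(tab$pair_i, tab$pair_j)
  pr <- tab[!duplicated(key), c("pair_i", "pair_j")]
  nf <- length(unique(tab$frame))
  distance_ensemble(
    pairs = tibble::tibble(i = pr$pair_i, j = pr$pair_j),
    d = matrix(tab$distance, nrow = nrow(pr), ncol = nf, byrow = TRUE),
    state = state_label
  )
}

#' @rdname read_distance_tsv
#' @param x a `distance_ensemble`.
#' @export
write_distance_tsv <- function(x, path) {
  nf <- ncol(x$d)
  tab <- tibble::tibble(
    pair_i = rep(x$pairs$i, each = nf),
    pair_j = rep(x$pairs$j, each = nf),
    frame = rep(seq_len(nf), nrow(x$pairs)),
    distance = as.vector(t(x$d))
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Build a distance ensemble from raw parts
#'
#' @param pairs tibble with residue ordinals `i`, `j` (and optionally
#'   `label_i`, `label_j`).
#' @param d numeric matrix, `n_pairs x n_frames`, distances in Angstrom.
#' @param state state label.
#' @return a `distance_ensemble`.
#' @export
distance_ensemble <- function(pairs, d, state = "state") {
  pairs <- tibble::as_tibble(pairs)
  d <- as.matrix(d)
  if (nrow(pairs) != nrow(d)) abort("one distance row per pair required")
  if (any(d < 0)) abort("distances must be >= 0")
  if (!"label_i" %in% names(pairs)) pairs$label_i <- paste0("R", pairs$i)
  if (!"label_j" %in% names(pairs)) pairs$label_j <- paste0("R", pairs$j)
  structure(
    list(pairs = pairs, d = d, state = state, n_conformations = ncol(d)),
    class = "distance_ensemble"
  )
}

#' Compare two conformational states with a masked eDDM
#'
#' For every residue pair, distances in both states are masked with
#' [mask_distance()], the masked samples are compared with a two-sided
#' two-sample Wilcoxon rank-sum test (frames treated as independent,
#' unpaired observations), and the masked difference is the difference of
#' per-state masked means (state B minus state A). A pair is flagged
#' significant when `p < alpha` and `|masked difference| > min_diff`;
#' by default no multiple-testing correction is applied (set
#' `p_adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param state_a,state_b `distance_ensemble` objects over the identical
#'   pair set, each with at least 2 conformations.
#' @param c1,c2 mask break points (Angstrom), see [mask_distance()].
#' @param alpha significance level (default 0.05).
#' @param min_diff minimum absolute masked difference (Angstrom, default 1).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return a tibble of class `eddm_tbl`, one row per pair: residue ordinals
#'   and labels, per-state masked and raw mean distances, `masked_diff`
#'   (B - A), `p_value`, `significant`, and `closer_in` (`"A"`, `"B"` or
#'   `"none"`); significant pairs sorted first by `|masked_diff|` descending.
#' @export
eddm_compare <- function(state_a, state_b, c1 = 4, c2 = 8,
                         alpha = 0.05, min_diff = 1,
                         p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1)")
  if (min_diff < 0) abort("`min_diff` must be >= 0")
  if (!identical(state_a$pairs[, c("i", "j")], state_b$pairs[, c("i", "j")]))
    abort("the two states must share an identical pair set")
  if (ncol(state_a$d) < 2 || ncol(state_b$d) < 2)
    abort("each state needs at least 2 conformations")
  ma <- mask_distance(state_a$d, c1, c2)
  mb <- mask_distance(state_b$d, c1, c2)
  dim(ma) <- dim(state_a$d); dim(mb) <- dim(state_b$d)
  np <- nrow(state_a$pairs)
  p_value <- vapply(seq_len(np), function(k) {
    # fully tied samples (e.g. both states saturated at the mask cap) carry
    # no evidence of a difference; the rank test is undefined there
    if (length(unique(c(ma[k, ], mb[k, ]))) == 1L) return(1)
    suppressWarnings(
      wilcox.test(ma[k, ], mb[k, ], alternative = "two.sided", exact = FALSE)$p.value
    )
  }, numeric(1))
  if (p_adjust == "BH") p_value <- stats::p.adjust(p_value, method = "BH")
  mean_masked_a <- rowMeans(ma)
  mean_masked_b <- rowMeans(mb)
  masked_diff <- mean_masked_b - mean_masked_a
  significant <- (p_value < alpha) & (abs(masked_diff) > min_diff)
  out <- tibble::tibble(
    res_i = state_a$pairs$i,
    res_j = state_a$pairs$j,
    label_i = state_a$pairs$label_i,
    label_j = state_a$pairs$label_j,
    mean_masked_A = mean_masked_a,
    mean_masked_B = mean_masked_b,
    masked_diff = masked_diff,
    mean_raw_A = rowMeans(state_a$d),
    mean_raw_B = rowMeans(state_b$d),
    p_value = p_value,
    significant = significant,
    closer_in = ifelse(
      !significant, "none", ifelse(masked_diff > 0, "A", "B")
    )
  )
  out <- out[order(!out$significant, -abs(out$masked_diff)), ]
  attr(out, "mask") <- c(c1 = c1, c2 = c2)
  attr(out, "thresholds") <- c(alpha = alpha, min_diff = min_diff)
  class(out) <- c("eddm_tbl", class(out))
  out
}

#' Signed contact-change matrix from an eDDM table
#'
#' Dense square matrix with the signed masked difference at significant
#' pairs and 0 elsewhere; cells (i, j) and (j, i) carry the same value, so
#' the map can be drawn with secondary-structure elements along both axes.
#'
#' @param table an `eddm_tbl` from [eddm_compare()].
#' @param n_residues matrix dimension; all pair ordinals must fit.
#' @return `n_residues x n_residues` numeric matrix.
#' @export
contact_map_matrix <- function(table, n_residues) {
  if (any(table$res_i > n_residues | table$res_j > n_residues))
    abort("pair ordinal exceeds `n_residues`")
  m <- matrix(0, n_residues, n_residues)
  sig <- table[table$significant, ]
  m[cbind(sig$res_i, sig$res_j)] <- sig$masked_diff
  m[cbind(sig$res_j, sig$res_i)] <- sig$masked_diff
  m
}

#' @export
autoplot.eddm_tbl <- function(object, ...) {
  nres <- max(object$res_j)
  m <- contact_map_matrix(object, nres)
  df <- tidyr::expand_grid(i = seq_len(nres), j = seq_len(nres))
  df$diff <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "white", high = "#2166ac", midpoint = 0,
      name = "masked Δd (Å)"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "residue", y = "residue",
      title = "Significant residue-pair distance changes (B - A)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
tidy.eddm_tbl <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.eddm_tbl <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_pairs = nrow(x),
    n_significant = sum(x$significant),
    alpha = th[["alpha"]],
    min_diff = th[["min_diff"]]
  )
}
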
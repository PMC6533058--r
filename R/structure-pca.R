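# Invariant-core superposition and C-alpha principal component analysis of
# conformational ensembles, with projection onto the resulting map.

# one marker atom per residue: the CA atom when named, else the first heavy
# atom (toy chains name their first atom CA, so both routes coincide there)
marker_atoms <- function(x, residues = NULL) {
  residues <- residues %||% x$residues$residue
  vapply(residues, function(r) {
    idx <- which(x$atoms$residue == r)
    if (length(idx) == 0) abort(sprintf("residue %d not present", r))
    ca <- idx[x$atoms$name[idx] == "CA"]
    if (length(ca) > 0) return(ca[1])
    hv <- idx[x$atoms$is_heavy[idx]]
    hv[1]
  }, integer(1))
}

# optimal rigid superposition (Kabsch): rotation R (det = +1) and translation
# mapping moving -> target, both n x 3
kabsch <- function(moving, target) {
  cm <- colMeans(moving); ct <- colMeans(target)
  p <- sweep(moving, 2, cm); q <- sweep(target, 2, ct)
  s <- svd(crossprod(p, q))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, center_moving = cm, center_target = ct)
}

apply_rigid <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_moving) %*% fit$rotation, 2, fit$center_target, `+`)
}

#' Superpose every frame of an ensemble onto an invariant core
#'
#' Each conformation is rigidly transformed (rotation with determinant +1
#' plus translation, never a reflection) to minimize the C-alpha RMSD of the
#' core residues to the reference. The core should be a set of structurally
#' stable secondary-structure elements (for kinesin motor domains:
#' beta1, beta2, beta3, P-loop, alpha2, beta6, beta7, alpha6), supplied as
#' residue ordinals since exact ranges depend on the structure set.
#'
#' @param ensemble a [conf_ensemble()].
#' @param core integer residue ordinals forming the superposition core
#'   (at least 3, non-collinear).
#' @param reference a [conformation()]; defaults to the first frame.
#' @return the superposed [conf_ensemble()].
#' @export
superpose_on_core <- function(ensemble, core, reference = NULL) {
  reference <- reference %||% get_conformation(ensemble, 1)
  if (length(core) < 3) abort("core needs at least 3 residues")
  ref_idx <- marker_atoms(reference, core)
  ens_idx <- marker_atoms(ensemble, core)
  q <- reference$xyz[ref_idx, , drop = FALSE]
  qc <- sweep(q, 2, colMeans(q))
  if (qr(qc)$rank < 2) abort("core residues are collinear (degenerate)")
  out <- ensemble
  for (f in seq_len(n_frames(ensemble))) {
    fit <- kabsch(ensemble$xyz[ens_idx, , f], q)
    out$xyz[, , f] <- apply_rigid(ensemble$xyz[, , f], fit)
  }
  out
}

#' Core C-alpha RMSD of each frame to a reference
#' @inheritParams superpose_on_core
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
core_rmsd <- function(ensemble, core, reference = NULL) {
  reference <- reference %||% get_conformation(ensemble, 1)
  ref_idx <- marker_atoms(reference, core)
  ens_idx <- marker_atoms(ensemble, core)
  q <- reference$xyz[ref_idx, , drop = FALSE]
  vapply(seq_len(n_frames(ensemble)), function(f) {
    sqrt(mean(rowSums((ensemble$xyz[ens_idx, , f] - q)^2)))
  }, numeric(1))
}

ca_matrix <- function(ensemble, selection) {
  idx <- marker_atoms(ensemble, selection)
  t(vapply(
    seq_len(n_frames(ensemble)),
    function(f) as.vector(t(ensemble$xyz[idx, , f])),
    numeric(3 * length(idx))
  ))
}

#' Principal component analysis of C-alpha coordinates
#'
#' Builds the 3N x 3N covariance matrix of the selected C-alpha coordinates
#' over a superposed ensemble, `C_ij = <(r_i - <r_i>)(r_j - <r_j>)>`, with
#' the ensemble-average normalization (divide by n, not n - 1), and
#' diagonalizes it. Eigenvectors are the principal components; eigenvalues
#' are the variances (Angstrom^2) along them, sorted descending. Each
#' eigenvector's sign is fixed so its largest-magnitude coordinate is
#' positive.
#'
#' @param ensemble a superposed [conf_ensemble()] with >= 2 frames.
#' @param selection residue ordinals of the equivalent, non-gap positions to
#'   analyze (default: all residues).
#' @return an object of class `kinlink_pca`: `mean_coords` (length 3N),
#'   `vectors` (3N x 3N orthonormal), `values` (variances), `fraction`
#'   (per-component variance fractions), `selection`, `n`.
#' @export
fit_pca <- function(ensemble, selection = NULL) {
  selection <- selection %||% ensemble$residues$residue
  nf <- n_frames(ensemble)
  if (nf < 2) abort("PCA needs at least 2 conformations")
  x <- ca_matrix(ensemble, selection)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / nf
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (k in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(
    list(
      mean_coords = mu,
      vectors = vecs,
      values = vals,
      fraction = if (sum(vals) > 0) vals / sum(vals) else vals,
      selection = selection,
      n = nf
    ),
    class = "kinlink_pca"
  )
}

#' @export
print.kinlink_pca <- function(x, ...) {
  cat(sprintf(
    "<kinlink_pca> %d positions, %d conformations; PC1 %.2f%%, PC2 %.2f%%\n",
    length(x$selection), x$n,
    100 * x$fraction[1], 100 * (x$fraction[2] %||% NA)
  ))
  invisible(x)
}

#' Project conformations onto a fitted PC sub-space
#'
#' Scores are `(coords - mean_coords) . eigenvector` for the requested
#' components; the ensemble must already be superposed onto the same
#' reference/core as the fitting set.
#'
#' @param model a [fit_pca()] model.
#' @param ensemble a superposed [conf_ensemble()].
#' @param selection residue ordinals matching the model's selection length
#'   (default: the model's own selection).
#' @param n_components number of leading PCs to report (default 2).
#' @return a tibble: `id` (state/frame label), one `PC<k>` column per
#'   component (Angstrom).
#' @export
project_ensemble <- function(model, ensemble, selection = NULL,
                             n_components = 2L) {
  selection <- selection %||% model$selection
  if (3 * length(selection) != length(model$mean_coords))
    abort("selection length does not match the fitted model")
  x <- ca_matrix(ensemble, selection)
  pcs <- seq_len(min(n_components, ncol(model$vectors)))
  sc <- sweep(x, 2, model$mean_coords) %*% model$vectors[, pcs, drop = FALSE]
  out <- tibble::tibble(
    id = paste0(ensemble$frames$state, "/", ensemble$frames$frame)
  )
  for (k in pcs) out[[paste0("PC", k)]] <- sc[, k]
  out
}

#' Variance accounted for by the leading principal components
#'
#' @param model a [fit_pca()] model.
#' @param k number of components to report.
#' @return tibble: `pc`, `eigenvalue` (Angstrom^2), `pct`, `cum_pct`.
#' @export
variance_report <- function(model, k = 2L) {
  if (k < 1) abort("`k` must be >= 1")
  k <- min(k, length(model$values))
  pct <- 100 * model$fraction
  tibble::tibble(
    pc = seq_len(k),
    eigenvalue = model$values[seq_len(k)],
    pct = pct[seq_len(k)],
    cum_pct = cumsum(pct)[seq_len(k)]
  )
}

#' 2-D density (topographic map) of PC scores
#'
#' Normalized 2-D histogram of two PC score columns (mass sums to 1), with
#' optional Gaussian smoothing, suitable for contouring conformational
#' sub-spaces sampled by different simulations.
#'
#' @param projection a [project_ensemble()] tibble.
#' @param pcs names of the two score columns (default `PC1`, `PC2`).
#' @param n_bins bins per axis (default 40).
#' @param limits optional list of `x` and `y` range vectors; default data
#'   range padded by one bin.
#' @param smooth_bw optional Gaussian kernel sd in score units; `NULL`
#'   (default) leaves the raw histogram.
#' @return tibble of class `pc_density`: `x`, `y` (bin centers), `density`.
#' @export
density_map <- function(projection, pcs = c("PC1", "PC2"), n_bins = 40L,
                        limits = NULL, smooth_bw = NULL) {
  if (nrow(projection) == 0) abort("empty projection")
  if (!all(pcs %in% names(projection))) abort("score columns not found")
  px <- projection[[pcs[1]]]; py <- projection[[pcs[2]]]
  pad <- function(r) {
    if (diff(r) == 0) r + c(-0.5, 0.5) else r + diff(r) / n_bins * c(-1, 1)
  }
  limits <- limits %||% list(x = pad(range(px)), y = pad(range(py)))
  bx <- seq(limits$x[1], limits$x[2], length.out = n_bins + 1L)
  by <- seq(limits$y[1], limits$y[2], length.out = n_bins + 1L)
  ix <- pmin(pmax(findInterval(px, bx, rightmost.closed = TRUE), 1L), n_bins)
  iy <- pmin(pmax(findInterval(py, by, rightmost.closed = TRUE), 1L), n_bins)
  h <- matrix(0, n_bins, n_bins)
  for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
  h <- h / sum(h)
  if (!is.null(smooth_bw) && smooth_bw > 0) {
    wx <- diff(bx)[1]; wy <- diff(by)[1]
    kx <- stats::dnorm(seq(-3 * smooth_bw, 3 * smooth_bw, by = wx), sd = smooth_bw)
    ky <- stats::dnorm(seq(-3 * smooth_bw, 3 * smooth_bw, by = wy), sd = smooth_bw)
    smooth1 <- function(m, kern, along_rows) {
      if (length(kern) < 2) return(m)
      kern <- kern / sum(kern)
      if (along_rows) m <- t(m)
      out <- apply(m, 2, function(v) {
        stats::filter(c(rep(0, length(kern)), v, rep(0, length(kern))),
                      kern, sides = 2)[length(kern) + seq_along(v)]
      })
      if (along_rows) t(out) else out
    }
    h <- smooth1(smooth1(h, kx, TRUE), ky, FALSE)
    h[is.na(h)] <- 0
    h <- h / sum(h)
  }
  out <- tidyr::expand_grid(
    x = (bx[-1] + bx[-length(bx)]) / 2,
    y = (by[-1] + by[-length(by)]) / 2
  )
  out$density <- as.vector(t(h))
  class(out) <- c("pc_density", class(out))
  out
}

#' @export
autoplot.pc_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y, z = .data$density)) +
    ggplot2::geom_contour(colour = "#2166ac") +
    ggplot2::labs(x = "PC1 (Å)", y = "PC2 (Å)",
                  title = "Conformational map") +
    ggplot2::theme_minimal()
}

#' @export
tidy.kinlink_pca <- function(x, ...) {
  variance_report(x, k = length(x$values))
}

#' @export
glance.kinlink_pca <- function(x, ...) {
  tibble::tibble(
    n_positions = length(x$selection),
    n_conformations = x$n,
    total_variance = sum(x$values),
    pc1_pct = 100 * x$fraction[1],
    pc2_pct = if (length(x$fraction) > 1) 100 * x$fraction[2] else NA_real_
  )
}
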
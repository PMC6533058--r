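# Seeded synthetic-data generators with recorded ground truth. Each
# generator is a pure function of its spec: the same spec (seed included)
# returns identical output, and a truth table records every generating
# parameter so recovery tests can score the pipeline against known answers.

new_ensemble <- function(xyz, atoms, residues, frames) {
  structure(
    list(xyz = xyz, atoms = atoms, residues = residues,
         frames = tibble::as_tibble(frames)),
    class = "conf_ensemble"
  )
}

#' A toy chain conformation
#'
#' Residues are laid out on a coarse helix with `atoms_per_residue` atoms
#' jittered around each residue center (first atom named CA at the center).
#' Geometric realism is irrelevant to the statistics the generators feed;
#' the chain only provides a valid topology with heavy atoms.
#'
#' @param n_residues number of residues.
#' @param atoms_per_residue atoms per residue (>= 1).
#' @param seed RNG seed for the fixed atom jitter.
#' @return a [conformation()].
#' @export
toy_conformation <- function(n_residues = 20L, atoms_per_residue = 4L,
                             seed = 1L) {
  if (n_residues < 2) abort("need at least 2 residues")
  if (atoms_per_residue < 1) abort("need at least 1 atom per residue")
  with_local_seed(seed, {
    k <- seq_len(n_residues)
    centers <- cbind(6 * cos(0.6 * k), 6 * sin(0.6 * k), 1.5 * k)
    elements <- rep(c("C", "N", "O", "C"), length.out = atoms_per_residue)
    xyz <- matrix(0, n_residues * atoms_per_residue, 3)
    res_of_atom <- rep(k, each = atoms_per_residue)
    names_of_atom <- rep(
      c("CA", paste0("X", seq_len(max(atoms_per_residue - 1L, 0L))))[
        seq_len(atoms_per_residue)], n_residues)
    for (r in k) {
      rows <- which(res_of_atom == r)
      off <- rbind(
        c(0, 0, 0),
        if (atoms_per_residue > 1)
          matrix(rnorm(3 * (atoms_per_residue - 1L), sd = 0.5), ncol = 3)
      )
      xyz[rows, ] <- sweep(off, 2, centers[r, ], `+`)
    }
    conformation(
      xyz,
      tibble::tibble(
        residue = res_of_atom, name = names_of_atom,
        element = rep(elements, n_residues)
      ),
      tibble::tibble(
        residue = k, resno = k, resname = "ALA", chain = "A"
      )
    )
  })
}

#' Specification for a pair of two-state toy ensembles
#'
#' Stand-in for replicated MD ensembles of two conformational states: a
#' shared toy chain, per-frame rigid Gaussian displacement of each residue
#' (noise), and a set of residue pairs whose separation differs between the
#' states (the injected contact changes the eDDM should recover).
#'
#' @param n_residues,atoms_per_residue toy chain size.
#' @param n_replicates replicates per state (default 4).
#' @param frames_per_replicate frames per replicate (default 100, so the
#'   pooled per-state ensemble holds 400 conformations).
#' @param noise_sd per-axis sd of each residue's rigid per-frame
#'   displacement (Angstrom); the realized pair-distance sd is about
#'   `sqrt(2) * noise_sd`.
#' @param shifted_pairs tibble with columns `i`, `j`, `dist_a`, `dist_b`
#'   (Angstrom): residue pairs placed at separation `dist_a` in state A and
#'   `dist_b` in state B. A residue may appear in at most one shifted pair
#'   (conflicting distance constraints are rejected).
#' @param seed root seed; fixes all randomness.
#' @return a `two_state_spec` list.
#' @export
two_state_spec <- function(n_residues = 20L, atoms_per_residue = 4L,
                           n_replicates = 4L, frames_per_replicate = 100L,
                           noise_sd = 0.3,
                           shifted_pairs = NULL, seed = 1L) {
  shifted_pairs <- shifted_pairs %||%
    tibble::tibble(i = integer(), j = integer(),
                   dist_a = numeric(), dist_b = numeric())
  shifted_pairs <- tibble::as_tibble(shifted_pairs)
  if (nrow(shifted_pairs) > 0) {
    if (any(shifted_pairs$dist_a <= 0) || any(shifted_pairs$dist_b <= 0))
      abort("shifted-pair distances must be > 0")
    ids <- c(shifted_pairs$i, shifted_pairs$j)
    if (anyDuplicated(ids))
      abort("a residue appears in more than one shifted pair: constraints may conflict")
    if (any(ids > n_residues)) abort("shifted pair ordinal exceeds n_residues")
  }
  stop_if_not_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  structure(
    list(
      n_residues = n_residues, atoms_per_residue = atoms_per_residue,
      n_replicates = n_replicates,
      frames_per_replicate = frames_per_replicate,
      noise_sd = noise_sd, shifted_pairs = shifted_pairs, seed = seed
    ),
    class = "two_state_spec"
  )
}

build_state_xyz <- function(spec, base, dist_col, seed) {
  nres <- spec$n_residues
  apr <- spec$atoms_per_residue
  xyz0 <- base$xyz
  sp <- spec$shifted_pairs
  if (nrow(sp) > 0) {
    # each shifted pair lives in its own remote site, far from the chain and
    # from other pairs, so only the injected distance is perturbed
    for (m in seq_len(nrow(sp))) {
      anchor <- c(150 + 60 * (m - 1), 150, 0)
      rows_i <- which(base$atoms$residue == sp$i[m])
      rows_j <- which(base$atoms$residue == sp$j[m])
      xyz0[rows_i, ] <- matrix(anchor, length(rows_i), 3, byrow = TRUE)
      xyz0[rows_j, ] <- matrix(anchor + c(sp[[dist_col]][m], 0, 0),
                               length(rows_j), 3, byrow = TRUE)
    }
  }
  nf <- spec$n_replicates * spec$frames_per_replicate
  xyz <- array(0, dim = c(nrow(xyz0), 3L, nf))
  res_of_atom <- base$atoms$residue
  with_local_seed(seed, {
    for (f in seq_len(nf)) {
      disp <- matrix(rnorm(3 * nres, sd = spec$noise_sd), nres, 3)
      xyz[, , f] <- xyz0 + disp[res_of_atom, , drop = FALSE]
    }
  })
  xyz
}

#' Generate two replicated toy ensembles with injected contact changes
#'
#' @param spec a [two_state_spec()].
#' @return list with `state_a`, `state_b` ([conf_ensemble()]s, replicate
#'   labels and frame times attached) and `truth` (the shifted-pair table:
#'   `i`, `j`, `dist_a`, `dist_b`).
#' @export
make_two_state_ensembles <- function(spec) {
  if (!inherits(spec, "two_state_spec")) abort("`spec` must be a two_state_spec")
  base <- toy_conformation(spec$n_residues, spec$atoms_per_residue,
                           seed = child_seed(spec$seed, 0L))
  nf <- spec$n_replicates * spec$frames_per_replicate
  frames <- tibble::tibble(
    frame = seq_len(nf),
    replicate = rep(seq_len(spec$n_replicates),
                    each = spec$frames_per_replicate),
    time_ns = rep(seq_len(spec$frames_per_replicate) * 0.2,
                  spec$n_replicates)
  )
  mk <- function(dist_col, state, counter) {
    xyz <- build_state_xyz(spec, base, dist_col, child_seed(spec$seed, counter))
    new_ensemble(xyz, base$atoms, base$residues,
                 cbind(frames[, "frame"], state = state,
                       frames[, c("replicate", "time_ns")]))
  }
  list(
    state_a = mk("dist_a", "A", 1L),
    state_b = mk("dist_b", "B", 2L),
    truth = spec$shifted_pairs
  )
}

#' Generate an ensemble with known principal modes
#'
#' Frames are `base + sum_k a_k v_k + noise`, with `a_k ~ N(0, sd_k^2)` and
#' isotropic coordinate noise, so the fitted PCA spectrum can be scored
#' against the injected variances. Modes are orthonormalized (with a warning
#' if they were not orthonormal already).
#'
#' @param base a [conformation()] providing geometry and topology.
#' @param modes matrix with `3 * n_atoms(base)` rows, one column per mode.
#' @param amplitude_sd per-mode amplitude sd (Angstrom), one per column.
#' @param noise_sd isotropic per-coordinate noise sd (Angstrom, default 0).
#' @param n number of frames.
#' @param seed RNG seed.
#' @return list with `ensemble` (a [conf_ensemble()]) and `truth`
#'   (tibble: mode, amplitude_sd, variance).
#' @export
make_mode_ensemble <- function(base, modes, amplitude_sd, noise_sd = 0,
                               n = 200L, seed = 1L) {
  modes <- as.matrix(modes)
  d <- 3L * nrow(base$xyz)
  if (nrow(modes) != d) abort("modes must have 3 * n_atoms rows")
  if (length(amplitude_sd) != ncol(modes))
    abort("one amplitude sd per mode required")
  gram <- crossprod(modes)
  if (max(abs(gram - diag(ncol(modes)))) > 1e-8) {
    warn("modes were not orthonormal; auto-orthonormalizing (QR)")
    modes <- qr.Q(qr(modes))
  }
  base_vec <- as.vector(t(base$xyz))
  xyz <- array(0, dim = c(nrow(base$xyz), 3L, n))
  amps <- with_local_seed(seed, {
    amps <- matrix(rnorm(n * ncol(modes)), n) %*% diag(amplitude_sd, ncol(modes))
    for (f in seq_len(n)) {
      v <- base_vec + as.vector(modes %*% amps[f, ])
      if (noise_sd > 0) v <- v + rnorm(d, sd = noise_sd)
      xyz[, , f] <- matrix(v, ncol = 3, byrow = TRUE)
    }
    amps
  })
  frames <- tibble::tibble(
    frame = seq_len(n), state = "synthetic", replicate = 1L,
    time_ns = as.numeric(seq_len(n))
  )
  # variance_realized is the ensemble-normalized (divide by n) variance of
  # the amplitudes actually drawn: the spectrum injected into *these* frames
  list(
    ensemble = new_ensemble(xyz, base$atoms, base$residues, frames),
    truth = tibble::tibble(
      mode = seq_along(amplitude_sd),
      amplitude_sd = amplitude_sd,
      variance = amplitude_sd^2,
      variance_realized =
        colMeans(sweep(amps, 2, colMeans(amps))^2)
    )
  )
}

#' Specification for simulated single-molecule motility events
#'
#' Defaults emulate a wild-type kinesin-1 population under standard TIRF
#' assay conditions: Gaussian velocities around 0.617 um/s, exponential run
#' lengths with mean 0.99 um, about 250 scored events, and no pauses.
#'
#' @param n_events number of events.
#' @param velocity_mean,velocity_sd Gaussian velocity parameters (um/s).
#' @param runlength_family `"exponential"` or `"gamma"`.
#' @param runlength_mean exponential mean run length (um).
#' @param gamma_shape,gamma_scale gamma run-length parameters (scale in um).
#' @param pause_prob probability an event contains a gap.
#' @param pause_duration_s gap duration (s).
#' @param pause_fraction fraction of the gap spent stationary (1 = fully
#'   paused; the rest of the gap moves at the event velocity).
#' @param frame_s camera frame interval (s, default 0.1).
#' @param mt_length_um,concentration_nM,time_s landing-assay context.
#' @param seed root seed.
#' @return a `motility_sim_spec` list.
#' @export
motility_sim_spec <- function(n_events = 250L,
                              velocity_mean = 0.617, velocity_sd = 0.08,
                              runlength_family = c("exponential", "gamma"),
                              runlength_mean = 0.99,
                              gamma_shape = 2, gamma_scale = 1,
                              pause_prob = 0, pause_duration_s = 1,
                              pause_fraction = 1,
                              frame_s = 0.1,
                              mt_length_um = 500, concentration_nM = 0.25,
                              time_s = 300, seed = 1L) {
  runlength_family <- match.arg(runlength_family)
  for (nm in c("velocity_mean", "velocity_sd", "runlength_mean",
               "gamma_shape", "gamma_scale", "frame_s", "mt_length_um",
               "concentration_nM", "time_s"))
    stop_if_not_scalar_number(get(nm), nm, positive = TRUE)
  if (pause_prob < 0 || pause_prob > 1) abort("`pause_prob` must be in [0, 1]")
  if (pause_fraction < 0 || pause_fraction > 1)
    abort("`pause_fraction` must be in [0, 1]")
  structure(
    list(
      n_events = n_events, velocity_mean = velocity_mean,
      velocity_sd = velocity_sd, runlength_family = runlength_family,
      runlength_mean = runlength_mean, gamma_shape = gamma_shape,
      gamma_scale = gamma_scale, pause_prob = pause_prob,
      pause_duration_s = pause_duration_s, pause_fraction = pause_fraction,
      frame_s = frame_s, mt_length_um = mt_length_um,
      concentration_nM = concentration_nM, time_s = time_s, seed = seed
    ),
    class = "motility_sim_spec"
  )
}

#' Simulate a motility event table with known ground truth
#'
#' @param spec a [motility_sim_spec()].
#' @param construct construct label attached to every event.
#' @return list with `events` (tibble: event_id, construct,
#'   duration_frames, duration_s, run_length_um, velocity_um_s,
#'   ended_at_mt_end, gaps list-column) and `truth` (tibble of all
#'   generating parameters plus the implied landing rate).
#' @export
simulate_motility_events <- function(spec, construct = "WT") {
  if (!inherits(spec, "motility_sim_spec"))
    abort("`spec` must be a motility_sim_spec")
  n <- spec$n_events
  with_local_seed(child_seed(spec$seed, 3L), {
    v <- pmax(rnorm(n, spec$velocity_mean, spec$velocity_sd), 1e-3)
    rl <- if (spec$runlength_family == "exponential")
      rexp(n, rate = 1 / spec$runlength_mean)
    else
      rgamma(n, shape = spec$gamma_shape, scale = spec$gamma_scale)
    rl <- pmax(rl, 1e-3)
    dur_s <- rl / v
    has_gap <- runif(n) < spec$pause_prob
    gaps <- purrr::map(seq_len(n), function(k) {
      if (!has_gap[k]) return(tibble::tibble(
        gap_duration_s = numeric(), gap_displacement_um = numeric()
      ))
      tibble::tibble(
        gap_duration_s = spec$pause_duration_s,
        gap_displacement_um =
          (1 - spec$pause_fraction) * v[k] * spec$pause_duration_s
      )
    })
    ended <- runif(n) < 0.05
    events <- tibble::tibble(
      event_id = seq_len(n),
      construct = construct,
      duration_frames = pmax(1L, as.integer(round(dur_s / spec$frame_s))),
      duration_s = dur_s,
      run_length_um = rl,
      velocity_um_s = v,
      ended_at_mt_end = ended,
      gaps = gaps
    )
    truth <- tibble::tibble(
      construct = construct,
      n_events = n,
      velocity_mean = spec$velocity_mean,
      velocity_sd = spec$velocity_sd,
      runlength_family = spec$runlength_family,
      runlength_mean = if (spec$runlength_family == "exponential")
        spec$runlength_mean else spec$gamma_shape * spec$gamma_scale,
      gamma_shape = spec$gamma_shape,
      gamma_scale = spec$gamma_scale,
      pause_prob = spec$pause_prob,
      pause_fraction = spec$pause_fraction,
      landing_rate = n /
        (spec$mt_length_um * spec$concentration_nM * spec$time_s)
    )
    list(events = events, truth = truth)
  })
}

#' Specification for a synthetic cell image
#'
#' Photons are placed by sampling a normalized radius from Beta(alpha, beta)
#' and a uniform angle inside a disk-shaped cell mask; optional Poisson
#' background is added per pixel. Beta(2, 8) gives perinuclear-clustered
#' cargo, Beta(8, 2) peripherally dispersed cargo, Beta(1, 1) cargo uniform
#' over radius (which is *not* uniform over area).
#'
#' @param image_size image side in pixels (square).
#' @param pixel_size_um pixel size (um/pixel).
#' @param cell_radius_px cell-mask radius in pixels (must fit inside).
#' @param beta_shape1,beta_shape2 Beta parameters of the radial density.
#' @param n_photons total photons placed.
#' @param background mean Poisson background per pixel (default 0).
#' @param seed root seed.
#' @return a `cell_sim_spec` list.
#' @export
cell_sim_spec <- function(image_size = 121L, pixel_size_um = 0.1,
                          cell_radius_px = 50,
                          beta_shape1 = 2, beta_shape2 = 8,
                          n_photons = 1e5, background = 0, seed = 1L) {
  if (2 * cell_radius_px + 1 > image_size)
    abort("cell radius does not fit in the image")
  stop_if_not_scalar_number(n_photons, "n_photons", positive = TRUE)
  if (background < 0) abort("`background` must be >= 0")
  structure(
    list(
      image_size = as.integer(image_size), pixel_size_um = pixel_size_um,
      cell_radius_px = cell_radius_px, beta_shape1 = beta_shape1,
      beta_shape2 = beta_shape2, n_photons = n_photons,
      background = background, seed = seed
    ),
    class = "cell_sim_spec"
  )
}

#' Simulate a cell image with a parameterized radial cargo distribution
#'
#' @param spec a [cell_sim_spec()].
#' @param cell_id,condition identifiers for the resulting [cell_image()].
#' @return list with `image` (a [cell_image()]) and `truth`
#'   (tibble: beta_shape1, beta_shape2, n_photons, background).
#' @export
simulate_cell_image <- function(spec, cell_id = "cell", condition = "sim") {
  if (!inherits(spec, "cell_sim_spec")) abort("`spec` must be a cell_sim_spec")
  n <- spec$image_size
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  mask <- (rows - ctr)^2 + (cols - ctr)^2 <= spec$cell_radius_px^2
  img <- matrix(0, n, n)
  with_local_seed(child_seed(spec$seed, 4L), {
    u <- rbeta(spec$n_photons, spec$beta_shape1, spec$beta_shape2)
    ang <- runif(spec$n_photons, 0, 2 * pi)
    pr <- pmin(pmax(round(ctr + u * spec$cell_radius_px * cos(ang)), 1L), n)
    pc <- pmin(pmax(round(ctr + u * spec$cell_radius_px * sin(ang)), 1L), n)
    keep <- mask[cbind(pr, pc)]
    counts <- tabulate((pr[keep] - 1L) * n + pc[keep], nbins = n * n)
    img <- matrix(counts, n, n, byrow = TRUE)
    if (spec$background > 0)
      img <- img + matrix(rpois(n * n, spec$background), n, n)
  })
  list(
    image = cell_image(
      img, mask, center = c(ctr, ctr),
      pixel_size_um = spec$pixel_size_um,
      cell_id = cell_id, condition = condition
    ),
    truth = tibble::tibble(
      beta_shape1 = spec$beta_shape1, beta_shape2 = spec$beta_shape2,
      n_photons = spec$n_photons, background = spec$background
    )
  )
}

#' Write a ground-truth table alongside generated data
#' @param truth a truth tibble from any generator.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}
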
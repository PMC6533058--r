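# Conformations and conformational ensembles: containers, PDB/TSV input,
# frame subsampling, summaries.

KNOWN_ELEMENTS <- c(
  "H", "D", "C", "N", "O", "S", "P", "SE", "F", "CL", "BR", "I",
  "NA", "K", "MG", "CA", "MN", "FE", "ZN", "CU", "NI", "CO", "MO", "W"
)

#' Construct a single conformation
#'
#' A conformation bundles atomic coordinates with a residue topology: each
#' atom maps to a residue ordinal, carries an element symbol and a heavy-atom
#' flag (element != hydrogen), and each residue keeps its author label
#' (chain, residue number, insertion code) alongside the 0-free internal
#' ordinal used by all downstream pair indices.
#'
#' @param xyz numeric matrix, `n_atoms x 3`, coordinates in Angstrom.
#' @param atoms tibble with columns `residue` (1-based residue ordinal),
#'   `name` (atom name), `element` (symbol). `is_heavy` is derived.
#' @param residues tibble with columns `residue` (ordinal), `resno`
#'   (author number), `resname`, `chain`. Optional `insert`.
#' @return an object of class `conformation`.
#' @export
conformation <- function(xyz, atoms, residues) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) abort("`xyz` must have 3 columns (x, y, z)")
  if (!all(is.finite(xyz))) abort("coordinates must be finite")
  atoms <- tibble::as_tibble(atoms)
  residues <- tibble::as_tibble(residues)
  if (nrow(atoms) != nrow(xyz)) abort("one atom row per coordinate row required")
  if (!all(c("residue", "element") %in% names(atoms)))
    abort("`atoms` needs columns `residue` and `element`")
  if (!"name" %in% names(atoms)) atoms$name <- atoms$element
  if (!"insert" %in% names(residues)) residues$insert <- ""
  atoms$element <- toupper(atoms$element)
  bad <- setdiff(unique(atoms$element), KNOWN_ELEMENTS)
  if (length(bad) > 0)
    abort(sprintf("unknown element symbol(s): %s", paste(bad, collapse = ", ")))
  if (!all(atoms$residue %in% residues$residue))
    abort("every atom must reference an existing residue")
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  n_heavy <- tapply(atoms$is_heavy, atoms$residue, sum)
  if (any(n_heavy == 0))
    abort("every residue needs at least one heavy atom")
  structure(
    list(xyz = unname(xyz), atoms = atoms, residues = residues),
    class = "conformation"
  )
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf(
    "<conformation> %d atoms (%d heavy), %d residues\n",
    nrow(x$atoms), sum(x$atoms$is_heavy), nrow(x$residues)
  ))
  invisible(x)
}

#' Number of residues / atoms in a conformation or ensemble
#' @param x a `conformation` or `conf_ensemble`.
#' @return integer count.
#' @export
n_residues <- function(x) nrow(x$residues)

#' @rdname n_residues
#' @export
n_atoms <- function(x) nrow(x$atoms)

infer_element <- function(atom_name) {
  # common PDB dialect: element = first non-digit character of the atom name
  sym <- toupper(sub("^[0-9 ]*([A-Za-z]).*$", "\\1", atom_name))
  sym[!grepl("[A-Za-z]", atom_name)] <- ""
  sym
}

#' Load one model from a (multi-model) PDB file
#'
#' Hydrogens are detected from the element column when present, otherwise
#' from the first non-digit character of the atom name. Residue ordering
#' follows file order; residue identity is (chain, author number, insertion
#' code) mapped to a 1-based internal ordinal.
#'
#' @param path path to a PDB file (possibly multi-MODEL).
#' @param model 1-based model index to extract.
#' @return a [conformation()].
#' @export
load_structure <- function(path, model = 1L) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models)
    abort(sprintf("model %d out of range (file has %d model(s))", model, n_models))
  at <- pdb$atom
  elem <- if ("elesy" %in% names(at)) toupper(trimws(at$elesy)) else rep("", nrow(at))
  missing_el <- is.na(elem) | elem == ""
  elem[missing_el] <- infer_element(at$elety[missing_el])
  if (any(elem == ""))
    abort("atom with unresolvable element symbol")
  ins <- if ("insert" %in% names(at)) ifelse(is.na(at$insert), "", at$insert) else ""
  res_key <- paste(at$chain, at$resno, ins, sep = "|")
  ord <- match(res_key, unique(res_key))
  residues <- tibble::tibble(
    residue = seq_along(unique(res_key)),
    resno = at$resno[!duplicated(res_key)],
    resname = at$resid[!duplicated(res_key)],
    chain = at$chain[!duplicated(res_key)],
    insert = if (length(ins) > 1) ins[!duplicated(res_key)] else ""
  )
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  conformation(
    xyz,
    tibble::tibble(residue = ord, name = at$elety, element = elem),
    residues
  )
}

same_topology <- function(a, b) {
  if (nrow(a$atoms) != nrow(b$atoms))
    return(sprintf("atom counts differ (%d vs %d)", nrow(a$atoms), nrow(b$atoms)))
  diff <- which(
    a$atoms$residue != b$atoms$residue |
      a$atoms$name != b$atoms$name |
      a$atoms$element != b$atoms$element
  )
  if (length(diff) > 0)
    return(sprintf(
      "first differing atom: #%d (%s/res %d vs %s/res %d)",
      diff[1], a$atoms$name[diff[1]], a$atoms$residue[diff[1]],
      b$atoms$name[diff[1]], b$atoms$residue[diff[1]]
    ))
  NULL
}

#' Construct an ensemble of conformations sharing one topology
#'
#' @param conformations list of [conformation()] objects with identical
#'   atom count and residue topology.
#' @param state_label free-text state label (e.g. `"apo"`, `"ATP"`).
#' @param replicate_id replicate label per conformation (recycled if scalar).
#' @param time_ns optional time stamp per conformation (ns); must be strictly
#'   increasing within a replicate.
#' @return an object of class `conf_ensemble`: a shared topology plus an
#'   `n_atoms x 3 x n_frames` coordinate array and a `frames` tibble.
#' @export
conf_ensemble <- function(conformations, state_label = "state",
                          replicate_id = 1L, time_ns = NULL) {
  if (length(conformations) == 0) {
    ref <- NULL
  } else {
    ref <- conformations[[1]]
    for (k in seq_along(conformations)[-1]) {
      msg <- same_topology(ref, conformations[[k]])
      if (!is.null(msg))
        abort(sprintf("topology mismatch at conformation %d: %s", k, msg))
    }
  }
  n <- length(conformations)
  replicate_id <- rep_len(replicate_id, max(n, 0L))
  frames <- tibble::tibble(
    frame = seq_len(n),
    state = rep_len(state_label, n),
    replicate = replicate_id,
    time_ns = if (is.null(time_ns)) NA_real_ else as.numeric(time_ns)
  )
  if (!is.null(time_ns)) {
    for (r in unique(replicate_id)) {
      tt <- frames$time_ns[frames$replicate == r]
      if (any(diff(tt) <= 0))
        abort(sprintf("time_ns must be strictly increasing within replicate %s", r))
    }
  }
  xyz <- if (n > 0) {
    array(
      unlist(lapply(conformations, function(cf) cf$xyz)),
      dim = c(nrow(ref$xyz), 3L, n)
    )
  } else {
    array(numeric(0), dim = c(0L, 3L, 0L))
  }
  structure(
    list(
      xyz = xyz,
      atoms = if (is.null(ref)) tibble::tibble() else ref$atoms,
      residues = if (is.null(ref)) tibble::tibble() else ref$residues,
      frames = frames
    ),
    class = "conf_ensemble"
  )
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conf_ensemble> %d frame(s), %d atoms, %d residues; states: %s\n",
    n_frames(x), nrow(x$atoms), nrow(x$residues),
    paste(unique(x$frames$state), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname n_residues
#' @export
n_frames <- function(x) dim(x$xyz)[3]

#' Extract one frame of an ensemble as a conformation
#' @param ensemble a `conf_ensemble`.
#' @param i frame index.
#' @return a [conformation()].
#' @export
get_conformation <- function(ensemble, i) {
  if (i < 1 || i > n_frames(ensemble)) abort("frame index out of range")
  conformation(ensemble$xyz[, , i], ensemble$atoms, ensemble$residues)
}

#' Load an ensemble from one or more (multi-model) PDB files
#'
#' Each file contributes all of its models; by default every file is one
#' replicate. All models must share the topology of the first.
#'
#' @param paths character vector of PDB paths.
#' @param state_label state label for the pooled ensemble.
#' @param replicate_ids one id per file (default `seq_along(paths)`).
#' @return a [conf_ensemble()].
#' @export
load_ensemble <- function(paths, state_label = "state", replicate_ids = NULL) {
  replicate_ids <- replicate_ids %||% seq_along(paths)
  if (length(replicate_ids) != length(paths))
    abort("`replicate_ids` must have one entry per path")
  confs <- list(); reps <- c()
  for (k in seq_along(paths)) {
    pdb <- bio3d::read.pdb(paths[k], multi = TRUE, verbose = FALSE)
    for (m in seq_len(nrow(pdb$xyz))) {
      confs[[length(confs) + 1L]] <- load_structure(paths[k], model = m)
      reps <- c(reps, replicate_ids[k])
    }
  }
  conf_ensemble(confs, state_label = state_label, replicate_id = reps)
}

#' Read an ensemble from a plain TSV trajectory table
#'
#' A lightweight text dialect for toy/solute-only trajectories: columns
#' `replicate`, `time_ns`, `atom_index`, `x`, `y`, `z`, one row per atom per
#' frame. The topology (atom elements, residue mapping) is supplied
#' separately since the table carries only coordinates.
#'
#' @param path TSV file path.
#' @param topology a [conformation()] providing `atoms` and `residues`.
#' @param state_label state label for the ensemble.
#' @return a [conf_ensemble()].
#' @export
read_ensemble_tsv <- function(path, topology, state_label = "state") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("replicate", "time_ns", "atom_index", "x", "y", "z")
  if (!all(need %in% names(tab)))
    abort(sprintf("trajectory TSV needs columns: %s", paste(need, collapse = ", ")))
  na <- nrow(topology$atoms)
  key <- interaction(tab$replicate, tab$time_ns, drop = TRUE)
  frames_split <- split(tab, key)
  ord <- order(
    vapply(frames_split, function(f) f$replicate[1], tab$replicate[1]),
    vapply(frames_split, function(f) f$time_ns[1], numeric(1))
  )
  frames_split <- frames_split[ord]
  confs <- lapply(frames_split, function(f) {
    if (nrow(f) != na)
      abort(sprintf("frame with %d atoms; topology has %d", nrow(f), na))
    f <- f[order(f$atom_index), ]
    conformation(cbind(f$x, f$y, f$z), topology$atoms, topology$residues)
  })
  conf_ensemble(
    confs,
    state_label = state_label,
    replicate_id = vapply(frames_split, function(f) f$replicate[1], tab$replicate[1]),
    time_ns = vapply(frames_split, function(f) f$time_ns[1], numeric(1))
  )
}

#' Write an ensemble as a plain TSV trajectory table
#' @param ensemble a [conf_ensemble()] with frame times.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  na <- nrow(ensemble$atoms)
  nf <- n_frames(ensemble)
  tab <- tibble::tibble(
    replicate = rep(ensemble$frames$replicate, each = na),
    time_ns = rep(ensemble$frames$time_ns, each = na),
    atom_index = rep(seq_len(na), nf),
    x = as.vector(ensemble$xyz[, 1, ]),
    y = as.vector(ensemble$xyz[, 2, ]),
    z = as.vector(ensemble$xyz[, 3, ])
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Subsample each replicate at equal time spacing over a trailing window
#'
#' Per replicate, `n_frames` target times are laid out as
#' `t_end - window + k * window/(n_frames - 1)`, `k = 0..n_frames-1`, and each
#' target is mapped to the nearest stored frame (no interpolation). Two
#' targets resolving to the same frame is an error, as is a replicate whose
#' time span is shorter than the window. With 4 replicates and
#' `n_frames = 100` the pooled ensemble holds 400 conformations.
#'
#' @param ensemble a [conf_ensemble()] with `time_ns` present.
#' @param n_frames frames to keep per replicate (default 100).
#' @param window_ns trailing window length in ns (default 20).
#' @return the pooled subsampled [conf_ensemble()], replicate labels kept.
#' @export
subsample_ensemble <- function(ensemble, n_frames = 100L, window_ns = 20) {
  if (n_frames < 1L) abort("`n_frames` must be >= 1")
  stop_if_not_scalar_number(window_ns, "window_ns", positive = TRUE)
  if (any(is.na(ensemble$frames$time_ns)))
    abort("subsampling requires frame times (`time_ns`)")
  keep <- integer(0)
  for (r in unique(ensemble$frames$replicate)) {
    idx <- which(ensemble$frames$replicate == r)
    tt <- ensemble$frames$time_ns[idx]
    t_end <- max(tt)
    # allow half a target spacing of slack: a replicate that was already
    # subsampled with this spec spans window - spacing/2 at worst, and
    # re-subsampling it must reproduce the same frame set (idempotence)
    tol <- if (n_frames > 1L) window_ns / (2 * (n_frames - 1L)) else 0
    if (t_end - min(tt) < window_ns - tol - 1e-9)
      abort(sprintf(
        "replicate %s spans %.4g ns, shorter than the %.4g ns window",
        r, t_end - min(tt), window_ns
      ))
    targets <- if (n_frames == 1L) t_end else
      t_end - window_ns + (seq_len(n_frames) - 1L) * window_ns / (n_frames - 1L)
    sel <- vapply(targets, function(tgt) idx[which.min(abs(tt - tgt))], integer(1))
    if (anyDuplicated(sel))
      abort(sprintf(
        "replicate %s: multiple target times map to the same stored frame", r
      ))
    keep <- c(keep, sel)
  }
  out <- ensemble
  out$xyz <- ensemble$xyz[, , keep, drop = FALSE]
  out$frames <- ensemble$frames[keep, ]
  out$frames$frame <- seq_len(nrow(out$frames))
  out
}

#' Write a per-frame summary table of an ensemble
#'
#' @param ensemble a [conf_ensemble()].
#' @param path output TSV path.
#' @return the summary tibble (one row per conformation), invisibly.
#' @export
write_ensemble_summary <- function(ensemble, path) {
  tab <- ensemble$frames[, c("frame", "state", "replicate", "time_ns")]
  readr::write_tsv(tab, path)
  invisible(tab)
}
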
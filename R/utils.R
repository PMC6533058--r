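# internal helpers shared across modules

# Counter-based child seeds: one root seed reproducibly expands into
# independent per-component streams, so regenerating one synthetic input
# does not perturb the others. Kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(root, counter) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  as.integer((abs(root) * 1009 + counter * 7919 + 11) %% 2147483629L)
}

# Hazen plotting positions (i - 0.5)/n for least-squares CDF fitting;
# avoids the 0 and 1 endpoints that distort the tails.
hazen_positions <- function(n) (seq_len(n) - 0.5) / n

# run `expr` under a local RNG state seeded with `seed`; restores
# .Random.seed afterwards so generators are pure functions of their spec
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# column-wise minimum of a numeric matrix (rows reduced), without
# matrixStats; fast enough for per-residue atom blocks
col_mins <- function(m) {
  if (nrow(m) == 1L) return(m[1L, ])
  do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
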
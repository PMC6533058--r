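# fixtures built in code: tiny PDB writers and independent oracles

# write a minimal (multi-)MODEL PDB; atoms = data.frame(name, resno, chain,
# x, y, z, element); coords_per_model = list of n_atoms x 3 matrices
write_tiny_pdb <- function(path, atoms, coords_per_model) {
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(coords_per_model) > 1
  for (m in seq_along(coords_per_model)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- coords_per_model[[m]]
    for (a in seq_len(nrow(atoms))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        a, atoms$name[a], atoms$chain[a], atoms$resno[a],
        xyz[a, 1], xyz[a, 2], xyz[a, 3], atoms$element[a]
      ), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

default_atoms <- function(n_res = 2, per_res = 4, elements = NULL) {
  elements <- elements %||% rep(c("C", "N", "O", "C"), length.out = per_res)
  data.frame(
    name = rep(c("CA", paste0("X", seq_len(max(per_res - 1, 0))))[seq_len(per_res)],
               n_res),
    resno = rep(seq_len(n_res), each = per_res),
    chain = "A",
    element = rep(elements, n_res)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent transcription of the smooth-mask formula (oracle; kept apart
# from the package implementation on purpose)
oracle_mask <- function(x, c1 = 4, c2 = 8) {
  vapply(x, function(v) {
    if (v <= c1) v
    else if (v <= c2) c1 + 2 * ((c2 - c1) / pi) * cos((pi / 2) * (c2 - v) / (c2 - c1))
    else c1 + 2 * (c2 - c1) / pi
  }, numeric(1))
}

# expected masked mean of a N(mu, sd) distance sample, by numerical
# integration of the oracle mask against the normal density
oracle_masked_mean <- function(mu, sd, c1 = 4, c2 = 8) {
  stats::integrate(
    function(x) oracle_mask(pmax(x, 0), c1, c2) * stats::dnorm(x, mu, sd),
    lower = max(mu - 8 * sd, 0), upper = mu + 8 * sd
  )$value
}

# brute-force minimum heavy-atom distance (double loop)
oracle_min_dist <- function(conf, i, j) {
  ai <- which(conf$atoms$residue == i & conf$atoms$is_heavy)
  aj <- which(conf$atoms$residue == j & conf$atoms$is_heavy)
  best <- Inf
  for (a in ai) for (b in aj)
    best <- min(best, sqrt(sum((conf$xyz[a, ] - conf$xyz[b, ])^2)))
  best
}

all_pairs_tbl <- function(n) {
  cmb <- utils::combn(n, 2)
  tibble::tibble(i = cmb[1, ], j = cmb[2, ])
}

random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = rnorm(3, sd = 10))
}
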
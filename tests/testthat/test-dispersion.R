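disk_image <- function(n = 121, radius = 50, intensity = NULL,
                       cell_id = "c1", condition = "cond") {
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  mask <- (rows - ctr)^2 + (cols - ctr)^2 <= radius^2
  intensity <- intensity %||% matrix(1, n, n)
  cell_image(intensity, mask, center = c(ctr, ctr),
             cell_id = cell_id, condition = condition)
}

test_that("cell_image validates masks and centers", {
  img <- disk_image()
  expect_s3_class(img, "cell_image")
  expect_error(
    cell_image(matrix(1, 5, 5), matrix(TRUE, 4, 4)),
    "shape"
  )
  expect_error(
    cell_image(matrix(-1, 5, 5), matrix(TRUE, 5, 5)),
    "nonnegative"
  )
  mask <- matrix(FALSE, 11, 11); mask[2:4, 2:4] <- TRUE
  expect_error(
    cell_image(matrix(1, 11, 11), mask, center = c(10, 10)),
    "outside"
  )
  # nucleus mask centroid defines the center
  nuc <- matrix(FALSE, 11, 11); nuc[3, 3] <- TRUE
  img2 <- cell_image(matrix(1, 11, 11), mask, center_mask = nuc)
  expect_equal(img2$center, c(3, 3))
})

test_that("all intensity at the center lands in the first bin", {
  n <- 61; ctr <- 31
  intens <- matrix(0, n, n); intens[ctr, ctr] <- 7
  img <- disk_image(n = n, radius = 25, intensity = intens)
  pr <- radial_profile(img, n_bins = 10)
  expect_equal(pr$fraction[1], 1)
  expect_equal(sum(pr$fraction), 1, tolerance = 1e-12)
})

test_that("uniform disk: outermost of 5 bins holds about 1 - 0.8^2 of the signal", {
  pr <- radial_profile(disk_image(), n_bins = 5)
  expect_equal(pr$fraction[5], 1 - 0.8^2, tolerance = 0.02 / 0.36)
  expect_equal(sum(pr$fraction), 1, tolerance = 1e-12)
})

test_that("a thin ring at normalized radius 0.5 peaks in the bin containing 0.5", {
  n <- 121; ctr <- 61; radius <- 50
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  r <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  intens <- matrix(0, n, n)
  intens[abs(r - 0.5 * radius) < 1] <- 1
  img <- disk_image(n = n, radius = radius, intensity = intens)
  pr <- radial_profile(img, n_bins = 10)
  peak <- pr[which.max(pr$fraction), ]
  expect_true(peak$r_lo <= 0.5 && 0.5 <= peak$r_hi)
})

test_that("profiles are invariant to global intensity scaling", {
  set.seed(1)
  intens <- matrix(runif(121^2), 121, 121)
  a <- radial_profile(disk_image(intensity = intens), n_bins = 8)
  b <- radial_profile(disk_image(intensity = 100 * intens), n_bins = 8)
  expect_equal(a$fraction, b$fraction, tolerance = 1e-12)
})

test_that("moving intensity outward never decreases the peripheral fraction", {
  set.seed(2)
  n <- 61; radius <- 25; ctr <- 31
  intens <- matrix(0, n, n)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  r <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  inner <- which(r < 0.3 * radius & r > 0)
  outer <- which(r > 0.7 * radius & r <= radius - 1)
  intens[inner] <- 5; intens[outer] <- 1
  img <- disk_image(n = n, radius = radius, intensity = intens)
  p0 <- intensity_fraction(radial_profile(img, 25), "peripheral", 0.6)
  # move some inner intensity to the outer zone
  intens2 <- intens
  intens2[inner[1:20]] <- 0
  intens2[outer[1:20]] <- intens2[outer[1:20]] + 5
  img2 <- disk_image(n = n, radius = radius, intensity = intens2)
  p1 <- intensity_fraction(radial_profile(img2, 25), "peripheral", 0.6)
  expect_gte(p1, p0)
})

test_that("aggregate_condition averages per-bin across cells with SEM", {
  img <- disk_image(cell_id = "a")
  pr <- radial_profile(img, 6)
  same <- dplyr::bind_rows(pr, dplyr::mutate(pr, cell_id = "b"))
  agg <- aggregate_condition(same)
  expect_equal(agg$mean_fraction, pr$fraction)
  expect_equal(agg$sem, rep(0, 6))
  expect_equal(agg$n_cells, rep(2L, 6))

  # two one-hot cells average to 0.5 at those bins
  p1 <- pr; p1$fraction <- c(1, rep(0, 5)); p1$cell_id <- "x"
  p2 <- pr; p2$fraction <- c(rep(0, 5), 1); p2$cell_id <- "y"
  agg2 <- aggregate_condition(dplyr::bind_rows(p1, p2))
  expect_equal(agg2$mean_fraction, c(0.5, 0, 0, 0, 0, 0.5))

  # brute-force average on random sets
  set.seed(3)
  prs <- purrr::map_dfr(1:4, function(k) {
    p <- pr; p$cell_id <- paste0("c", k)
    f <- runif(6); p$fraction <- f / sum(f); p
  })
  agg3 <- aggregate_condition(prs)
  brute <- tapply(prs$fraction, prs$bin, mean)
  expect_equal(agg3$mean_fraction, as.numeric(brute[as.character(agg3$bin)]))
})

test_that("compare_conditions gives p near 1 for identical cells and calibrated nulls", {
  img <- disk_image()
  pr <- radial_profile(img, 5)
  cells <- purrr::map_dfr(1:3, function(k) {
    p <- pr; p$cell_id <- paste0("a", k); p$condition <- "A"; p
  })
  cells2 <- dplyr::mutate(cells, condition = "B",
                          cell_id = sub("^a", "b", cell_id))
  cmp <- compare_conditions(dplyr::bind_rows(cells, cells2), "A", "B")
  expect_true(all(cmp$p_value > 0.9))

  expect_error(
    compare_conditions(dplyr::bind_rows(cells, cells2[1:5, ]), "A", "B"),
    "at least 2"
  )
})

test_that("clustered vs peripheral synthetic conditions differ at the extremes", {
  profs <- purrr::map_dfr(1:6, function(k) {
    periph <- simulate_cell_image(
      cell_sim_spec(image_size = 81, cell_radius_px = 35,
                    beta_shape1 = 8, beta_shape2 = 2, n_photons = 2e4,
                    seed = 100 + k),
      cell_id = paste0("p", k), condition = "peripheral"
    )
    clust <- simulate_cell_image(
      cell_sim_spec(image_size = 81, cell_radius_px = 35,
                    beta_shape1 = 2, beta_shape2 = 8, n_photons = 2e4,
                    seed = 200 + k),
      cell_id = paste0("c", k), condition = "clustered"
    )
    dplyr::bind_rows(radial_profile(periph$image, 10),
                     radial_profile(clust$image, 10))
  })
  cmp <- compare_conditions(profs, "clustered", "peripheral")
  expect_lt(cmp$p_value[1], 0.05)
  expect_lt(cmp$p_value[10], 0.05)
})

test_that("intensity fractions partition at a bin edge and saturate correctly", {
  pr <- radial_profile(disk_image(), n_bins = 5)
  peri <- intensity_fraction(pr, "peripheral", 0.8)
  nucl <- intensity_fraction(pr, "perinuclear", 0.8)
  expect_equal(peri + nucl, 1, tolerance = 1e-12)
  expect_equal(peri, 1 - 0.8^2, tolerance = 0.02 / 0.36)

  # all intensity beyond the threshold
  n <- 61; ctr <- 31; radius <- 25
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  r <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  intens <- matrix(0, n, n)
  intens[r > 0.9 * radius & r <= radius - 0.5] <- 1
  img <- disk_image(n = n, radius = radius, intensity = intens)
  expect_gt(intensity_fraction(radial_profile(img, 25), "peripheral", 0.8), 0.97)

  expect_error(intensity_fraction(pr, "peripheral", 1.5), "0, 1")
})

test_that("dispersion_report combines means, SEMs and reference p-values", {
  profs <- purrr::map_dfr(1:2, function(k) {
    purrr::map_dfr(1:3, function(cc) {
      sim <- simulate_cell_image(
        cell_sim_spec(image_size = 61, cell_radius_px = 25,
                      beta_shape1 = c(2, 8)[k], beta_shape2 = c(8, 2)[k],
                      n_photons = 5e3, seed = 10 * k + cc),
        cell_id = paste0(k, "_", cc),
        condition = c("ctrl", "dispersed")[k]
      )
      radial_profile(sim$image, 8)
    })
  })
  rep1 <- dispersion_report(profs)
  expect_equal(nrow(rep1), 16)
  rep2 <- dispersion_report(profs, reference = "ctrl")
  expect_true("p_vs_ref" %in% names(rep2))
  expect_true(all(is.na(rep2$p_vs_ref[rep2$condition == "ctrl"])))
  # per-cell fractions sum to 1
  sums <- tapply(profs$fraction, profs$cell_id, sum)
  expect_equal(as.numeric(sums), rep(1, 6), tolerance = 1e-9)
  expect_error(dispersion_report(profs, reference = "zz"), "not present")
})

test_that("grid TSV round-trips an intensity matrix", {
  m <- matrix(rpois(30, 4), 5, 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(as.data.frame(m), path, col_names = FALSE)
  back <- read_grid_tsv(path)
  expect_equal(unname(as.matrix(back)), m)
})
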
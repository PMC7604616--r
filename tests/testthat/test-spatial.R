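# Spatial statistics: PDI anchors and invariances, compartment ratios,
# PLA dot calling and classification.

test_that("PDI anchors: centroid spots give 0, uniform spots give ~1", {
  cell <- disk_cell()
  ctr <- spot_set(rep(cell$nucleus_centroid["x"], 5),
                  rep(cell$nucleus_centroid["y"], 5))
  expect_equal(compute_pdi(cell, ctr)$pdi, 0)
  u <- gen_spots(cell, spot_sim_params(n_spots = 500, seed = 14))
  expect_lt(abs(compute_pdi(cell, u)$pdi - 1), 0.1)
  expect_error(compute_pdi(cell, ctr[0, ]), "at least one spot")
})

test_that("boundary-ring spots on a disk give the closed-form PDI of 2", {
  cell <- disk_cell(cell_radius = 200, image_size = 440)
  theta <- seq(0, 2 * pi, length.out = 721)[-1]
  ring <- spot_set(cell$cell_centroid["x"] + 200 * cos(theta),
                   cell$cell_centroid["y"] + 200 * sin(theta))
  res <- compute_pdi(cell, ring)
  # raster reference moment carries lattice-discretization error ~3e-4
  expect_lt(abs(res$pdi - 2), 5e-3)
  # continuum limit: exact ring second moment over the closed-form disk
  # moment R^2/2 recovers 2 to floating-point accuracy
  d2 <- (ring$x - cell$nucleus_centroid["x"])^2 +
    (ring$y - cell$nucleus_centroid["y"])^2
  expect_lt(abs(mean(d2) / (200^2 / 2) - 2), 1e-6)
})

test_that("PDI is invariant under translation and isotropic rescaling", {
  base <- cell_sim_params(image_size = 300, cell_radius = 60,
                          nucleus_radius = 20, nucleus_offset = c(10, 5))
  cell <- gen_cell(base)
  spots <- gen_spots(cell, spot_sim_params(n_spots = 400, bias_exponent = 2,
                                           seed = 6))
  pdi0 <- compute_pdi(cell, spots)$pdi
  # integer translation of the whole scene is exact on the raster
  shift <- c(17, -9)
  shift_mask <- function(m, dx, dy) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    idx <- which(m, arr.ind = TRUE)
    out[cbind(idx[, 1] + dy, idx[, 2] + dx)] <- TRUE
    out
  }
  tr_cell <- cell_geometry(shift_mask(cell$cell_mask, shift[1], shift[2]),
                           shift_mask(cell$nucleus_mask, shift[1], shift[2]))
  tr_spots <- spot_set(spots$x + shift[1], spots$y + shift[2])
  expect_equal(compute_pdi(tr_cell, tr_spots)$pdi, pdi0, tolerance = 1e-12)
  # rescaling the scene (disk radii and spot coordinates x3); the raster
  # reference moment re-discretizes, so agreement is to raster accuracy
  big <- gen_cell(cell_sim_params(image_size = 900, cell_radius = 180,
                                  nucleus_radius = 60,
                                  nucleus_offset = c(30, 15)))
  ctr_small <- (300 + 1) / 2
  ctr_big <- (900 + 1) / 2
  big_spots <- spot_set(ctr_big + 3 * (spots$x - ctr_small),
                        ctr_big + 3 * (spots$y - ctr_small))
  expect_equal(compute_pdi(big, big_spots)$pdi, pdi0, tolerance = 2e-3)
})

test_that("PDI increases strictly with the planted radial bias", {
  cell <- disk_cell()
  betas <- c(-2, 0, 2, 4)
  for (seed in 1:10) {
    pdis <- vapply(betas, function(b)
      compute_pdi(cell, gen_spots(cell, spot_sim_params(
        n_spots = 2000, bias_exponent = b,
        seed = derive_seed(seed, match(b, betas)))))$pdi, numeric(1))
    expect_true(all(diff(pdis) > 0))
  }
})

test_that("peripheral/perinuclear ratio follows band means", {
  cell <- disk_cell()
  bands <- compartment_bands(cell)
  img <- matrix(1, nrow(cell$cell_mask), ncol(cell$cell_mask))
  expect_equal(peripheral_perinuclear_ratio(cell, img)$ratio, 1)
  img2 <- matrix(0, nrow(img), ncol(img)); img2[bands$perinuclear] <- 5
  expect_equal(peripheral_perinuclear_ratio(cell, img2)$ratio, 0)
  img3 <- matrix(0, nrow(img), ncol(img))
  img3[bands$peripheral] <- 2; img3[bands$perinuclear] <- 4
  expect_equal(peripheral_perinuclear_ratio(cell, img3)$ratio, 0.5)
  img4 <- matrix(0, nrow(img), ncol(img)); img4[bands$peripheral] <- 1
  flagged <- peripheral_perinuclear_ratio(cell, img4)
  expect_equal(flagged$flag, "zero_perinuclear_mean")
  expect_true(is.infinite(flagged$ratio))
  wide <- compartment_spec(peripheral_width = 60, perinuclear_width = 60)
  expect_error(peripheral_perinuclear_ratio(cell, img, wide), "overlap")
})

test_that("PLA dot calling recovers planted dots and rejects flat images", {
  cell <- disk_cell()
  sim <- gen_pla_image(cell, pla_sim_params(n_dots = 7, dot_amplitude = 100,
                                            background_sd = 10, seed = 19))
  dots <- call_pla_dots(sim$image, cell)
  expect_equal(nrow(dots), 7L)
  # centers localize to within a pixel of the planted truth
  for (i in seq_len(nrow(sim$truth))) {
    dd <- sqrt((dots$x - sim$truth$x[i])^2 + (dots$y - sim$truth$y[i])^2)
    expect_lt(min(dd), 1)
  }
  flat <- matrix(5, nrow(cell$cell_mask), ncol(cell$cell_mask))
  expect_error(call_pla_dots(flat, cell), "flat image")
})

test_that("the dot threshold is strict and k_sd is monotone", {
  # deterministic background: 40% at 10, 20% at 11, 40% at 12 gives a
  # stable median of 11 and MAD-derived SD of 1.4826
  cell <- disk_cell()
  img <- matrix(10, nrow(cell$cell_mask), ncol(cell$cell_mask))
  idx <- which(cell$cell_mask)
  phase <- seq_along(idx) %% 5
  img[idx[phase == 2]] <- 11
  img[idx[phase %in% c(3, 4)]] <- 12
  thr <- 11 + 3 * 1.4826
  put_dot <- function(img, val) {
    img[118:120, 118:120] <- val
    img
  }
  at <- call_pla_dots(put_dot(img, thr), cell)
  expect_equal(nrow(at), 0L)          # exactly at threshold: not called
  above <- call_pla_dots(put_dot(img, thr + 1e-6), cell)
  expect_equal(nrow(above), 1L)       # strictly above: called
  expect_equal(above$area, 9L)
  # raising k_sd never increases the dot count
  noisy <- gen_pla_image(cell, pla_sim_params(n_dots = 12,
                                              dot_amplitude = 40,
                                              seed = 8))$image
  counts <- vapply(c(1, 2, 3, 4, 6), function(k)
    nrow(call_pla_dots(noisy, cell, pla_params(k_sd = k))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("dot calling has a near-zero false-positive rate on null images", {
  cell <- disk_cell()
  fp <- vapply(1:100, function(seed) {
    img <- gen_pla_image(cell, pla_sim_params(n_dots = 0,
                                              seed = seed))$image
    nrow(call_pla_dots(img, cell))
  }, numeric(1))
  expect_lt(mean(fp), 1)  # fewer than one spurious dot per cell on average
})

test_that("dot classification conserves counts and matches planted truth", {
  cell <- disk_cell()
  for (split in c(0, 0.5, 1)) {
    sim <- gen_pla_image(cell, pla_sim_params(n_dots = 40,
                                              dot_region_split = split,
                                              dot_amplitude = 100,
                                              seed = 50 + split * 10))
    dots <- call_pla_dots(sim$image, cell)
    cls <- classify_dots(cell, dots)
    expect_equal(cls$n_peripheral + cls$n_body, cls$n_total)
    expect_equal(cls$n_total, 40L)
    expect_equal(cls$n_peripheral,
                 sum(sim$truth$compartment == "peripheral"))
  }
  outside <- data.frame(x = c(1, 128), y = c(1, 128))
  expect_warning(cls <- classify_dots(cell, outside), "excluded")
  expect_equal(cls$n_excluded, 1L)
  expect_equal(cls$n_total, 1L)
})

test_that("geometry constructors validate containment and connectivity", {
  m <- matrix(FALSE, 40, 40); m[10:30, 10:30] <- TRUE
  n <- matrix(FALSE, 40, 40); n[15:20, 15:20] <- TRUE
  g <- cell_geometry(m, n)
  expect_equal(unname(g$nucleus_centroid), c(17.5, 17.5))
  bad_n <- matrix(FALSE, 40, 40); bad_n[28:35, 28:35] <- TRUE
  expect_error(cell_geometry(m, bad_n), "not contained")
  split <- m; split[25, ] <- FALSE
  expect_error(cell_geometry(split, n), "not connected")
  expect_error(cell_geometry(m, matrix(FALSE, 40, 40)), "non-empty")
})

test_that("spots outside the cell are dropped with a warning", {
  cell <- disk_cell()
  expect_warning(s <- spot_set(c(128, 1), c(128, 1), cell = cell),
                 "dropped")
  expect_equal(nrow(s), 1L)
  expect_equal(attr(s, "n_dropped"), 1L)
})
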
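test_that("Gaussian smoothing is exact on impulses and neutral on constants", {
  grid <- small_grid(dim = c(12, 12, 12))
  vals <- array(0, grid$dim)
  m <- stat_map(vals, grid, "F")
  expect_identical(smooth_map(m, 0), m)
  # constant map unchanged, including at the mask boundary
  cm <- stat_map(array(3.7, grid$dim), grid, "F")
  sm <- smooth_map(cm, 0.009)
  expect_equal(sm$values[grid$mask], rep(3.7, sum(grid$mask)),
               tolerance = 1e-12)
  # interior impulse: neighbour/peak ratio is the Gaussian kernel ratio
  ctr <- round(grid$dim / 2)
  vals[ctr[1], ctr[2], ctr[3]] <- 1
  im <- smooth_map(stat_map(vals, grid, "F"), 0.009)
  sigma <- 0.009 / (2 * sqrt(2 * log(2)))
  ratio <- im$values[ctr[1] + 1, ctr[2], ctr[3]] /
    im$values[ctr[1], ctr[2], ctr[3]]
  expect_equal(ratio, exp(-(0.003)^2 / (2 * sigma^2)), tolerance = 1e-6)
})

test_that("F-to-p conversion is the exact upper tail", {
  grid <- small_grid()
  vals <- array(0, grid$dim)
  vox <- which(grid$mask)
  vals[vox[1]] <- 0
  vals[vox[2]] <- qf(0.95, 1, 60)
  vals[vox[3]] <- qf(0.999, 1, 60)
  p <- map_to_p(stat_map(vals, grid, "F"), c(1, 60))
  expect_equal(p$values[vox[1]], 1)
  expect_equal(p$values[vox[2]], 0.05, tolerance = 1e-9)
  expect_equal(p$values[vox[3]], 0.001, tolerance = 1e-9)
  # monotone decreasing in F
  expect_true(p$values[vox[3]] < p$values[vox[2]])
})

test_that("maximum-p conjunction dominates each input and checks grids", {
  grid <- small_grid()
  set.seed(1)
  mk <- function() {
    v <- array(NA_real_, grid$dim)
    v[grid$mask] <- runif(sum(grid$mask))
    stat_map(v, grid, "p")
  }
  maps <- list(mk(), mk(), mk())
  conj <- conjunction_p(maps)
  for (m in maps) {
    expect_true(all(conj$values[grid$mask] >= m$values[grid$mask]))
  }
  expect_equal(conjunction_p(list(maps[[1]], maps[[1]]))$values,
               maps[[1]]$values)
  # adding a participant can never lower the conjunction p
  conj2 <- conjunction_p(maps[1:2])
  expect_true(all(conj$values[grid$mask] >= conj2$values[grid$mask]))
  other <- small_grid(dim = c(6, 6, 6))
  ov <- array(0.5, other$dim)
  expect_error(conjunction_p(list(maps[[1]], stat_map(ov, other, "p"))),
               "share one grid")
})

test_that("BH mask equals the brute-force step-up on random p vectors", {
  grid <- small_grid(dim = c(5, 5, 4))
  nvox <- sum(grid$mask)
  set.seed(2)
  for (i in 1:300) {
    p <- runif(nvox)^sample(c(1, 2, 4), 1)   # varying signal density
    q <- runif(1, 0.001, 0.2)
    pm <- opmtheta:::stat_map_from_values(p, grid, which(as.vector(grid$mask)), "p")
    got <- fdr_mask(pm, q)$values[grid$mask] == 1
    expect_identical(got, bh_stepup_oracle(p, q))
  }
  # worked example: first two of (0.001, 0.002, 0.2, 0.9) pass at q = 0.05
  g4 <- source_grid(sphere_head(), spacing = 0.003, dim = c(4, 1, 1))
  expect_true(all(g4$mask))
  pm4 <- stat_map(array(c(0.001, 0.002, 0.2, 0.9), c(4, 1, 1)), g4, "p")
  expect_equal(as.numeric(fdr_mask(pm4, 0.05)$values), c(1, 1, 0, 0))
  # all p = 1: empty mask
  pm1 <- stat_map(array(1, c(4, 1, 1)), g4, "p")
  expect_equal(sum(fdr_mask(pm1, 0.05)$values), 0)
})

test_that("lowering q never adds voxels to the FDR mask", {
  grid <- small_grid()
  set.seed(3)
  p <- runif(sum(grid$mask))^3
  pm <- opmtheta:::stat_map_from_values(p, grid, which(as.vector(grid$mask)), "p")
  qs <- c(0.2, 0.1, 0.05, 0.01, 0.005, 0.001)
  masks <- lapply(qs, function(q) fdr_mask(pm, q)$values[grid$mask])
  for (i in seq_along(qs)[-1]) {
    expect_true(all(masks[[i]] <= masks[[i - 1]]))
  }
})

test_that("cluster labelling agrees with a flood-fill oracle", {
  grid <- small_grid(dim = c(7, 7, 7))
  set.seed(4)
  for (i in 1:15) {
    mask_arr <- array(runif(prod(grid$dim)) < 0.25, grid$dim) & grid$mask
    lab <- opmtheta:::label_components6(mask_arr, grid$dim)
    oracle <- flood_fill_oracle(mask_arr)
    expect_equal(max(lab), max(oracle))
    # same partition: cross-tabulated labels map one-to-one
    if (max(lab) > 0) {
      tab <- table(lab[mask_arr], oracle[mask_arr])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
  }
})

test_that("edge-sharing voxels are separate clusters under 6-connectivity", {
  grid <- small_grid(dim = c(6, 6, 6))
  mv <- array(0, grid$dim)
  mv[3, 3, 3] <- 1
  mv[4, 4, 3] <- 1   # shares an edge, not a face
  mask <- stat_map(mv, grid, "mask01")
  sv <- array(0, grid$dim); sv[3, 3, 3] <- 5; sv[4, 4, 3] <- 7
  rep_ <- clusters_and_peaks(mask, stat_map(sv, grid, "F"))
  expect_equal(nrow(rep_), 2)
  expect_setequal(rep_$n_voxels, c(1, 1))
  # a face-sharing bridge voxel merges everything into one cluster
  mv[4, 3, 3] <- 1
  sv[4, 3, 3] <- 9
  rep2 <- clusters_and_peaks(stat_map(mv, grid, "mask01"),
                             stat_map(sv, grid, "F"))
  expect_equal(nrow(rep2), 1)
  expect_equal(rep2$n_voxels, 3)
  expect_equal(rep2$peak_stat, 9)
  # empty mask gives an empty, well-formed report
  empty <- clusters_and_peaks(stat_map(array(0, grid$dim), grid, "mask01"),
                              stat_map(sv, grid, "F"))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("cluster", "n_voxels", "peak_x", "peak_y", "peak_z",
                        "peak_stat", "voxels"))
})

test_that("cluster peak ties break to the lowest linear index", {
  grid <- small_grid(dim = c(6, 6, 6))
  mv <- array(0, grid$dim); sv <- array(0, grid$dim)
  mv[2:4, 3, 3] <- 1
  sv[2:4, 3, 3] <- 4   # three-way tie
  rep_ <- clusters_and_peaks(stat_map(mv, grid, "mask01"),
                             stat_map(sv, grid, "F"))
  expect_equal(rep_$n_voxels, 3)
  ijk <- grid_world_to_index(grid, cbind(rep_$peak_x, rep_$peak_y, rep_$peak_z) / 1000)
  expect_equal(as.numeric(ijk), c(2, 3, 3))
})
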
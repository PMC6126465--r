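test_that("symmetry orbits map to one canonical key", {
  p1 <- symmetry_ops("P1", friedel = TRUE)
  expect_equal(unname(map_to_unique(c(-1, 2, 3), p1)[1, ]), c(1, -2, -3))
  ident <- symmetry_ops("P1", friedel = FALSE)
  expect_equal(unname(map_to_unique(c(-1, 2, 3), ident)[1, ]), c(-1, 2, 3))
  set.seed(2)
  for (sg in c("P2", "P212121", "P4", "P6")) {
    ops <- symmetry_ops(sg)
    hkl <- cbind(sample(-6:6, 30, TRUE), sample(-6:6, 30, TRUE), sample(-6:6, 30, TRUE))
    base_key <- map_to_unique(hkl, ops)
    for (R in ops$rotations) {
      moved <- hkl %*% R
      expect_equal(map_to_unique(moved, ops), base_key)
      expect_equal(map_to_unique(-moved, ops), base_key)
    }
  }
  expect_error(symmetry_ops("X999"), "no shipped operators")
})

test_that("cell tolerance check fails loudly and can be disabled", {
  a <- unit_cell(100, 100, 100, 90, 90, 90)
  b <- unit_cell(103, 100, 100, 90, 90, 90)
  expect_true(check_tolerance(list(a, a), 2))
  bad <- check_tolerance(list(a, b), 2)
  expect_false(bad)
  expect_match(attr(bad, "worst"), "3.00 %")
  expect_true(check_tolerance(list(a, b), 100))
  c2 <- unit_cell(100, 100, 100, 90, 93, 90)
  expect_false(check_tolerance(list(a, c2), 2))  # angles compared in degrees
})

test_that("a doubled copy is rescaled to k = 0.5 with B = 0", {
  set.seed(4)
  obs <- data.frame(h = sample(1:5, 60, TRUE), k = sample(-4:4, 60, TRUE),
                    l = sample(-4:4, 60, TRUE),
                    intensity = runif(60, 50, 200), sigma = 1,
                    image = sample(1:5, 60, TRUE))
  ds1 <- toy_dataset(obs, cell = unit_cell(30, 30, 30, 90, 90, 90), serial = 1L)
  obs2 <- obs; obs2$intensity <- obs2$intensity * 2
  ds2 <- toy_dataset(obs2, cell = unit_cell(30, 30, 30, 90, 90, 90), serial = 2L)
  sc <- scale_datasets(list(ds1, ds2), symmetry_ops("P1"))
  expect_equal(sc$scales$k, c(1, 0.5), tolerance = 1e-6)
  expect_equal(sc$scales$B, c(0, 0), tolerance = 1e-8)
  expect_true(sc$converged)
  # single dataset: identity scales, observations unchanged
  sc1 <- scale_datasets(list(ds1), symmetry_ops("P1"))
  expect_equal(sc1$scales$k, 1)
  expect_equal(sort(sc1$scaled$intensity), sort(obs$intensity))
})

test_that("planted (k, B) scales are recovered on noiseless groups", {
  cfg <- sim_config(n_groups = 1, n_per_group = 4, wedge_images = 8,
                    obs_per_image = 50, noise_frac = 0, background_sigma = 0,
                    cell_jitter = 0, d_min = 3.5, seed = 6)
  truth <- ground_truth(cfg)
  grp <- lapply(1:4, function(i) simulate_dataset(cfg, i, truth))
  plan <- isomerge:::sim_plan(cfg)
  sc <- scale_datasets(grp, symmetry_ops(cfg$spacegroup))
  # reference-frame truth: k_hat_j = k_1/k_j, B_hat_j = B_1 - B_j
  expect_equal(sc$scales$k, plan$k_true[1] / plan$k_true, tolerance = 1e-4)
  expect_equal(sc$scales$B, plan$B_true[1] - plan$B_true, tolerance = 1e-4)
})

test_that("disconnected groups are refused", {
  obs_a <- data.frame(h = 1, k = 0, l = 0, intensity = 10, sigma = 1, image = 1)
  obs_b <- data.frame(h = 2, k = 0, l = 0, intensity = 10, sigma = 1, image = 1)
  dsa <- toy_dataset(obs_a, serial = 1L)
  dsb <- toy_dataset(obs_b, serial = 2L)
  expect_error(scale_datasets(list(dsa, dsb), symmetry_ops("P1")),
               "unconnected")
})

test_that("merging is the inverse-variance mean, order independent", {
  mk <- function(I, sig) {
    dt <- data.table::data.table(serial = seq_along(I), h = 1L, k = 0L,
                                 l = 0L, s = 0.01, intensity = I,
                                 sigma = sig, image = 1L)
    dt$key <- "1 0 0"
    dt
  }
  m1 <- merge_observations(mk(c(10, 10), c(1, 1)))
  expect_equal(m1$intensity, 10)
  expect_equal(m1$sigma, 1 / sqrt(2))
  m2 <- merge_observations(mk(c(10, 20), c(1, 2)))
  expect_equal(m2$intensity, 12)
  expect_equal(m2$sigma, (5 / 4)^(-1 / 2), tolerance = 1e-9)
  expect_equal(m2$sigma, 0.894, tolerance = 1e-3)
  m3 <- merge_observations(mk(c(20, 10), c(2, 1)))
  expect_equal(m3$intensity, m2$intensity)
})

test_that("R statistics match the hand-computed two-observation case", {
  sc <- data.table::data.table(serial = c(1L, 2L), h = 1L, k = 0L, l = 0L,
                               s = 0.01, intensity = c(10, 12), sigma = 1,
                               image = 1L)
  sc$key <- "1 0 0"
  rs <- isomerge:::r_statistics(sc)
  expect_equal(unname(rs["r_merge"]), 2 / 22, tolerance = 1e-9)
  expect_equal(unname(rs["r_meas"]), sqrt(2) * 2 / 22, tolerance = 1e-9)
  expect_equal(unname(rs["r_pim"]), 2 / 22, tolerance = 1e-9)
  expect_equal(unname(rs["r_merge"]), 0.0909, tolerance = 1e-3)
  expect_equal(unname(rs["r_meas"]), 0.1286, tolerance = 1e-3)
  # all singletons: R undefined
  sc1 <- sc[1]
  expect_true(all(is.na(isomerge:::r_statistics(sc1))))
})

test_that("completeness denominators match exhaustive enumeration", {
  p1 <- symmetry_ops("P1")
  cell <- unit_cell(10, 10, 10, 90, 90, 90)
  expect_equal(isomerge:::count_unique_reflections(cell, p1, 5),
               oracle_unique_count(cell, "P1", 5))
  p21 <- symmetry_ops("P21")
  cell2 <- unit_cell(12, 15, 11, 90, 95, 90)
  expect_equal(isomerge:::count_unique_reflections(cell2, p21, 3),
               oracle_unique_count(cell2, "P21", 3))
  expect_equal(isomerge:::count_unique_reflections(cell, p1, 3),
               oracle_unique_count(cell, "P1", 3))
})

test_that("merge statistics obey the weight inequalities and invariances", {
  cfg <- sim_config(n_groups = 1, n_per_group = 3, wedge_images = 10,
                    obs_per_image = 50, noise_frac = 0.1, d_min = 3.5,
                    cell_jitter = 0, seed = 31)
  truth <- ground_truth(cfg)
  grp <- lapply(1:3, function(i) simulate_dataset(cfg, i, truth))
  res <- merge_group(grp, keywords = keyword_set(tolerance = 100))
  st <- res$stats
  expect_gte(st$r_meas, st$r_merge)
  expect_gte(st$r_merge, st$r_pim)
  expect_gte(st$r_pim, 0)
  expect_true(st$completeness >= 0 && st$completeness <= 100)
  expect_gte(st$multiplicity, 1)
  expect_true(abs(st$cc_half) <= 1)
  # global rescaling of every dataset leaves the statistics unchanged
  grp2 <- lapply(grp, function(ds) {
    ds$observations$intensity <- ds$observations$intensity * 7
    ds$observations$sigma <- ds$observations$sigma * 7
    ds
  })
  st2 <- merge_group(grp2, keywords = keyword_set(tolerance = 100))$stats
  expect_equal(st2$r_merge, st$r_merge, tolerance = 1e-9)
  expect_equal(st2$r_meas, st$r_meas, tolerance = 1e-9)
  expect_equal(st2$completeness, st$completeness)
  expect_equal(st2$cc_half, st$cc_half, tolerance = 1e-9)
})

test_that("duplicating a dataset doubles multiplicity but not completeness", {
  cfg <- sim_config(n_groups = 1, n_per_group = 2, wedge_images = 8,
                    obs_per_image = 40, noise_frac = 0.05, cell_jitter = 0,
                    d_min = 3.5, seed = 13)
  truth <- ground_truth(cfg)
  grp <- lapply(1:2, function(i) simulate_dataset(cfg, i, truth))
  base <- merge_group(grp, keywords = keyword_set(tolerance = 100))
  dup <- grp[[2]]; dup$serial <- 3L
  more <- merge_group(c(grp, list(dup)), keywords = keyword_set(tolerance = 100))
  expect_equal(more$stats$completeness, base$stats$completeness)
  expect_gt(more$stats$multiplicity, base$stats$multiplicity)
  # identical duplicated observations correlate perfectly
  two <- merge_group(list(grp[[2]], dup), keywords = keyword_set(tolerance = 100))
  expect_equal(two$stats$cc_half, 1, tolerance = 1e-12)
  expect_equal(two$stats$r_merge, 0, tolerance = 1e-12)
})

test_that("merge_group honours tolerance, image ranges and resolution cuts", {
  cfg <- sim_config(n_groups = 2, n_per_group = 1, group_shift = 8,
                    wedge_images = 10, obs_per_image = 30, noise_frac = 0,
                    background_sigma = 0, d_min = 3.5, seed = 17)
  truth <- ground_truth(cfg)
  grp <- lapply(1:2, function(i) simulate_dataset(cfg, i, truth))
  expect_error(merge_group(grp, keywords = keyword_set(tolerance = 2)),
               "tolerance")
  kw <- keyword_set(tolerance = 100, resolution_high = 4.5)
  res <- merge_group(grp, keywords = kw,
                     accepted_ranges = list(`1` = c(1, 5), `2` = c(1, 10)))
  expect_true(all(res$scaled[serial == 1]$image <= 5))
  expect_true(all(res$scaled$s <= 1 / 4.5^2 + 1e-9))
  expect_equal(res$d_min, 4.5)
})
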
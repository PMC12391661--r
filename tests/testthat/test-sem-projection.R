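unit_cube_pore <- function(id = "cube", vol = NULL) {
  fake_pore(id, as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)),
            volume = vol)
}

test_that("volume-budgeted sampling honours the greedy stop rule", {
  pores <- lapply(1:5, function(i) unit_cube_pore(paste0("p", i), vol = 1e5))
  pol <- sampling_policy(volume_budget = 3e5, seed = 4)
  sel <- sample_pores_by_volume(pores, pol)
  expect_length(sel, 3)
  expect_equal(attr(sel, "total_volume"), 3e5)

  # budget not binding: everything selected
  small <- lapply(1:4, function(i) unit_cube_pore(paste0("s", i), vol = 10))
  expect_length(sample_pores_by_volume(small, pol), 4)

  # determinism and seed sensitivity
  ids <- function(x) vapply(x, `[[`, character(1), "track_id")
  pores2 <- lapply(1:30, function(i) unit_cube_pore(paste0("q", i),
                                                    vol = runif(1, 2e4, 9e4)))
  s1 <- sample_pores_by_volume(pores2, sampling_policy(seed = 9))
  s2 <- sample_pores_by_volume(pores2, sampling_policy(seed = 9))
  expect_identical(ids(s1), ids(s2))
  expect_lte(attr(s1, "total_volume"), 3e5)
  expect_length(sample_pores_by_volume(list(), pol), 0)
})

test_that("flattening projects the hull and keeps the closed CCW ring", {
  f <- flatten_pore(unit_cube_pore())
  expect_s3_class(f, "flat_pore")
  expect_equal(f$area, 1)
  expect_equal(f$diameter_2d, sqrt(2))
  expect_equal(f$centroid, c(0.5, 0.5))
  ring <- f$vertices_2d
  expect_equal(ring[1, ], ring[nrow(ring), ])

  octa <- fake_pore("octa", rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  fo <- flatten_pore(octa)
  expect_equal(fo$area, 2)           # projected square with diagonal 2
  expect_equal(fo$diameter_2d, 2)
})

test_that("flattening never increases the Feret diameter", {
  p <- diffusion_params(n_beads = 6, n_steps = 400, seed = 19)
  ps <- build_pore_models(simulate_confined(p, confine_sphere(9)))
  for (pm in ps$pores) {
    f <- flatten_pore(pm)
    expect_lte(f$diameter_2d, pm$diameter_raw + 1e-12)
  }
})

test_that("median flattened diameter underestimates the 3D corrected one", {
  pores <- list()
  for (i in seq_len(8)) {
    p <- diffusion_params(n_beads = 1, n_steps = 500, seed = 1000 + i)
    ps <- build_pore_models(simulate_confined(p, confine_sphere(4 + i)))
    pores <- c(pores, ps$pores)
  }
  d3 <- vapply(pores, `[[`, numeric(1), "diameter_corrected")
  d2 <- vapply(lapply(pores, flatten_pore), `[[`, numeric(1), "diameter_2d")
  expect_lt(median(d2), median(d3))
})

test_that("the resolution filter removes by diameter and area and is idempotent", {
  pores <- lapply(c(1, 2.5, 6), function(s) {
    fake_pore(paste0("s", s), as.matrix(expand.grid(0:1, 0:1, 0:1)) * s)
  })
  flats <- lapply(pores, flatten_pore)   # areas 1, 6.25, 36
  pol <- sampling_policy(min_diameter = 2, min_area = 10, seed = 1)
  kept <- apply_resolution_filter(flats, pol)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$source_track_id, "s6")
  expect_equal(unname(attr(kept, "removed")["area"]), 2L)
  again <- apply_resolution_filter(kept, pol)
  expect_equal(vapply(again, `[[`, character(1), "source_track_id"),
               vapply(kept, `[[`, character(1), "source_track_id"))

  # 9 um^2 pore removed at the 10 um^2 floor
  small <- flatten_pore(fake_pore("tiny", as.matrix(expand.grid(0:1, 0:1, 0:1)) * 3))
  expect_equal(small$area, 9)
  expect_length(apply_resolution_filter(list(small),
                                        sampling_policy(min_area = 10,
                                                        seed = 1)), 0)

  # zero thresholds are the identity
  pol0 <- sampling_policy(min_diameter = 0, min_area = 0, seed = 1)
  expect_length(apply_resolution_filter(flats, pol0), 3)
})

test_that("Mann-Whitney comparison reports U, p and medians", {
  x <- c(1, 2, 3)
  cmp <- compare_distributions(x, c(101, 102, 103))
  expect_equal(cmp$statistic, 0)    # complete separation: U = 0 for sample a
  expect_lt(cmp$p_value, 0.1)
  expect_equal(cmp$median_a, 2)
  expect_equal(cmp$median_b, 102)

  same <- compare_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.99)
  expect_error(compare_distributions(numeric(0), 1:3),
               class = "porehull_validation_error")
})

test_that("the test is calibrated under the null", {
  set.seed(303)
  pvals <- replicate(500, {
    compare_distributions(rlnorm(20, 2, 0.4), rlnorm(20, 2, 0.4))$p_value
  })
  # p should be ~uniform: check mass below 0.05 within 3 binomial SE
  frac <- mean(pvals < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
  expect_gt(mean(pvals), 0.42)
  expect_lt(mean(pvals), 0.58)
})
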
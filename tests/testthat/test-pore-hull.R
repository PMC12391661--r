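test_that("closed-form solids come out exactly", {
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  h <- convex_hull_3d(tetra)
  expect_equal(h$volume, 1 / 6)
  expect_equal(h$surface_area, 3 / 2 + sqrt(3) / 2)

  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  hc <- convex_hull_3d(cube)
  expect_equal(hc$volume, 1)
  expect_equal(hc$surface_area, 6)
  expect_equal(sort(hc$vertex_idx), 1:8)
})

test_that("hull volume of dense sphere samples converges from below", {
  set.seed(404)
  u <- matrix(rnorm(3e4), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 5 * runif(1e4)^(1 / 3)  # uniform in ball r=5
  h <- convex_hull_3d(u)
  v_true <- 4 / 3 * pi * 125
  expect_lt(h$volume, v_true)
  expect_gt(h$volume, 0.95 * v_true)
})

test_that("small random clouds match the brute-force polytope oracle", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(5:12, 1)
    pts <- matrix(runif(3 * n, -4, 4), ncol = 3)
    h <- convex_hull_3d(pts)
    o <- oracle_hull_3d(pts)
    expect_equal(h$volume, o$volume, tolerance = 1e-9)
    expect_equal(h$surface_area, o$surface_area, tolerance = 1e-9)
    expect_equal(h$vertex_idx, o$vertex_idx)
  }
})

test_that("every input point lies inside or on its hull", {
  for (s in 1:5) {
    set.seed(100 + s)
    pts <- matrix(rnorm(3 * 200), ncol = 3)
    h <- convex_hull_3d(pts)
    d <- pts %*% t(h$face_normals) -
      rep(h$face_offsets, each = nrow(pts))
    expect_lt(max(d), 1e-9)
  }
})

test_that("adding points never shrinks hull volume or Feret diameter", {
  set.seed(11)
  pts <- matrix(rnorm(3 * 60), ncol = 3)
  h1 <- convex_hull_3d(pts[1:30, ])
  h2 <- convex_hull_3d(pts)
  expect_gte(h2$volume, h1$volume)
  expect_gte(feret_diameter(h2, pts), feret_diameter(h1, pts[1:30, ]))
})

test_that("Feret diameter is the max pairwise vertex distance", {
  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  expect_equal(feret_diameter(convex_hull_3d(cube), cube), sqrt(3))
  expect_equal(feret_diameter(rbind(c(0, 0, 0), c(7, 0, 0))), 7)
  th <- 2 * pi * (0:5) / 6
  hexa <- cbind(cos(th), sin(th))   # regular hexagon, side 1
  expect_equal(feret_diameter(convex_hull_2d(hexa)), 2)
})

test_that("bead correction adds exactly one bead diameter", {
  expect_equal(correct_for_bead(8, 2), 10)
  expect_equal(correct_for_bead(10, 0), 10)
  expect_equal(correct_for_bead(10, 0.5), 10.5)
  expect_error(correct_for_bead(-1, 2), class = "porehull_domain_error")
})

test_that("sphericity matches closed forms and is bounded by 1", {
  r <- 3.7
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6)
  expect_equal(sphericity(1, 6), 0.806, tolerance = 1e-3)
  expect_equal(sphericity(10, 42), pi^(1 / 3) * 60^(2 / 3) / 42)
  expect_error(sphericity(0, 6), class = "porehull_domain_error")
  # random hulls: always <= 1
  for (s in 1:5) {
    set.seed(s)
    h <- convex_hull_3d(matrix(rnorm(45), ncol = 3))
    expect_lte(sphericity(h$volume, h$surface_area), 1)
  }
})

test_that("sphericity of sphere-sampled clouds increases toward 1", {
  sph_at <- function(n, seed) {
    set.seed(seed)
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * 5
    h <- convex_hull_3d(u)
    sphericity(h$volume, h$surface_area)
  }
  s_small <- sph_at(40, 2)
  s_big <- sph_at(2000, 2)
  expect_gt(s_big, s_small)
  expect_gt(s_big, 0.99)
})

test_that("xy-projection never increases the Feret diameter", {
  for (s in 1:5) {
    set.seed(50 + s)
    pts <- matrix(rnorm(3 * 50, sd = 3), ncol = 3)
    h3 <- convex_hull_3d(pts)
    d3 <- feret_diameter(h3, pts)
    h2 <- convex_hull_2d(pts[, 1:2])
    expect_lte(feret_diameter(h2), d3 + 1e-12)
  }
})

test_that("degenerate clouds are refused, not silently projected", {
  flat3 <- cbind(matrix(runif(20), ncol = 2), 1)  # coplanar z = 1
  expect_error(convex_hull_3d(flat3), class = "porehull_degenerate")
  line2 <- cbind(1:5, 2 * (1:5))
  expect_error(convex_hull_2d(line2), class = "porehull_degenerate")
  expect_error(convex_hull_3d(matrix(0, 3, 3)),
               class = "porehull_validation_error")
})

test_that("build_pore_models quantifies eligible tracks and logs skips", {
  p <- diffusion_params(n_beads = 3, n_steps = 300, seed = 8)
  ts <- simulate_confined(p, confine_sphere(9))
  # append a short track and a degenerate (collinear) one
  extra <- data.frame(
    track_id = rep(c("short", "flat"), c(3, 12)),
    t = c(0:2 * 5, 0:11 * 5),
    x = c(0, 1, 2, seq(0, 11)), y = 0, z = 0)
  ts$data <- rbind(ts$data, extra)
  ps <- build_pore_models(ts)
  expect_length(ps$pores, 3)
  expect_setequal(ps$skipped$track_id, c("short", "flat"))
  expect_equal(ps$skipped$reason[ps$skipped$track_id == "short"], "too_short")
  expect_equal(ps$skipped$reason[ps$skipped$track_id == "flat"], "degenerate")
  df <- as.data.frame(ps)
  expect_equal(df$diameter_corrected, df$diameter_raw + ts$bead_diameter)
  expect_true(all(df$sphericity > 0 & df$sphericity <= 1))
  # hull vertices are a subset of the track's localizations
  for (pm in ps$pores) {
    trk <- ts$data[ts$data$track_id == pm$track_id, c("x", "y", "z")]
    match_rows <- apply(pm$vertices, 1, function(v) {
      any(abs(trk$x - v[1]) < 1e-12 & abs(trk$y - v[2]) < 1e-12 &
            abs(trk$z - v[3]) < 1e-12)
    })
    expect_true(all(match_rows))
  }
})

test_that("planar track sets give 2D pore models without sphericity", {
  p <- diffusion_params(n_beads = 3, n_steps = 200, seed = 12)
  panel <- simulate_microwell_panel(30, p)
  ps <- build_pore_models(panel[["30"]])
  df <- as.data.frame(ps)
  expect_equal(unique(df$dims), 2L)
  expect_true(all(is.na(df$sphericity)))
  expect_true(all(df$volume > 0))          # area in 2D
  expect_true(all(df$surface_area > 0))    # perimeter in 2D
})
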
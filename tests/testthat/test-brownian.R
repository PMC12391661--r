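test_that("Stokes-Einstein evaluates and scales as expected", {
  D <- stokes_einstein(300, 0.001, 0.5e-6)
  expect_equal(D, 1.38e-23 * 300 / (6 * pi * 0.001 * 0.5e-6),
               tolerance = 1e-12)
  expect_equal(D * 1e12, 0.439, tolerance = 1e-3)        # um^2/s
  expect_equal(stokes_einstein(300, 0.001, 1e-6), D / 2) # 1/r
  expect_equal(stokes_einstein(600, 0.001, 0.5e-6), D * 2) # linear in T
  expect_error(stokes_einstein(-300, 0.001, 1e-6),
               class = "porehull_domain_error")
})

test_that("the simulator is deterministic in its seed", {
  p <- diffusion_params(n_beads = 3, n_steps = 10, seed = 5)
  expect_identical(simulate_free(p), simulate_free(p))
  expect_false(identical(simulate_free(p)$data,
                         simulate_free(diffusion_params(
                           n_beads = 3, n_steps = 10, seed = 6))$data))
  g <- confine_sphere(9)
  expect_identical(simulate_confined(p, g), simulate_confined(p, g))
})

test_that("free diffusion matches 2*D*k*dt per-axis variance within 3 SE", {
  p <- diffusion_params(n_beads = 1000, n_steps = 10, seed = 21)
  D <- stokes_einstein(p$temperature, p$viscosity, p$bead_radius) * 1e12
  ts <- simulate_free(p)
  d <- ts$data
  for (k in c(5, 10)) {
    at_k <- d[d$t == k * p$frame_interval, ]
    v <- var(at_k$x)   # per-axis displacement variance from a zero origin
    expected <- 2 * D * k * p$frame_interval
    se <- expected * sqrt(2 / (nrow(at_k) - 1))
    expect_lt(abs(v - expected), 3 * se)
  }
})

test_that("free-diffusion ensemble MSD is ~6Dt and ~13.2 um^2 at t = 5 s", {
  p <- diffusion_params(n_beads = 1000, n_steps = 30, seed = 22)
  D <- stokes_einstein(p$temperature, p$viscosity, p$bead_radius) * 1e12
  curve <- compute_msd(simulate_free(p))
  m5 <- curve$msd[curve$t == 5]
  expect_equal(m5, 6 * D * 5, tolerance = 3 * sqrt(2 / 1000)) # 3 SE relative
  expect_equal(m5, 13.2, tolerance = 0.15)
  fit <- lm(msd ~ 0 + t, data = curve)
  expect_equal(unname(coef(fit)), 6 * D, tolerance = 0.1)
})

test_that("confined walks never leave the bead-accessible region", {
  p <- diffusion_params(n_beads = 3, n_steps = 400, seed = 31)
  r_bead <- p$bead_radius * 1e6
  cases <- list(
    sphere = confine_sphere(6),
    cylinder = confine_cylinder(8, depth = 12),
    box = confine_box(c(4, 5, 6)),
    polyhedron = confine_polyhedron(rbind(
      c(6, 0, 0), c(-6, 0, 0), c(0, 6, 0), c(0, -6, 0), c(0, 0, 6),
      c(0, 0, -6)))
  )
  for (nm in names(cases)) {
    g <- cases[[nm]]
    ts <- simulate_confined(p, g)
    d <- ts$data
    ok <- switch(nm,
      sphere = all(sqrt(d$x^2 + d$y^2 + d$z^2) <= g$radius - r_bead + 1e-9),
      cylinder = all(sqrt(d$x^2 + d$y^2) <= g$radius - r_bead + 1e-9) &&
        all(abs(d$z) <= g$depth / 2 - r_bead + 1e-9),
      box = all(abs(d$x) <= 4 - r_bead + 1e-9) &&
        all(abs(d$y) <= 5 - r_bead + 1e-9) &&
        all(abs(d$z) <= 6 - r_bead + 1e-9),
      polyhedron = {
        pl <- g$hull
        pos <- as.matrix(d[, c("x", "y", "z")])
        all(pos %*% t(pl$face_normals) -
              rep(pl$face_offsets - r_bead, each = nrow(pos)) <= 1e-9)
      })
    expect_true(ok, label = sprintf("confinement respected in %s", nm))
  }
})

test_that("a bead larger than the geometry is rejected", {
  p <- diffusion_params(bead_radius = 5e-6, n_beads = 1, n_steps = 5)
  expect_error(simulate_confined(p, confine_sphere(4)),
               class = "porehull_infeasible_geometry")
})

test_that("confined MSD plateaus while free MSD keeps growing", {
  p <- diffusion_params(n_beads = 50, n_steps = 600, seed = 41)
  conf <- compute_msd(simulate_confined(p, confine_sphere(9)))
  tmax <- max(conf$t)
  mid <- mean(conf$msd[conf$t >= 0.25 * tmax & conf$t < 0.5 * tmax])
  late <- mean(conf$msd[conf$t >= 0.75 * tmax])
  expect_lt(late / mid, 1.5)   # bounded: no further growth after saturation
  free <- compute_msd(simulate_free(p))
  mid_f <- mean(free$msd[free$t >= 0.25 * tmax & free$t < 0.5 * tmax])
  late_f <- mean(free$msd[free$t >= 0.75 * tmax])
  expect_gt(late_f / mid_f, 1.8)  # linear growth roughly doubles it
})

test_that("microwell panels are per-well planar and element-wise reproducible", {
  p <- diffusion_params(n_beads = 2, n_steps = 50, seed = 77)
  panel <- simulate_microwell_panel(c(9, 30, 250), p)
  expect_named(panel, c("9", "30", "250"))
  expect_true(all(vapply(panel, function(ts) ts$dims == 2L, logical(1))))
  expect_true(all(panel[["30"]]$data$z == 0))
  # radial confinement of the accessible disk
  d9 <- panel[["9"]]$data
  expect_true(all(sqrt(d9$x^2 + d9$y^2) <= 9 / 2 - 0.5 + 1e-9))
  # element-wise: same well from a fresh panel is identical
  panel2 <- simulate_microwell_panel(c(9, 30, 250), p)
  expect_identical(panel[["250"]], panel2[["250"]])
  expect_identical(simulate_microwell_panel(numeric(0), p),
                   structure(list(), names = character(0)))
})
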
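test_that("polygon centroid matches closed forms and its oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(polygon_centroid(sq), c(0.5, 0.5))
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1), c(0, 0))
  expect_equal(polygon_centroid(tri), c(1 / 3, 1 / 3))
  set.seed(5)
  for (i in 1:20) {
    ring <- random_convex_ring(sample(5:9, 1))
    expect_equal(polygon_centroid(ring), oracle_centroid(ring),
                 tolerance = 1e-9)
  }
})

test_that("centroid refuses clockwise or open rings", {
  cw <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 0))
  expect_error(polygon_centroid(cw), class = "porehull_orientation_error")
  open_ring <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_error(polygon_centroid(open_ring),
               class = "porehull_orientation_error")
})

test_that("small packings are tangent and centred as specified", {
  one <- pack_circles(4)
  expect_equal(c(one$x, one$y), c(0, 0))
  two <- pack_circles(c(4, 6))
  expect_equal(sqrt(diff(two$x)^2 + diff(two$y)^2), 2 + 3)
  expect_error(pack_circles(c(3, -1)), class = "porehull_domain_error")
  expect_equal(nrow(pack_circles(numeric(0))), 0)
})

test_that("packing is deterministic and order-sensitive as documented", {
  set.seed(8)
  d <- runif(40, 2, 20)
  expect_identical(pack_circles(d), pack_circles(d))
  a <- audit_packing(pack_circles(d))
  expect_equal(a$overlaps, 0L)
  expect_equal(a$untouched, 0L)
})

test_that("50 mixed circles pack without overlap and fully tangent", {
  set.seed(99)
  d <- c(runif(25, 1, 5), runif(25, 10, 40))
  a <- audit_packing(pack_circles(d))
  expect_equal(a$overlaps, 0L)
  expect_equal(a$untouched, 0L)
})

test_that("repositioning is a rigid translation", {
  f <- flatten_pore(fake_pore("cube", as.matrix(expand.grid(0:1, 0:1, 0:1))))
  same <- reposition_pore(f, f$centroid)
  expect_equal(same$vertices_2d, f$vertices_2d)
  moved <- reposition_pore(f, c(10, 10))
  expect_equal(moved$centroid, c(10, 10))
  expect_equal(moved$vertices_2d, f$vertices_2d + 9.5)
  expect_equal(moved$area, f$area)
  expect_equal(moved$diameter_2d, f$diameter_2d)
  # centroid recomputed from the translated ring agrees
  expect_equal(polygon_centroid(moved$vertices_2d), c(10, 10))
})

test_that("fixed-gap layout spaces bounding boxes along x", {
  f <- flatten_pore(fake_pore("cube", as.matrix(expand.grid(0:1, 0:1, 0:1))))
  lay <- layout_pores(list(f, f), mode = "fixed_gap", gap = 10)
  cx <- vapply(lay$pores, function(p) p$centroid[1], numeric(1))
  expect_equal(diff(cx), 11)  # 1 um width + 10 um gap
  # gap measured between boxes
  x1max <- max(lay$pores[[1]]$vertices_2d[, 1])
  x2min <- min(lay$pores[[2]]$vertices_2d[, 1])
  expect_equal(x2min - x1max, 10)
})

test_that("packed layout puts every centroid on its placeholder circle", {
  set.seed(12)
  flats <- lapply(1:12, function(i) {
    s <- runif(1, 1, 6)
    flatten_pore(fake_pore(paste0("c", i),
                           as.matrix(expand.grid(0:1, 0:1, 0:1)) * s))
  })
  lay <- layout_pores(flats, mode = "packed")
  expect_equal(lay$placements$r,
               vapply(flats, `[[`, numeric(1), "diameter_2d") / 2)
  for (i in seq_along(flats)) {
    expect_equal(lay$pores[[i]]$centroid,
                 c(lay$placements$x[i], lay$placements$y[i]))
    expect_equal(lay$pores[[i]]$area, flats[[i]]$area)
  }
  a <- audit_packing(lay$placements)
  expect_equal(a$overlaps, 0L)
  expect_error(layout_pores(list()), class = "porehull_validation_error")
})

test_that("rendering writes SVG and PNG files", {
  f <- flatten_pore(fake_pore("cube", as.matrix(expand.grid(0:1, 0:1, 0:1))))
  lay <- layout_pores(list(f, f, f), mode = "packed")
  svg <- withr::local_tempfile(fileext = ".svg")
  render_layout(lay, svg)
  txt <- readLines(svg)
  expect_equal(sum(grepl("<polygon", txt)), 3)
  expect_true(any(grepl("10 um", txt)))   # scale bar label

  # empty layout still yields a canvas with a scale bar
  svg2 <- withr::local_tempfile(fileext = ".svg")
  render_layout(list(), svg2)
  expect_true(any(grepl("<line", readLines(svg2))))

  png <- withr::local_tempfile(fileext = ".png")
  render_layout(lay, png)
  expect_gt(file.size(png), 0)
  expect_error(render_layout(lay, withr::local_tempfile(fileext = ".pdf")),
               class = "porehull_io_error")
})
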
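test_that("relativistic velocity matches closed forms", {
  cc <- pgt_constants()$c
  expect_identical(velocity(0), 0)
  # E = m_p c^2 means gamma = 2, v = sqrt(3)/2 c
  expect_equal(velocity(938.272), sqrt(3) / 2 * cc, tolerance = 1e-12)
  # one-line independent evaluation at a therapeutic energy
  oracle <- cc * sqrt(1 - (1 + 230 / 938.272)^-2)
  expect_equal(velocity(230), oracle, tolerance = 1e-12)
  expect_true(oracle / cc > 0.59 && oracle / cc < 0.60)
  E <- seq(0, 300, by = 10)
  expect_true(all(diff(velocity(E)) > 0))
  expect_true(all(velocity(E) < cc))
  expect_error(velocity(-1), "E >= 0")
})

test_that("energy at depth matches the 1-um Euler oracle", {
  ph <- phantom_homogeneous("water", 500)
  expect_equal(energy_at_depth(ph, 230, 0), 230)
  zhalf <- csda_range(ph, 230) / 2
  expect_equal(energy_at_depth(ph, 230, zhalf),
               oracle_energy(ph, 230, zhalf), tolerance = 0.01 / 230)
  # heterogeneous 3-slice phantom
  ph3 <- layered_phantom(list(slice("pmma", 80), slice("cortical_bone", 30),
                              slice("pmma", 200)))
  for (z in c(50, 100, 170)) {
    expect_equal(energy_at_depth(ph3, 200, z), oracle_energy(ph3, 200, z),
                 tolerance = 0.01 / 200)
  }
  # non-increasing in z, zero beyond the range
  z <- seq(0, 300, by = 5)
  E <- energy_at_depth(ph3, 200, z)
  expect_true(all(diff(E) <= 0))
  expect_identical(E[z > csda_range(ph3, 200)],
                   rep(0, sum(z > csda_range(ph3, 200))))
})

test_that("energy is nearly flat across an air slice", {
  ph <- layered_phantom(list(slice("pmma", 100), slice("air", 20),
                             slice("pmma", 200)))
  E_in <- energy_at_depth(ph, 230, 100)
  E_out <- energy_at_depth(ph, 230, 120)
  expect_lt((E_in - E_out) / E_in, 0.002)
})

test_that("CSDA range: closed form, insert arithmetic, limits", {
  ph <- phantom_homogeneous("water", 500)
  w <- pgt_material("water")
  expect_equal(csda_range(ph, 230), w$bk_alpha * 230^w$bk_p, tolerance = 0.1)
  expect_equal(csda_range(ph, 100), w$bk_alpha * 100^w$bk_p, tolerance = 0.1)
  # air cavity extends the range by its own thickness
  p0 <- phantom_homogeneous("pmma", 400)
  pc <- phantom_with_insert("pmma", 400, "air", f = 169, h = 5)
  d <- csda_range(pc, 230) - csda_range(p0, 230)
  expect_gt(d, 4.9); expect_lt(d, 5.1)
  # denser bone shortens the range
  pb <- phantom_with_insert("pmma", 400, "cortical_bone", f = 169, h = 20)
  expect_lt(csda_range(pb, 230), csda_range(p0, 230))
  expect_identical(csda_range(ph, 0.5), 0)
  expect_error(csda_range(ph, 350), "validity")
  expect_warning(csda_range(phantom_homogeneous("water", 10), 230), "exit")
})

test_that("transit time matches the 1-um trapezoid oracle within 1 ps", {
  ph <- phantom_homogeneous("water", 500)
  R <- csda_range(ph, 230)
  expect_identical(transit_time(ph, 230, 0), 0)
  expect_equal(transit_time(ph, 230, R), oracle_transit(ph, 230, R),
               tolerance = 1e-3 / 2.4)
  ph3 <- layered_phantom(list(slice("pmma", 80), slice("air", 15),
                              slice("cortical_bone", 25), slice("pmma", 200)))
  for (z in c(60, 90, 110, 200)) {
    expect_equal(transit_time(ph3, 210, z), oracle_transit(ph3, 210, z),
                 tolerance = 1e-3 / oracle_transit(ph3, 210, z))
  }
  z <- seq(10, 240, by = 20)
  expect_true(all(diff(transit_time(ph3, 210, z)) > 0))
  expect_error(transit_time(ph, 230, R + 5), "attainable")
})

test_that("velocity is locally constant across an air cavity", {
  ph <- layered_phantom(list(slice("pmma", 100), slice("air", 30),
                             slice("pmma", 200)))
  # dt/dz inside the cavity varies by < 0.5%
  zg <- seq(101, 129, by = 2)
  dt <- diff(transit_time(ph, 230, zg))
  expect_lt((max(dt) - min(dt)) / min(dt), 0.005)
})

test_that("depth_at_time inverts transit_time", {
  ph3 <- layered_phantom(list(slice("pmma", 120), slice("air", 10),
                              slice("pmma", 250)))
  R <- csda_range(ph3, 230)
  tmax <- transit_time(ph3, 230, R)
  expect_identical(depth_at_time(ph3, 230, 0), 0)
  expect_equal(depth_at_time(ph3, 230, tmax), R, tolerance = 1e-6)
  set.seed(42)
  zs <- runif(100, 0, R)
  back <- depth_at_time(ph3, 230, transit_time(ph3, 230, zs))
  expect_lt(max(abs(back - zs)), 0.01)
  expect_error(depth_at_time(ph3, 230, tmax + 1), "attainable")
})

test_that("phantom structure: length conservation, half-open slices, file round trip", {
  ph <- layered_phantom(list(slice("pmma", 169.25), slice("air", 5),
                             slice("pmma", 225.75)))
  expect_identical(phantom_length(ph), 400)
  expect_identical(material_at(ph, 169.25)$name, "air")   # boundary is downstream
  expect_identical(material_at(ph, 174.25)$name, "pmma")
  expect_error(material_at(ph, 400), "outside")
  tmp <- tempfile(fileext = ".txt")
  write_phantom(ph, tmp)
  ph2 <- read_phantom(tmp)
  expect_equal(ph2$boundaries, ph$boundaries, tolerance = 1e-15)
  expect_identical(material_name_at(ph2, c(0, 170, 300)),
                   c("pmma", "air", "pmma"))
  empty <- tempfile(); writeLines("# only a comment", empty)
  expect_error(read_phantom(empty), "no slices")
  bad <- tempfile(); writeLines("pmma ten", bad)
  expect_error(read_phantom(bad), "thickness")
})

test_that("first_divergence locates an insert", {
  p0 <- phantom_homogeneous("pmma", 400)
  pc <- phantom_with_insert("pmma", 400, "air", f = 169, h = 5)
  expect_identical(first_divergence(p0, pc), 169)
  expect_null(first_divergence(p0, p0))
})
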
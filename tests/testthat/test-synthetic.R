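test_that("rendering is a pure function of parameters and seed", {
  s1 <- small_section(seed = 33)
  s2 <- small_section(seed = 33)
  s3 <- small_section(seed = 34)
  expect_identical(s1$image, s2$image)
  expect_false(identical(s1$image, s3$image))
})

test_that("ground truth bookkeeping records borders and labels", {
  sec <- small_section(seed = 2, areas = list(area_low_iv, area_high_iv),
                       borders = 150)
  expect_equal(sec$truth_borders_um, 150)
  expect_equal(sec$truth_labels$arc_from_um, c(0, 150))
  expect_equal(sec$truth_labels$area, 1:2)
})

test_that("invalid geometry and borders are rejected", {
  geo <- flat_ribbon(300, 150, 1.5)
  expect_error(render_section(geo, list(area_low_iv, area_high_iv, area_low_iv),
                              c(200, 100)),
               "strictly increasing")
  expect_error(render_section(geo, list(area_low_iv, area_high_iv), 400),
               "strictly increasing|inside")
  expect_error(render_section(geo, list(area_low_iv), numeric(0),
                              margin_px = 0) -> x, NA)
  # intersecting contours refused at geometry construction
  expect_error(ribbon_geometry(cbind(c(0, 100), c(0, 100)),
                               cbind(c(0, 100), c(100, 0))),
               "intersect")
})

test_that("foreground fraction of a homogeneous band converges to the density", {
  for (dens in c(0.2, 0.5)) {
    spec <- laminar_spec(rep(1 / 6, 6), rep(dens, 6))
    sec <- render_section(flat_ribbon(500, 250, pixel_size_um = 1),
                          list(spec), seed = 7, noise_sd = 0)
    seg <- segment_cell_bodies(sec, "fixed", threshold = 0.5)
    frame <- cytoborder:::ribbon_pixel_frame(sec$geometry, ncol(sec$image),
                                             nrow(sec$image), 1)
    inside <- matrix(frame$inside, nrow(sec$image), ncol(sec$image))
    expect_gt(sum(inside), 1e5)
    frac <- mean(seg$pixels[inside])
    expect_lt(abs(frac - dens), 0.03)
  }
})

test_that("stacks jitter borders within the stated bound and reproduce", {
  geo <- flat_ribbon(300, 150, 1.5)
  st0 <- make_stack(geo, list(area_low_iv, area_high_iv), 150,
                    n_sections = 4, border_jitter_um = 0, seed = 5)
  expect_true(all(sapply(st0, function(s) s$truth_borders_um) == 150))
  st <- make_stack(geo, list(area_low_iv, area_high_iv), 150,
                   n_sections = 5, border_jitter_um = 50, seed = 5)
  pos <- sapply(st, function(s) s$truth_borders_um)
  expect_true(all(abs(pos - 150) <= 50))
  st2 <- make_stack(geo, list(area_low_iv, area_high_iv), 150,
                    n_sections = 5, border_jitter_um = 50, seed = 5)
  expect_identical(lapply(st, `[[`, "image"), lapply(st2, `[[`, "image"))
  expect_equal(sapply(st, `[[`, "section_id"), 1:5)
})

test_that("profile-level simulator respects truth and determinism", {
  st <- simulate_profile_stack(list(area_low_iv, area_high_iv), 60, 30L,
                               n_sections = 4, jitter_profiles = 2, seed = 9)
  expect_length(st, 4)
  pos <- sapply(st, function(s) s$truth_borders)
  expect_true(all(abs(pos - 30) <= 2))
  st2 <- simulate_profile_stack(list(area_low_iv, area_high_iv), 60, 30L,
                                n_sections = 4, jitter_profiles = 2, seed = 9)
  expect_identical(lapply(st, `[[`, "values"), lapply(st2, `[[`, "values"))
  expect_true(all(st[[1]]$values >= 0 & st[[1]]$values <= 1))
})

test_that("cohorts honour variability, sex design and shrinkage realism", {
  co0 <- make_cohort(n_subjects = 4, area_shape_variability = 0, seed = 3)
  expect_identical(co0$subjects[[1]], co0$subjects[[3]])
  expect_equal(as.character(co0$sex), c("male", "female", "male", "female"))
  co <- make_cohort(n_subjects = 10, seed = 3)
  expect_equal(sum(co$sex == "male"), 5)
  expect_true(all(co$volumes$fresh_volume_mm3 >= co$volumes$processed_volume_mm3))
  expect_true(all(co$volumes$shrinkage_factor >= 1.5 &
                    co$volumes$shrinkage_factor <= 2.5))
  expect_true(all(unlist(lapply(co$subjects, unique)) %in% c(0, co$area_ids)))
  co2 <- make_cohort(n_subjects = 10, seed = 3)
  expect_identical(co$subjects, co2$subjects)
  expect_error(make_cohort(n_subjects = 1), ">= 2")
})

test_that("ground-truth borders agree between arc length and profile index", {
  geo <- flat_ribbon(400, 120, 2)
  sec <- render_section(geo, list(area_low_iv, area_high_iv), 200, seed = 4)
  fld <- solve_laplace(geo, grid_res_um = 6, tol = 1e-5)
  trs <- trace_traverses(fld, n_traverses = 40)
  idx <- arclength_to_traverse(sec$truth_borders_um, trs)
  seeds <- sapply(trs$traverses, `[[`, "seed_arclength_um")
  # the mapped traverse's seed must be the nearest one to the true position
  expect_lt(abs(seeds[idx] - 200), diff(seeds)[1])
})
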
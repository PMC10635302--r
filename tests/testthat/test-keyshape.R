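test_that("key-shape membership: keyhole and noise holes are empty", {
  spec <- key_shape_spec()
  cl <- sample_key_cloud(spec, 2000, 1, "none", seed = 1)
  expect_true(all(key_region_contains(spec, cl$points, "none")))
  r2 <- (cl$points[, 1] - spec$head_center[1])^2 +
    (cl$points[, 2] - spec$head_center[2])^2
  expect_equal(sum(r2 < spec$keyhole_radius^2), 0L)
  # noise variant: its small disc is empty, keyhole still empty
  cn <- sample_key_cloud(spec, 2000, 1, "noise_2", seed = 2)
  site <- spec$noise_hole_sites[2, ]
  d2 <- (cn$points[, 1] - site[1])^2 + (cn$points[, 2] - site[2])^2
  expect_equal(sum(d2 <= spec$noise_hole_radius^2), 0L)
  # invariant: noise hole much smaller than keyhole
  expect_lt(spec$noise_hole_radius, spec$keyhole_radius / 3)
  expect_error(key_shape_spec(noise_hole_radius = 0.05), "third")
})

test_that("fraction handling: off-shape points, rounding half up, determinism", {
  spec <- key_shape_spec()
  all_off <- sample_key_cloud(spec, 50, 0, "none", seed = 3)
  expect_equal(nrow(all_off$points), 50L)
  # 95% of 100 is exactly 95 on-shape points
  cl95 <- sample_key_cloud(spec, 100, 0.95, "none", seed = 4)
  on <- key_region_contains(spec, cl95$points, "none")
  expect_equal(sum(on[1:95]), 95L)
  # round-half-up: 0.5 * 5 -> 3 on-shape
  cl5 <- sample_key_cloud(spec, 5, 0.5, "none", seed = 5)
  expect_true(all(key_region_contains(spec, cl5$points[1:3, ], "none")))
  # determinism and seed sensitivity
  a <- sample_key_cloud(spec, 40, 1, "none", seed = 6)
  b <- sample_key_cloud(spec, 40, 1, "none", seed = 6)
  c <- sample_key_cloud(spec, 40, 1, "none", seed = 7)
  expect_identical(a$points, b$points)
  expect_false(isTRUE(all.equal(a$points, c$points)))
})

test_that("keyhole dominates the dimension-1 diagram of full key clouds", {
  spec <- key_shape_spec()
  ratios <- vapply(1:40, function(s) {
    cl <- sample_key_cloud(spec, 100, 1, "none", seed = 1000 + s)
    p <- rips_diagram(cl, 1)$dim1$points
    pers <- sort(p[, 2] - p[, 1], decreasing = TRUE)
    pers[1] / pers[2]
  }, 0)
  expect_gte(mean(ratios > 3), 0.95)
})

test_that("quarter variants change geometry but not first-homology rank", {
  spec <- key_shape_spec()
  for (q in 1:4) {
    v <- paste0("quarter_", q)
    cl <- sample_key_cloud(spec, 150, 1, v, seed = 20 + q)
    expect_true(all(key_region_contains(spec, cl$points, v)))
    # most of the keyhole disc is filled under the variant
    th <- seq(0, 2 * pi, length.out = 400)
    ring <- cbind(spec$head_center[1] + 0.06 * cos(th),
                  spec$head_center[2] + 0.06 * sin(th))
    inside <- key_region_contains(spec, ring, v)
    expect_equal(mean(inside), 0.75, tolerance = 0.02)
  }
  # retained quarters partition the keyhole boundary
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  ring <- cbind(spec$head_center[1] + 0.06 * cos(th),
                spec$head_center[2] + 0.06 * sin(th))
  counts <- rowSums(!vapply(1:4, function(q)
    key_region_contains(spec, ring, paste0("quarter_", q)), logical(401 - 1)))
  expect_true(all(counts == 1))
})

test_that("two-sample settings compose the groups the designs prescribe", {
  spec <- key_shape_spec()
  s <- make_two_sample_setting("power", 5, 5, 100, seed = 31, spec = spec)
  expect_length(s$groupA, 5); expect_length(s$groupB, 5)
  # group 1 clouds are rectangle-only (not constrained to the shape)
  onA <- mean(key_region_contains(spec, do.call(rbind, lapply(s$groupA, `[[`, "points")), "none"))
  expect_lt(onA, 0.6)
  onB <- vapply(s$groupB, function(cl)
    all(key_region_contains(spec, cl$points, "none")), TRUE)
  expect_true(all(onB))

  sn <- make_two_sample_setting("noise_fixed", 4, 4, 100, seed = 32, spec = spec)
  site <- spec$noise_hole_sites[1, ]
  for (cl in sn$groupB) {
    d2 <- (cl$points[, 1] - site[1])^2 + (cl$points[, 2] - site[2])^2
    expect_equal(sum(d2 <= spec$noise_hole_radius^2), 0L)
  }
  expect_error(make_two_sample_setting("bogus", 5, 5), "valid")
  expect_error(make_two_sample_setting("power", 0, 5), "positive")
})

test_that("three-group settings compose the groups the designs prescribe", {
  spec <- key_shape_spec()
  s <- make_anova_setting("sensitivity", 5, 5, 5, 100, seed = 41, spec = spec)
  expect_equal(lengths(s), c(5L, 5L, 5L))
  on3 <- vapply(s[[3]], function(cl)
    all(key_region_contains(spec, cl$points, "none")), TRUE)
  expect_true(all(on3))
  sn <- make_anova_setting("noise_random", 5, 20, 100, 100, seed = 42,
                           spec = spec, n_points = 30)
  expect_equal(lengths(sn), c(5L, 20L, 100L))
  expect_error(make_anova_setting("sensitivity", 0, 5, 5), "positive")
  expect_error(make_anova_setting("nope", 5, 5, 5), "valid")
})

test_that("simulation study driver: single-simulation table and summary", {
  bas <- tiny_basis()
  sp <- list(design = "power", test = "two_sample", sizes = c(3, 3),
             percentage = 100, sigma = 0.1, kappa = bas$kappa, steps = 500,
             n_points = 40)
  res <- run_simulation_study(sp, n_sims = 1, seed = 51, basis = bas)
  expect_equal(nrow(res), 1L)
  s <- attr(res, "summary")
  expect_true(is.na(s$sd_p))
  res2 <- run_simulation_study(sp, n_sims = 2, seed = 52, basis = bas)
  expect_equal(nrow(res2), 2L)
  expect_false(is.na(attr(res2, "summary")$sd_p))
  expect_true(all(res2$p_value > 0 & res2$p_value <= 1))
  # determinism under the master seed
  res3 <- run_simulation_study(sp, n_sims = 2, seed = 52, basis = bas)
  expect_identical(res2$p_value, res3$p_value)
})
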
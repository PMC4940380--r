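test_that("a deterministic uniform field gives a straight line to mask exit", {
  f <- uniform_field(c(12L, 12L, 12L), dir = c(0, 0, 1), kappa = Inf)
  sl <- propagate(f, c(5, 5, 1), tracking_params(step_mm = 0.5), seed = 1)
  expect_equal(sl$reason, "mask-exit")
  expect_true(all(abs(sl$points[, 1] - 5) < 1e-12))
  expect_true(all(abs(sl$points[, 2] - 5) < 1e-12))
  expect_true(all(diff(sl$points[, 3]) > 0))
  # consecutive points are step_mm apart
  steps <- sqrt(rowSums(diff(sl$points)^2))
  expect_equal(steps, rep(0.5, length(steps)), tolerance = 1e-12)
  expect_gte(nrow(sl$points), 2)
})

test_that("turns sharper than the curvature limit terminate the streamline", {
  # abrupt change from +z to a direction 85 deg away: even after antipodal
  # sign alignment the per-step turn exceeds an 80 deg limit
  n <- c(10L, 10L, 20L)
  tilted <- c(sin(85 * pi / 180), 0, cos(85 * pi / 180))
  dir1 <- array(0, c(n, 3))
  dir1[, , 1:10, 3] <- 1
  for (a in 1:3) dir1[, , 11:20, a] <- tilted[a]
  f <- orientation_field(dir1, array(Inf, n), diag(4))
  sl <- propagate(f, c(5, 5, 2),
                  tracking_params(step_mm = 0.5, curvature_limit_deg = 80),
                  seed = 1)
  expect_equal(sl$reason, "curvature")
  # with a permissive limit the streamline instead carries on to the edge
  sl2 <- propagate(f, c(5, 5, 2),
                   tracking_params(step_mm = 0.5, curvature_limit_deg = 90),
                   seed = 1)
  expect_equal(sl2$reason, "mask-exit")
})

test_that("closed circulating fields terminate as loops without repeats", {
  f <- spiral_field()
  sl <- propagate(f, c(24 + 10, 24, 24),
                  tracking_params(step_mm = 0.5, max_steps = 1000), seed = 1)
  expect_equal(sl$reason, "loop")
  # the visited trail holds no repeated voxel: the re-entry that triggered
  # the loop rule is the final recorded point, everything before is unique
  keys <- apply(round(sl$points), 1, paste, collapse = ",")
  trail <- rle(keys)$values
  body <- trail[-length(trail)]
  expect_equal(anyDuplicated(body), 0)
  expect_true(trail[length(trail)] %in% body)
})

test_that("start points outside the valid mask are rejected", {
  msk <- array(TRUE, c(8, 8, 8)); msk[, , 5:8] <- FALSE
  f <- uniform_field(c(8L, 8L, 8L), mask = msk)
  expect_error(propagate(f, c(4, 4, 6)), "rejected seed")
})

test_that("counters follow the geometric oracle on a straight tube", {
  # every sample from the two seed voxels must reach the slab above
  n <- c(9L, 9L, 16L)
  f <- uniform_field(n, dir = c(0, 0, 1), kappa = Inf)
  seed <- volume(array(FALSE, n), affine = diag(4))
  seed$data[5, 5, 2] <- TRUE; seed$data[5, 6, 2] <- TRUE
  target <- volume(array(FALSE, n), affine = diag(4))
  target$data[, , 12:14] <- TRUE
  cm <- track_seed_mask(f, seed, list(slab = target),
                        tracking_params(samples_per_seed_voxel = 100,
                                        step_mm = 0.5),
                        master_seed = 5)
  expect_equal(as.numeric(cm$counts), c(100, 100))
  expect_equal(cm$waytotal, 200)
  expect_true(all(cm$counts <= 100))  # counter bound
})

test_that("targets behind an absorbing boundary receive no samples", {
  n <- c(9L, 9L, 16L)
  msk <- array(TRUE, n); msk[, , 8] <- FALSE  # absorbing wall
  f <- uniform_field(n, dir = c(0, 0, 1), kappa = Inf, mask = msk)
  seed <- volume(array(FALSE, n), affine = diag(4))
  seed$data[5, 5, 2] <- TRUE
  target <- volume(array(FALSE, n), affine = diag(4))
  target$data[, , 12:14] <- TRUE
  cm <- track_seed_mask(f, seed, list(slab = target),
                        tracking_params(samples_per_seed_voxel = 50,
                                        step_mm = 0.5), master_seed = 5)
  expect_equal(sum(cm$counts), 0)
  expect_equal(cm$waytotal, 0)
})

test_that("tracking is reproducible in the master seed", {
  cfg <- phantom_config(grid_shape = c(32, 36, 32), master_seed = 3L)
  atlas <- generate_atlas(cfg)
  s <- generate_subject(atlas, 1, cfg)
  sp <- intent_spec(s$labels, "precentral", "l")
  pars <- tracking_params(samples_per_seed_voxel = 20)
  cm1 <- track_seed_mask(s$field, sp$seed, sp$targets, pars, master_seed = 9)
  cm2 <- track_seed_mask(s$field, sp$seed, sp$targets, pars, master_seed = 9)
  cm3 <- track_seed_mask(s$field, sp$seed, sp$targets, pars, master_seed = 10)
  expect_identical(cm1$counts, cm2$counts)
  expect_identical(cm1$waytotal, cm2$waytotal)
  expect_false(identical(cm1$counts, cm3$counts))
  expect_true(all(cm1$counts <= 20))
  expect_equal(cm1$waytotal, sum(cm1$counts))
})

test_that("seed and target preconditions are enforced", {
  n <- c(8L, 8L, 8L)
  f <- uniform_field(n)
  empty <- volume(array(FALSE, n), affine = diag(4))
  seed <- volume(array(FALSE, n), affine = diag(4)); seed$data[4, 4, 4] <- TRUE
  expect_error(track_seed_mask(f, empty, list(t = seed)), "empty seed")
  expect_error(track_seed_mask(f, seed, list()), "empty target")
  expect_error(track_seed_mask(f, seed, list(t = seed)), "disjoint")
})

test_that("waytotal normalization divides counters and guards reuse", {
  n <- c(8L, 8L, 8L)
  cm <- structure(list(seed_voxels = rbind(c(4, 4, 2), c(4, 5, 2)),
                       counts = matrix(c(10, 30), 2, 1),
                       targets = "t", waytotal = 40, normalized = FALSE,
                       samples_per_voxel = 50,
                       reasons = NULL, dims = n, affine = diag(4)),
                  class = "thala_cmap")
  nm <- normalize_by_waytotal(cm)
  expect_equal(as.numeric(nm$counts), c(0.25, 0.75))
  expect_true(nm$normalized)
  expect_error(normalize_by_waytotal(nm), "already normalized")
  cm0 <- cm; cm0$counts[] <- 0; cm0$waytotal <- 0
  expect_warning(nz <- normalize_by_waytotal(cm0), "waytotal is 0")
  expect_true(all(nz$counts == 0))
})

test_that("dilation matches the L1-ball oracle and is monotone", {
  n <- c(11L, 11L, 11L)
  single <- volume(array(FALSE, n), affine = diag(4))
  single$data[6, 6, 6] <- TRUE
  d4 <- dilate_mask(single, 4)
  expect_equal(sum(d4$data), 129)  # integer points with L1 norm <= 4
  expect_identical(dilate_mask(single, 0)$data, single$data)
  a <- random_mask(c(7L, 7L, 7L), seed = 2, p_on = 0.1)
  b <- a; b$data <- a$data | random_mask(c(7L, 7L, 7L), 3, 0.1)$data
  expect_true(all(dilate_mask(b, 2)$data[dilate_mask(a, 2)$data]))
  expect_identical(dilate_mask(a, 3)$data, dilate_oracle(a, 3))
})

test_that("ordered way-points keep forward arcs and reject inversions", {
  n <- c(48L, 48L, 48L); C <- c(24, 24)
  f <- arc_field(n, C, max_angle_deg = 75)
  seed <- arc_sector_mask(n, C, c(14, 18), c(-3, 3))
  seed$data <- seed$data & f$mask
  wpA <- arc_sector_mask(n, C, c(10, 22), c(20, 28))
  wpB <- arc_sector_mask(n, C, c(10, 22), c(40, 48))
  term <- arc_sector_mask(n, C, c(10, 22), c(60, 70))
  pars <- tracking_params(samples_per_seed_voxel = 5, step_mm = 0.5,
                          max_steps = 500)
  fwd <- track_waypoint_tract(f, seed, waypoint_spec(list(wpA, wpB), term),
                              pars, master_seed = 2)
  expect_equal(fwd$n_kept, fwd$n_launched)
  expect_gt(sum(fwd$map$data), 0)
  inv <- track_waypoint_tract(f, seed, waypoint_spec(list(wpB, wpA), term),
                              pars, master_seed = 2)
  expect_equal(inv$n_kept, 0)
  expect_equal(sum(inv$map$data), 0)
  # unreachable terminal target: nothing kept, empty map
  far <- volume(array(FALSE, n), affine = diag(4)); far$data[1, 1, 1] <- TRUE
  none <- track_waypoint_tract(f, seed, waypoint_spec(list(wpA, wpB), far),
                               pars, master_seed = 2)
  expect_equal(none$n_kept, 0)
  expect_equal(sum(none$map$data), 0)
})

test_that("kept streamlines serialize as JSON lines", {
  n <- c(48L, 48L, 48L); C <- c(24, 24)
  f <- arc_field(n, C, max_angle_deg = 75)
  seed <- arc_sector_mask(n, C, c(15, 17), c(-2, 2))
  seed$data <- seed$data & f$mask
  wp <- arc_sector_mask(n, C, c(10, 22), c(25, 35))
  term <- arc_sector_mask(n, C, c(10, 22), c(60, 70))
  tr <- track_waypoint_tract(f, seed, waypoint_spec(list(wp), term),
                             tracking_params(samples_per_seed_voxel = 2,
                                             step_mm = 1),
                             master_seed = 1)
  path <- tempfile(fileext = ".jsonl")
  on.exit(unlink(path))
  write_streamlines_json(tr, path)
  lines <- readLines(path)
  expect_equal(length(lines), length(tr$streamlines))
  parsed <- jsonlite::fromJSON(lines[1])
  expect_equal(ncol(parsed$points), 3)
})
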
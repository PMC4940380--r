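cfg0 <- phantom_config(master_seed = 11L)

test_that("atlas contains every region with the stated nesting and layout", {
  atlas <- generate_atlas(cfg0)
  expect_gte(length(atlas$legend), 12)
  expect_true(all(atlas$legend %in% atlas$data))
  for (side in c("l", "r")) {
    vlpv <- label_mask(atlas, paste0("vlpv_", side))
    vplp <- label_mask(atlas, paste0("vplp_", side))
    thal <- label_mask(atlas, paste0("thalamus_", side))
    expect_equal(sum(vlpv$data & vplp$data), 0)
    expect_true(all(thal$data[vlpv$data | vplp$data]))
    # vlpv sits anterior (+y) of vplp
    expect_gt(center_of_gravity(vlpv)[2], center_of_gravity(vplp)[2])
  }
  thal_vol <- sum(label_mask(atlas, "thalamus")$data)
  expect_gt(thal_vol, 0)
  expect_lt(thal_vol, prod(dim(atlas$data)))
})

test_that("a 32^3 grid still carries all regions; smaller grids error", {
  small <- phantom_config(grid_shape = c(32, 32, 32))
  atlas <- generate_atlas(small)
  expect_true(all(atlas$legend %in% atlas$data))
  expect_error(phantom_config(grid_shape = c(24, 32, 32)), "at least 32")
})

test_that("atlas generation is deterministic in the configuration", {
  a1 <- generate_atlas(cfg0)
  a2 <- generate_atlas(cfg0)
  expect_identical(a1$data, a2$data)
})

test_that("zero displacement reproduces the atlas exactly", {
  cfg <- phantom_config(subject_displacement_mm = 0)
  atlas <- generate_atlas(cfg)
  s <- generate_subject(atlas, 1, cfg)
  expect_identical(s$labels$data, atlas$data)
  expect_equal(s$centerlines, atlas$centerlines)
})

test_that("subjects are deterministic and distinct per index", {
  atlas <- generate_atlas(cfg0)
  s1a <- generate_subject(atlas, 1, cfg0)
  s1b <- generate_subject(atlas, 1, cfg0)
  s2 <- generate_subject(atlas, 2, cfg0)
  expect_identical(s1a$labels$data, s1b$labels$data)
  expect_identical(s1a$field$dir1, s1b$field$dir1)
  expect_false(identical(s1a$labels$data, s2$labels$data))
})

test_that("warp RMS matches the configured displacement magnitude", {
  # the CoG shift of a small nucleus estimates the local displacement; its
  # RMS over random warp draws recovers the configured RMS amplitude
  cfg <- phantom_config(n_subjects = 100, subject_displacement_mm = 2,
                        master_seed = 5L)
  atlas <- generate_atlas(cfg)
  cog0 <- center_of_gravity(label_mask(atlas, "vlpv_l"))
  shifts <- vapply(1:100, function(s) {
    subj <- generate_subject(atlas, s, cfg)
    sum((center_of_gravity(label_mask(subj$labels, "vlpv_l")) - cog0)^2)
  }, numeric(1))
  rms <- sqrt(mean(shifts))
  expect_gt(rms, 2 * 0.7)
  expect_lt(rms, 2 * 1.4)
  # and every single draw stays within a few times the RMS scale
  expect_true(all(sqrt(shifts) < 3 * 2 + 1))
})

test_that("warps approximately conserve region volumes", {
  atlas <- generate_atlas(cfg0)
  n0 <- table(factor(atlas$data[atlas$data > 0], levels = atlas$legend))
  for (s in 1:3) {
    subj <- generate_subject(atlas, s, cfg0)
    ns <- table(factor(subj$labels$data[subj$labels$data > 0],
                       levels = atlas$legend))
    expect_true(all(abs(ns - n0) / n0 < 0.10))
  }
})

test_that("scanner 1 is the identity; repeats reproduce; scanners differ", {
  atlas <- generate_atlas(cfg0)
  s <- generate_subject(atlas, 1, cfg0)
  f1 <- apply_scanner(s$field, 1, cfg0)
  expect_identical(f1$dir1, s$field$dir1)
  expect_identical(f1$kappa, s$field$kappa)
  f2a <- apply_scanner(s$field, 2, cfg0)
  f2b <- apply_scanner(s$field, 2, cfg0)
  f3 <- apply_scanner(s$field, 3, cfg0)
  expect_identical(f2a$dir1, f2b$dir1)
  expect_false(identical(f2a$dir1, f3$dir1))
})

test_that("orientation scatter grows monotonically with the scanner delta", {
  atlas <- generate_atlas(cfg0)
  s <- generate_subject(atlas, 1, cfg0)
  bundle <- which(s$field$kappa == cfg0$kappa_bundle)
  nv <- prod(dim(s$field$kappa))
  ref <- matrix(s$field$dir1, nv, 3)[bundle, ]
  tilt <- vapply(c(5, 20, 60), function(delta) {
    cfg <- phantom_config(scanner_dispersion_delta = c(0, delta),
                          n_scanners = 2, master_seed = 11L)
    f <- apply_scanner(s$field, 2, cfg)
    pert <- matrix(f$dir1, nv, 3)[bundle, ]
    mean(acos(pmin(abs(rowSums(ref * pert)), 1)))
  }, numeric(1))
  expect_true(all(diff(tilt) > 0))
  # the sampling dispersion itself also widens as kappa drops
  angs <- vapply(c(60, 40, 15), function(k) {
    mean(acos(pmin(abs(rwatson(3000, c(0, 0, 1), k, seed = 2)[, 3]), 1)))
  }, numeric(1))
  expect_true(all(diff(angs) > 0))
})

test_that("zero subject and scanner effects give voxel-identical units", {
  cfg <- phantom_config(n_subjects = 2, n_scanners = 2,
                        subject_displacement_mm = 0,
                        scanner_dispersion_delta = 0,
                        scanner_noise_sd = 0)
  set <- generate_phantom_set(cfg)
  ref <- set$units$field[[1]]
  for (i in 2:nrow(set$units)) {
    expect_identical(set$units$field[[i]]$dir1, ref$dir1)
    expect_identical(set$units$field[[i]]$kappa, ref$kappa)
  }
})

test_that("the tract arc meets scp before red nucleus walking from dentate", {
  atlas <- generate_atlas(cfg0)
  for (side in c("l", "r")) {
    contra <- if (side == "l") "r" else "l"
    pts <- densify_centerline(atlas$centerlines[[paste0("ctt_", side)]],
                              step_mm = 0.5)
    vox <- round(sweep(pts, 2, cfg0$voxel_size_mm, "/")) + 1
    labs <- atlas$data[vox]
    i_scp <- which(labs == atlas$legend[paste0("scp_", contra)])
    rn <- dilate_mask(label_mask(atlas, paste0("red_nucleus_", side)), 4)
    i_rn <- which(rn$data[vox] > 0)
    expect_gt(length(i_scp), 0)
    expect_gt(length(i_rn), 0)
    expect_lt(min(i_scp), min(i_rn))
    # and the arc's dentate origin is contralateral to the thalamus it feeds
    dent <- label_mask(atlas, paste0("dentate_", contra))
    expect_true(dent$data[vox[1, 1], vox[1, 2], vox[1, 3]])
  }
})

test_that("simulated DWI matches the Stejskal-Tanner closed form", {
  # stick tensor along +z: signal ratio between z- and x-oriented gradients
  b <- 1000
  d6 <- matrix(c(0, 0, 1.7e-3, 0, 0, 0), 1)
  g <- rbind(c(0, 0, 1), c(1, 0, 0))
  s <- dwi_signal(d6, c(b, b), g, s0 = 100)
  expect_equal(s[1, 1] / 100, exp(-b * 1.7e-3))
  expect_equal(s[1, 2], 100)
  # isotropic tensor: all weighted volumes equal
  d6i <- matrix(c(8e-4, 8e-4, 8e-4, 0, 0, 0), 1)
  gi <- gradient_directions(12)
  si <- dwi_signal(d6i, rep(b, 12), gi, s0 = 100)
  expect_equal(max(si) - min(si), 0, tolerance = 1e-9)
})

test_that("noise-free DWI stacks are reproducible and positive", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32))
  atlas <- generate_atlas(cfg)
  s <- generate_subject(atlas, 1, cfg)
  d1 <- simulate_dwi(s$field, cfg)
  d2 <- simulate_dwi(s$field, cfg)
  expect_identical(d1$data, d2$data)
  expect_true(all(d1$data > 0))
  expect_equal(dim(d1$data)[4], cfg$acquisition$n_directions + 1)
  dn <- simulate_dwi(s$field, cfg, scanner_index = 2)
  expect_false(identical(dn$data, d1$data))
})
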
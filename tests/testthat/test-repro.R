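blob_cbt <- function(n, at, affine = diag(4)) {
  v <- volume(array(FALSE, n), affine = affine)
  v$data[at] <- TRUE
  v
}

test_that("pair bookkeeping enumerates and tags every unordered pair", {
  n <- c(6L, 6L, 6L)
  units <- tidyr::expand_grid(subject = 1:2, scanner = 1:2)
  units$cbt <- lapply(1:4, function(i) blob_cbt(n, i:(i + 7)))
  pr <- pairwise_dice(units)
  expect_equal(nrow(pr), 6)  # C(4,2)
  expect_equal(sum(pr$group == "inter_scanner"), 2)
  expect_equal(sum(pr$group == "inter_subject"), 2)
  expect_equal(sum(pr$group == "crossed"), 2)
  # the general count law: n_subjects*C(n_scanners,2), n_scanners*C(n_subjects,2)
  u2 <- tidyr::expand_grid(subject = 1:3, scanner = 1:3)
  u2$cbt <- lapply(1:9, function(i) blob_cbt(n, i:(i + 5)))
  p2 <- pairwise_dice(u2)
  expect_equal(nrow(p2), choose(9, 2))
  expect_equal(sum(p2$group == "inter_scanner"), 3 * choose(3, 2))
  expect_equal(sum(p2$group == "inter_subject"), 3 * choose(3, 2))
})

test_that("identical CBTs give unit Dice; degenerate units are dropped", {
  n <- c(6L, 6L, 6L)
  units <- tidyr::expand_grid(subject = 1:2, scanner = 1:2)
  units$cbt <- lapply(1:4, function(i) blob_cbt(n, 1:10))
  pr <- pairwise_dice(units)
  expect_true(all(pr$dice == 1))
  units$cbt[[2]] <- blob_cbt(n, integer(0))  # empty CBT
  expect_message(pr2 <- pairwise_dice(units), "degenerate")
  expect_equal(nrow(pr2), choose(3, 2))
})

test_that("group means, SDs and the Welch test match direct arithmetic", {
  pr <- tibble::tibble(
    intent = "x", side = "l",
    subject_a = c(1, 2, 1, 1), scanner_a = c(1, 1, 1, 1),
    subject_b = c(1, 2, 2, 3), scanner_b = c(2, 2, 1, 1),
    dice = c(0.6, 0.6, 0.8, 0.8),
    group = c("inter_scanner", "inter_scanner",
              "inter_subject", "inter_subject"))
  g <- glance(decompose_variability(pr))
  expect_equal(g$inter_scanner_mean, 0.6)
  expect_equal(g$inter_subject_mean, 0.8)
  expect_equal(g$overall_mean, 0.7)
  expect_equal(g$p_value, 0)  # constant groups with different means
  pr_same <- pr; pr_same$dice <- rep(0.7, 4)
  expect_gt(glance(decompose_variability(pr_same))$p_value, 0.99)
  # against stats::t.test on non-degenerate data
  pr_rand <- pr; pr_rand$dice <- c(0.61, 0.55, 0.82, 0.74)
  expect_equal(glance(decompose_variability(pr_rand))$p_value,
               stats::t.test(c(0.61, 0.55), c(0.82, 0.74))$p.value)
})

test_that("the permutation test is calibrated and seeded", {
  set.seed(99)
  units <- tidyr::expand_grid(subject = 1:4, scanner = 1:3)
  units$cbt <- lapply(seq_len(nrow(units)), function(i) {
    at <- sample(6^3, 40)
    blob_cbt(c(6L, 6L, 6L), at)
  })
  pr <- pairwise_dice(units)
  d1 <- decompose_variability(pr, test = "permutation", n_perm = 300,
                              perm_seed = 5, cbt_units = units)
  d2 <- decompose_variability(pr, test = "permutation", n_perm = 300,
                              perm_seed = 5)  # units reconstructed
  expect_equal(glance(d1)$p_value, glance(d2)$p_value)
  expect_gte(glance(d1)$p_value, 0)
  expect_lte(glance(d1)$p_value, 1)
  # exchangeable units rarely produce small p: aggregate over draws
  ps <- vapply(1:8, function(r) {
    set.seed(500 + r)
    u <- units
    u$cbt <- lapply(seq_len(nrow(u)), function(i)
      blob_cbt(c(6L, 6L, 6L), sample(6^3, 40)))
    p <- pairwise_dice(u)
    glance(decompose_variability(p, test = "permutation", n_perm = 200,
                                 perm_seed = r, cbt_units = u))$p_value
  }, numeric(1))
  expect_gte(sum(ps > 0.05), 6)
})

test_that("slab restriction keeps exactly the voxels near the AC-PC plane", {
  aff <- diag(c(2, 2, 2, 1))
  n <- c(8L, 8L, 24L)
  set.seed(8)
  v <- volume(array(runif(prod(n)), n), affine = aff)
  acpc <- 22
  out <- restrict_slab(v, acpc, 20)
  # brute-force per-voxel enumeration under the affine
  manual <- v$data
  for (k in seq_len(n[3])) {
    z <- (k - 1) * 2
    if (abs(z - acpc) > 20) manual[, , k] <- 0
  }
  expect_equal(out$data, manual)
  # a half-extent covering the grid changes nothing
  expect_equal(restrict_slab(v, acpc, 1000)$data, v$data)
  # boundary: a voxel 21 mm away is removed, one at 20 mm is kept
  single <- volume(array(0, c(4, 4, 44)), affine = diag(4))
  single$data[2, 2, 22] <- 1  # z = 21
  expect_equal(sum(restrict_slab(single, 0, 20)$data), 0)
  single$data[2, 2, 22] <- 0; single$data[2, 2, 21] <- 1  # z = 20
  expect_equal(sum(restrict_slab(single, 0, 20)$data), 1)
  expect_error(restrict_slab(single, 1e5, 20), "does not intersect")
})

test_that("tract reproducibility restricts the slab before thresholding", {
  # high intensities OUTSIDE the slab would dominate the percentile cutoff;
  # slab-first confines the CBT to the slab and keeps its interior blob
  n <- c(8L, 8L, 40L)
  arr <- array(0, n)
  arr[4, 4, 1:8] <- 100    # far outside the slab
  arr[4, 4, 18:22] <- 1:5  # inside the slab
  m <- volume(arr, affine = diag(4))
  acpc <- 19
  units <- tibble::tibble(subject = c(1, 2), scanner = c(1, 1),
                          map = list(m, m))
  rep_ <- ctt_reproducibility(units, acpc_z_mm = acpc, percentile = 60,
                              half_extent_mm = 3)
  expect_equal(glance(rep_)$overall_mean, 1)
  slab_first <- percentile_threshold(restrict_slab(m, acpc, 3), 60)
  thr_first <- restrict_slab(percentile_threshold(m, 60), acpc, 3)
  expect_gt(sum(slab_first$data), 0)
  expect_equal(sum(thr_first$data), 0)  # all kept voxels lay outside
  expect_false(identical(slab_first$data != 0, thr_first$data != 0))
})

test_that("zero-noise phantom tract maps are identical across units", {
  cfg <- phantom_config(grid_shape = c(32, 36, 32), n_subjects = 2,
                        n_scanners = 2, subject_displacement_mm = 0,
                        scanner_dispersion_delta = 0, scanner_noise_sd = 0,
                        master_seed = 21L)
  atlas <- generate_atlas(cfg)
  pars <- tracking_params(samples_per_seed_voxel = 60)
  units <- tidyr::expand_grid(subject = 1:2, scanner = 1:2)
  units$map <- purrr::map2(units$subject, units$scanner, function(s, sc) {
    subj <- generate_subject(atlas, s, cfg)
    f <- apply_scanner(subj$field, sc, cfg)
    ct <- ctt_waypoint_spec(subj$labels, "l")
    track_waypoint_tract(f, ct$seed, ct$spec, pars, master_seed = 17,
                         keep_streamlines = FALSE)$map
  })
  rep_ <- ctt_reproducibility(units, acpc_z_mm = atlas$acpc_z_mm)
  expect_true(all(tidy(rep_)$dice == 1))
  # perturbing half the units (a strong scanner tilt splitting the path)
  # lowers the overall agreement below the zero-noise value
  cfg2 <- phantom_config(grid_shape = c(32, 36, 32), n_subjects = 2,
                         n_scanners = 2, subject_displacement_mm = 0,
                         scanner_dispersion_delta = c(0, 20),
                         tilt_base = 300, master_seed = 21L)
  units2 <- units
  units2$map <- purrr::map2(units2$subject, units2$scanner, function(s, sc) {
    subj <- generate_subject(atlas, s, cfg2)
    f <- apply_scanner(subj$field, sc, cfg2)
    ct <- ctt_waypoint_spec(subj$labels, "l")
    track_waypoint_tract(f, ct$seed, ct$spec, pars, master_seed = 17,
                         keep_streamlines = FALSE)$map
  })
  rep2 <- ctt_reproducibility(units2, acpc_z_mm = atlas$acpc_z_mm)
  expect_lt(glance(rep2)$overall_mean, glance(rep_)$overall_mean)
})

test_that("repro plots and tidiers expose pairs and the summary row", {
  n <- c(6L, 6L, 6L)
  units <- tidyr::expand_grid(subject = 1:3, scanner = 1:2)
  set.seed(31)
  units$cbt <- lapply(seq_len(nrow(units)), function(i)
    blob_cbt(n, sample(6^3, 30)))
  rp <- decompose_variability(pairwise_dice(units, intent = "vlpv",
                                            side = "l"))
  expect_named(glance(rp)[, 1:2], c("intent", "side"))
  expect_equal(nrow(tidy(rp)), choose(6, 2))
  expect_s3_class(autoplot(rp), "ggplot")
})
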
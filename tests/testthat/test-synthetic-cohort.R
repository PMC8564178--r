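test_that("generated atlas tiles the in-mask grid with balanced regions", {
  spec <- cohort_spec(group_sizes = c(mild = 3, moderate = 3, severe = 3),
                      atlas_shape = c(8, 8, 8), n_regions = 8)
  at <- generate_atlas(spec)
  sizes <- table(at$atlas$labels[at$atlas$labels > 0])
  expect_length(sizes, 8)
  expect_true(all(sizes >= 32))
  # every in-mask voxel carries exactly one label; background outside
  expect_true(all(at$atlas$labels[at$mask] > 0))
  expect_true(all(at$atlas$labels[!at$mask] == 0))
  # sizes within a factor of two of each other
  expect_lte(max(sizes) / min(sizes), 2)
  # same holds on an anisotropic grid with a margin
  at2 <- generate_atlas(cohort_spec(group_sizes = c(mild = 3, moderate = 3,
                                                    severe = 3),
                                    atlas_shape = c(18, 14, 12),
                                    n_regions = 10))
  s2 <- table(at2$atlas$labels[at2$atlas$labels > 0])
  expect_length(s2, 10)
  expect_lte(max(s2) / min(s2), 2)
  expect_error(generate_atlas(cohort_spec(
    group_sizes = c(mild = 3, moderate = 3, severe = 3),
    atlas_shape = c(4, 4, 4), n_regions = 20)), class = "nc_tiling_error")
})

test_that("BOLD community structure controls the correlation pattern", {
  spec1 <- tiny_spec(bold_community_weight = 1, n_communities = 1)
  at <- generate_atlas(spec1)
  b1 <- generate_subject_bold(at$atlas, at$mask, spec1, 3)
  ts <- t(matrix(b1$data, ncol = dim(b1$data)[4]))[, as.vector(at$mask)][, 1:50]
  R <- cor(ts)
  expect_true(all(R > 0.999))  # single shared series

  spec0 <- tiny_spec(bold_community_weight = 0)
  b0 <- generate_subject_bold(at$atlas, at$mask, spec0, 3)
  ts0 <- t(matrix(b0$data, ncol = dim(b0$data)[4]))[, as.vector(at$mask)][, 1:100]
  R0 <- cor(ts0)
  expect_lt(abs(mean(R0[upper.tri(R0)])), 0.02)

  spec2 <- tiny_spec(bold_community_weight = 0.8, n_communities = 2)
  b2 <- generate_subject_bold(at$atlas, at$mask, spec2, 3)
  lab <- as.vector(at$atlas$labels)[as.vector(at$mask)]
  comm <- neurocouple:::region_communities(8, 2)[lab]
  ts2 <- t(matrix(b2$data, ncol = dim(b2$data)[4]))[, as.vector(at$mask)]
  idx <- c(which(comm == 1)[1:60], which(comm == 2)[1:60])
  R2 <- cor(ts2[, idx])
  same <- outer(comm[idx], comm[idx], `==`)
  diag(R2) <- NA
  expect_gt(mean(R2[same], na.rm = TRUE), mean(R2[!same], na.rm = TRUE))
  # motion parameters ride along, bounded under the exclusion gate
  expect_identical(nrow(b2$motion_params), dim(b2$data)[4])
  expect_true(motion_exclusion(b2$motion_params)$pass)
})

test_that("generate_subject_cbf induces the requested voxelwise coupling", {
  mask <- small_mask(c(18, 18, 18))
  fz <- white_zmap(mask, 11)
  # rho = 1: perfect coupling survives the affine rescale
  c1 <- generate_subject_cbf(fz, 0.999999, 0, NULL, 1)
  expect_gt(cor(in_mask(c1), in_mask(fz)), 0.999)
  # rho = 0: no coupling beyond sampling error
  c0 <- generate_subject_cbf(fz, 0, 0, NULL, 2)
  expect_lt(abs(cor(in_mask(c0), in_mask(fz))), 0.05)
  # rho = 0.225 on ~4000 voxels recovered within +-0.05
  c225 <- generate_subject_cbf(fz, 0.225, 0, NULL, 3)
  expect_lt(abs(cor(in_mask(c225), in_mask(fz)) - 0.225), 0.05)
  # rescaled to mean 50, SD 10
  expect_equal(mean(in_mask(c0)), 50, tolerance = 1e-6)
  expect_equal(sd(in_mask(c0)), 10, tolerance = 1e-6)
  expect_error(generate_subject_cbf(fz, 1.2, 0, NULL, 1),
               class = "nc_validation_error")
})

test_that("hub-region CBF reduction has the requested size and direction", {
  spec <- tiny_spec(seed = 9)
  at <- generate_atlas(spec)
  fz <- white_zmap(at$mask, 12)
  eff <- 0.8
  hits <- vapply(1:50, function(s) {
    cb <- generate_subject_cbf(fz, 0.2, eff, at$atlas, s)
    cb0 <- generate_subject_cbf(fz, 0.2, 0, at$atlas, s)
    hub_ids <- at$atlas$regions$id[at$atlas$regions$is_hub]
    hub <- as.vector(at$atlas$labels)[as.vector(at$mask)] %in% hub_ids
    mean(in_mask(cb)[hub]) < mean(in_mask(cb0)[hub])
  }, logical(1))
  expect_true(all(hits))  # direction recovered in every replicate at d = 0.8
})

test_that("ASL generation inverts the quantification model", {
  mask <- small_mask(c(6, 6, 6))
  set.seed(4)
  cbf <- masked_volume(array(pmax(rnorm(216, 50, 10), 0), c(6, 6, 6)), mask)
  # zero noise: exact round trip
  asl <- generate_subject_asl(cbf, n_pairs = 3, noise_sd = 0, seed = 1)
  rec <- estimate_cbf(asl, mask)
  expect_lt(max(abs(in_mask(rec) - in_mask(cbf)) /
                pmax(in_mask(cbf), 1e-12)), 1e-8)
  # zero CBF gives zero difference signal
  z <- masked_volume(array(0, c(6, 6, 6)), mask)
  aslz <- generate_subject_asl(z, n_pairs = 2, noise_sd = 0, seed = 1)
  expect_equal(max(abs(in_mask(perfusion_difference(aslz, mask)))), 0)
  # with noise, recovery is unbiased across voxels (Monte Carlo)
  errs <- vapply(1:30, function(s) {
    a <- generate_subject_asl(cbf, n_pairs = 40, noise_sd = 1, seed = s)
    mean(in_mask(estimate_cbf(a, mask)) - in_mask(cbf))
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.5)  # 1% of the mean CBF of 50
})

test_that("demographic tables reproduce the design", {
  spec <- tiny_spec(seed = 1)
  df <- generate_tables(spec)
  expect_identical(as.integer(table(factor(df$group, c("mild", "moderate",
                                                       "severe")))),
                   c(4L, 4L, 4L))
  expect_true(all(df$fazekas_total[df$group == "mild"] %in% 1:2))
  expect_true(all(df$fazekas_total[df$group == "severe"] %in% 5:6))
  # prevalence 1 makes every subject positive
  rp <- neurocouple:::default_risk_prevalences()
  rp["hypertension", ] <- 1
  df2 <- generate_tables(tiny_spec(risk_prevalences = rp, seed = 2))
  expect_true(all(df2$hypertension))
  # fixed seed is bit-reproducible
  expect_identical(generate_tables(spec), generate_tables(spec))
})

test_that("severe group scores worst in most cognitive domains", {
  spec <- cohort_spec(seed = 0)   # default 32/24/30 design
  timed <- c("tmt_a", "tmt_b")
  n_lowest <- vapply(1:100, function(s) {
    df <- generate_tables(spec, seed = s)
    z <- zscore_cognition(df[, names(spec$cognition)], timed)
    sum(vapply(z, function(col)
      which.min(tapply(col, factor(df$group, c("mild", "moderate", "severe")),
                       mean)) == 3L, logical(1)))
  }, numeric(1))
  expect_true(all(n_lowest >= 4))
})

test_that("full generation with a fixed seed is bit-reproducible", {
  spec <- tiny_spec(seed = 33)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$cbf[[5]]$data, b$cbf[[5]]$data)
  expect_identical(a$asl[[2]]$frames, b$asl[[2]]$frames)
  expect_identical(a$bold[[7]]$data, b$bold[[7]]$data)
})

test_that("optional hub attenuation lowers hub connectivity strength", {
  spec <- tiny_spec(seed = 21)
  at <- generate_atlas(spec)
  b0 <- generate_subject_bold(at$atlas, at$mask, spec, 50, group_effect = 0)
  b1 <- generate_subject_bold(at$atlas, at$mask, spec, 50, group_effect = 1.2)
  f0 <- compute_fcs(b0, at$mask)
  f1 <- compute_fcs(b1, at$mask)
  hub_ids <- at$atlas$regions$id[at$atlas$regions$is_hub]
  hub <- as.vector(at$atlas$labels)[as.vector(at$mask)] %in% hub_ids
  expect_lt(mean(in_mask(f1)[hub]), mean(in_mask(f0)[hub]))
  # default generation applies no attenuation
  bd <- generate_subject_bold(at$atlas, at$mask, spec, 50)
  expect_identical(bd$data, b0$data)
})
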
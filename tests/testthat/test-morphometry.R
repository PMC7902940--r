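# Morphometry: volume integration, whole-brain normalization, voxel-wise
# genotype linear models, and BH FDR control.

make_toy_atlas <- function() {
  labels <- array(0L, c(10, 10, 10))
  labels[1:10, 1:10, 1:5] <- 1L   # 500 voxels
  labels[1:10, 1:10, 6:10] <- 2L  # 500 voxels
  label_atlas(labels, c(top = 1, bottom = 2), voxel_size = 0.05)
}

test_that("identity Jacobian gives voxel-count volumes at 50-um voxels", {
  atlas <- make_toy_atlas()
  # 1,000 brain voxels at 0.05 mm -> 1,000 * 1.25e-4 = 0.125 mm^3
  jac <- jacobian_map(array(1, c(10, 10, 10)), "s1")
  vols <- integrate_structure_volumes(atlas, jac)
  expect_equal(attr(vols, "whole_brain"), 0.125, tolerance = 1e-12)
  expect_equal(vols$absolute_volume, c(500, 500) * 0.05^3, tolerance = 1e-12)
  # linearity: doubling the Jacobian doubles every volume
  jac2 <- jacobian_map(array(2, c(10, 10, 10)), "s1")
  expect_equal(integrate_structure_volumes(atlas, jac2)$absolute_volume,
               2 * vols$absolute_volume, tolerance = 1e-12)
})

test_that("volume integration matches the naive triple-loop oracle", {
  atlas <- make_synthetic_atlas(morphometry_sim_params(
    atlas_shape = c(12, 12, 12), n_structures = 4))
  set.seed(21)
  jac <- jacobian_map(array(exp(rnorm(12^3, 0, 0.3)), c(12, 12, 12)), "s1")
  got <- integrate_structure_volumes(atlas, jac)
  expected <- naive_volume_oracle(atlas, jac)
  expect_equal(stats::setNames(got$absolute_volume, got$structure),
               expected[got$structure], tolerance = 1e-9)
  # conservation: structures partition the brain integral exactly
  lab <- atlas$labels
  expect_equal(sum(got$absolute_volume),
               sum(jac$values[lab > 0]) * atlas$voxel_size^3,
               tolerance = 1e-12)
})

test_that("grid mismatches and non-positive Jacobians are rejected", {
  atlas <- make_toy_atlas()
  expect_error(
    integrate_structure_volumes(atlas, jacobian_map(array(1, c(5, 5, 5)), "s")),
    "10x10x10.*5x5x5")
  expect_error(jacobian_map(array(c(-1, rep(1, 999)), c(10, 10, 10)), "s"),
               "positive")
})

test_that("relative volumes normalize by whole brain and sum to one", {
  atlas <- make_toy_atlas()
  jac <- jacobian_map(array(1, c(10, 10, 10)), "s1")
  vols <- relative_volumes(integrate_structure_volumes(atlas, jac))
  expect_equal(vols$relative_volume, c(0.5, 0.5))  # each half the brain
  # global Jacobian rescaling leaves relative volumes unchanged
  jac3 <- jacobian_map(array(3.7, c(10, 10, 10)), "s1")
  vols3 <- relative_volumes(integrate_structure_volumes(atlas, jac3))
  expect_equal(vols3$relative_volume, vols$relative_volume, tolerance = 1e-12)
  # full-partition normalization
  set.seed(5)
  jr <- jacobian_map(array(exp(rnorm(1000, 0, 0.2)), c(10, 10, 10)), "s1")
  vr <- relative_volumes(integrate_structure_volumes(atlas, jr))
  expect_equal(sum(vr$relative_volume), 1, tolerance = 1e-12)
})

test_that("voxel-wise LM equals the closed-form pooled two-sample t", {
  d <- cohort_design(6, exclude = "M_WT_1")  # 6 KO vs 5 WT males
  males <- d[d$sex == "M", ]
  shp <- c(5, 5, 5)
  set.seed(31)
  jacs <- lapply(males$subject_id, function(s) {
    jacobian_map(array(exp(rnorm(prod(shp), 0, 0.5)), shp), s)
  })
  names(jacs) <- males$subject_id
  vs <- voxelwise_lm(jacs, d, "M")
  expect_equal(vs$df, nrow(males) - 2)  # df = n - 2 = 9 after the exclusion
  y <- sapply(jacs, function(j) log(as.vector(j$values)))
  wt_cols <- males$genotype == "WT"
  for (vox in c(1, 17, 125)) {
    oracle <- pooled_t_oracle(y[vox, wt_cols], y[vox, !wt_cols])
    expect_equal(as.vector(vs$t)[vox], oracle$t, tolerance = 1e-10)
    expect_equal(as.vector(vs$p)[vox], oracle$p, tolerance = 1e-10)
  }
  # and against R's own linear-model fitter at one voxel
  fit <- summary(stats::lm(y[17, ] ~ I(males$genotype == "KO")))
  expect_equal(as.vector(vs$t)[17], fit$coefficients[2, "t value"],
               tolerance = 1e-10)
})

test_that("identical group means give t = 0, p = 1", {
  d <- cohort_design(2)
  males <- d[d$sex == "M", ]
  shp <- c(3, 3, 3)
  vals <- c(1.0, 1.2)  # same two values in each genotype
  jacs <- list()
  for (i in seq_len(nrow(males))) {
    jacs[[males$subject_id[i]]] <-
      jacobian_map(array(vals[(i %% 2) + 1], shp), males$subject_id[i])
  }
  vs <- voxelwise_lm(jacs, d, "M")
  expect_true(all(abs(vs$t) < 1e-10))
  expect_true(all(abs(vs$p - 1) < 1e-10))
})

test_that("degenerate strata and zero-variance voxels are handled", {
  d <- cohort_design(2)
  onesex <- d[!(d$sex == "M" & d$genotype == "KO"), ]
  shp <- c(3, 3, 3)
  jacs <- lapply(onesex$subject_id, function(s) jacobian_map(array(1, shp), s))
  names(jacs) <- onesex$subject_id
  expect_error(voxelwise_lm(jacs, onesex, "M"), "absent")
  # constant response: undefined t excluded, counted
  jacs_f <- jacs[onesex$subject_id[onesex$sex == "F"]]
  vs <- voxelwise_lm(jacs_f, onesex, "F")
  expect_true(all(is.na(vs$t)))
  expect_equal(vs$n_undefined, prod(shp))
  adj <- fdr_bh(vs$p, 0.01)
  expect_false(any(adj$significant))
})

test_that("planted-effect voxels carry the stratum's largest |t|", {
  d <- cohort_design(3)
  p <- morphometry_sim_params(atlas_shape = c(12, 12, 12), n_structures = 3,
                              structure_effects = c(structure_01 = 0.3),
                              subject_noise_sd = 0.02, seed = 13)
  m <- simulate_morphometry_cohort(d, p)
  vs <- voxelwise_lm(m$jacobians, d, "F", atlas = m$atlas)
  inside <- m$atlas$labels == m$atlas$name_map[["structure_01"]]
  expect_gt(min(abs(vs$t[inside])), max(abs(vs$t[!inside & m$atlas$labels > 0])))
})

test_that("BH step-up matches the literal scan oracle", {
  expect_true(fdr_bh(0.001, 0.01)$significant)
  all_ones <- fdr_bh(rep(1, 10), 0.01)
  expect_false(any(all_ones$significant))
  expect_true(all(all_ones$q == 1))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  got <- fdr_bh(p, 0.05)
  expect_equal(got$significant, bh_stepup_oracle(p, 0.05))
  # random p sets, several levels
  set.seed(41)
  for (r in 1:20) {
    p <- stats::runif(50)^2
    for (q in c(0.01, 0.05, 0.2)) {
      expect_equal(fdr_bh(p, q)$significant, bh_stepup_oracle(p, q))
    }
  }
  # q monotone in p after adjustment
  p <- stats::runif(100)
  q <- fdr_bh(p, 0.05)$q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
  empty <- fdr_bh(numeric(0), 0.01)
  expect_length(empty$significant, 0)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("run_morphometry recovers a planted relative-volume increase", {
  d <- cohort_design(6, exclude = "M_WT_1")
  p <- morphometry_sim_params(atlas_shape = c(16, 16, 16), n_structures = 6,
                              structure_effects = c(structure_03 = log(1.1)),
                              subject_noise_sd = 0.02, seed = 17)
  m <- simulate_morphometry_cohort(d, p)
  res <- run_morphometry(m$atlas, m$jacobians, d)
  for (sx in c("M", "F")) {
    st <- res$structure_tests[res$structure_tests$sex == sx, ]
    expect_equal(st$structure[which.min(st$p)], "structure_03")
  }
  # male stratum uses n - 2 = 9 df after the exclusion
  expect_equal(res$voxel_stats[["M"]]$df, 9)
  expect_equal(res$voxel_stats[["M"]]$n_subjects, 11)
  # group-mean log-volume difference recovers the planted shift (small noise)
  vols <- res$volumes[res$volumes$structure == "structure_03", ]
  shift <- mean(log(vols$absolute_volume[vols$genotype == "KO"])) -
    mean(log(vols$absolute_volume[vols$genotype == "WT"]))
  expect_lt(abs(shift - log(1.1)), 0.01)
})

test_that("a null cohort with large noise yields empty significance masks", {
  d <- cohort_design(3)
  hits <- 0
  for (seed in 1:5) {
    m <- simulate_morphometry_cohort(d, morphometry_sim_params(
      atlas_shape = c(10, 10, 10), n_structures = 3,
      subject_noise_sd = 1, seed = seed))
    res <- run_morphometry(m$atlas, m$jacobians, d, level = 0.01)
    hits <- hits + sum(vapply(res$voxel_stats, function(v) {
      sum(v$significant, na.rm = TRUE)
    }, numeric(1)))
  }
  expect_equal(hits, 0)
})
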
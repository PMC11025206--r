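make_labels <- function(dims = c(20, 20, 20), fill = list()) {
  lab <- array(0L, dim = dims)
  for (f in fill) lab[f$idx] <- f$code
  label_map(lab)
}

test_that("initial mask is the union of the six ventricular labels", {
  lab <- array(0L, dim = c(20, 20, 20))
  lab[1:500] <- 4L
  lab[501:1000] <- 43L
  m <- build_initial_mask(label_map(lab))
  expect_equal(sum(m), 1000L)
  expect_equal(attr(m, "n_voxels"), 1000L)
  # partition property: union count equals the sum of per-code counts
  lab[1001:1100] <- 31L
  lab[1101:1150] <- 63L
  lab[1151:1200] <- 5L
  lab[1201:1210] <- 44L
  m2 <- build_initial_mask(label_map(lab))
  expect_equal(sum(m2), sum(lab %in% aseg_codes()))
  # other structures are excluded
  lab[1300] <- 17L
  expect_equal(sum(build_initial_mask(label_map(lab))), sum(m2))
  expect_error(build_initial_mask(label_map(array(0L, c(5, 5, 5)))),
               "empty")
})

test_that("stage-1 clustering partitions the mask into CSF and CP+wall", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  init <- build_initial_mask(ph$labels)
  s1 <- stage1_cluster(ph$image, init)
  expect_true(all(xor(s1$low_mask[init], s1$high_mask[init])))
  expect_false(any(s1$low_mask & !init) || any(s1$high_mask & !init))
  # high class contains every true CP voxel (CSF/wall boundary is below
  # the wall mean, far below CP)
  expect_true(all(s1$high_mask[ph$truth]))
  expect_gt(mean(ph$image$data[s1$high_mask]),
            mean(ph$image$data[s1$low_mask]))
  # sample-size guard propagates from the mixture fit
  tiny <- array(FALSE, dim = dim(init))
  tiny[1:9] <- TRUE
  expect_error(stage1_cluster(ph$image, tiny), "at least 20")
})

test_that("stage-2 assignment tracks the Bayes-optimal decision rule", {
  set.seed(42)
  vals <- c(rnorm(300, 40, 5), rnorm(300, 70, 5), rnorm(300, 110, 5))
  dm <- array(TRUE, dim = c(900, 1, 1))
  s2 <- stage2_cluster(vals, dm)
  fit <- s2$fit
  pred <- rank(fit$means)[gmm_assign(fit)]
  # equal weights and variances: Bayes boundaries at the midpoints
  bayes <- cut(vals, c(-Inf, 55, 90, Inf), labels = FALSE)
  bayes_err <- (2 * pnorm(-3) + 2 * pnorm(-4)) / 3
  expect_lte(mean(pred != bayes), 2 * bayes_err)
  # the final mask is exactly the highest-mean component's voxels
  expect_equal(sum(s2$cp_mask), sum(pred == 3))
  expect_error(stage2_cluster(rnorm(20), array(TRUE, c(20, 1, 1))),
               "at least 30")
})

test_that("component relabeling changes neither stage's selection", {
  ph <- generate_phantom(small_phantom_spec(seed = 3))
  init <- build_initial_mask(ph$labels)
  s1 <- stage1_cluster(ph$image, init)
  sm <- susan_smooth(ph$image, s1$high_mask)
  s2 <- stage2_cluster(sm, s1$high_mask)
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(3, 2, 1))) {
    pf <- cpseg:::permute_components(s2$fit, perm)
    hi <- cpseg:::select_high_component(pf$means, pf$variances)
    assign <- gmm_assign(pf)
    cp <- array(FALSE, dim = dim(init))
    cp[which(s1$high_mask)[assign == hi]] <- TRUE
    expect_identical(cp, s2$cp_mask)
  }
})

test_that("manual edits follow remove-then-add order and are idempotent", {
  mask <- array(FALSE, c(10, 10, 10))
  mask[1:100] <- TRUE
  expect_identical(apply_manual_edits(mask, list()), mask)
  add <- arrayInd(101:110, dim(mask))
  rem <- arrayInd(1:4, dim(mask))
  out <- apply_manual_edits(mask, list(add = add, remove = rem))
  expect_equal(sum(out), 106L)
  expect_identical(apply_manual_edits(out, list(add = add, remove = rem)),
                   out)
  # a voxel in both lists ends up present: removal happens first
  both <- arrayInd(50, dim(mask))
  out2 <- apply_manual_edits(mask, list(add = both, remove = both))
  expect_true(out2[50])
  expect_error(apply_manual_edits(mask, list(add = cbind(11, 1, 1))),
               "outside the grid")
})

test_that("volume is voxel count times voxel volume", {
  m <- array(FALSE, c(12, 12, 12))
  m[1:1000] <- TRUE
  expect_equal(compute_volume(m, 1), 1000)
  expect_equal(compute_volume(array(FALSE, c(4, 4, 4)), 1), 0)
  m2 <- array(FALSE, c(10, 10, 10))
  m2[1:100] <- TRUE
  expect_equal(compute_volume(m2, c(1, 1, 6)), 600)
  expect_error(compute_volume(array(1, c(2, 2, 2)), 1), "logical")
})

test_that("noiseless phantoms are segmented essentially exactly", {
  ph <- generate_phantom(small_phantom_spec(noise_sd = 0))
  seg <- segment_cp(ph$image, ph$labels)
  true_vol <- compute_volume(ph$truth, ph$image$voxel_size)
  expect_lte(abs(seg$cp_volume_mm3 - true_vol) / true_vol, 0.10)
  expect_gte(dice(seg$final_cp_mask, ph$truth), 0.9)
})

test_that("masks nest and reruns are bit-identical", {
  ph <- generate_phantom(small_phantom_spec(seed = 8))
  seg <- segment_cp(ph$image, ph$labels)
  expect_true(all(seg$initial_mask[seg$stage1_high_mask]))
  expect_true(all(seg$stage1_high_mask[seg$final_cp_mask]))
  expect_equal(seg$cp_volume_mm3,
               compute_volume(seg$final_cp_mask, ph$image$voxel_size))
  seg2 <- segment_cp(ph$image, ph$labels)
  expect_identical(seg$final_cp_mask, seg2$final_cp_mask)
})

test_that("estimated volume is monotone in true blob size", {
  radii <- c(2.5, 3, 3.5, 4, 4.5)
  vols <- vapply(radii, function(r) {
    ph <- generate_phantom(small_phantom_spec(cp_blob_radius_mm = r,
                                              noise_sd = 0))
    c(true = compute_volume(ph$truth, ph$image$voxel_size),
      est = segment_cp(ph$image, ph$labels)$cp_volume_mm3)
  }, numeric(2))
  expect_equal(cor(vols["true", ], vols["est", ], method = "spearman"), 1)
})

test_that("pipeline failures carry a stage tag", {
  ph <- generate_phantom(small_phantom_spec())
  empty <- label_map(array(0L, dim = dim(ph$labels$data)))
  expect_error(segment_cp(ph$image, empty), "\\[initial_mask\\]")
  bad <- volume_image(array(1, c(4, 4, 4)))
  expect_error(segment_cp(bad, ph$labels), "mismatched grid")
})
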
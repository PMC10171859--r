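test_that("gray-matter normalization rescales, is idempotent, and validates input", {
  d <- c(6, 6, 3)
  gm <- array(FALSE, d); gm[1:3, , ] <- TRUE

  expect_equal(normalize_to_gm(toy_volume(d, 7), gm), toy_volume(d, 1))

  # GM averaging 200, one voxel at 300 -> 1.5
  v <- toy_volume(d, 200)
  v[5, 5, 2] <- 300
  expect_equal(normalize_to_gm(v, gm)[5, 5, 2], 1.5)

  # WM at 0.7x GM level lands in the NAWM band
  v <- toy_volume(d, 140); v[gm] <- 200
  nv <- normalize_to_gm(v, gm)
  expect_true(all(nv[!gm] >= 0.65 & nv[!gm] <= 0.75))

  # idempotence and the GM-mean postcondition
  set.seed(1)
  v <- array(stats::runif(prod(d), 50, 300), d)
  n1 <- normalize_to_gm(v, gm)
  expect_lt(abs(mean(n1[gm]) - 1), 1e-9)
  expect_equal(normalize_to_gm(n1, gm), n1, tolerance = 1e-9)

  expect_error(normalize_to_gm(v, array(FALSE, d)), "empty")
  expect_error(normalize_to_gm(toy_volume(d, -5), gm), "positive")
})

test_that("MTR map matches its definition and stays in [0,1) for physical inputs", {
  d <- c(5, 4, 3)
  m0 <- toy_volume(d, 2)
  expect_equal(compute_mtr(m0, m0), toy_volume(d, 0))
  expect_equal(compute_mtr(toy_volume(d, 2), toy_volume(d, 1))[1], 0.5)

  set.seed(42)
  for (rep in 1:5) {
    m0 <- array(stats::runif(prod(d), 0.5, 2), d)
    msat <- m0 * array(stats::runif(prod(d), 0.01, 1), d)  # 0 < MSAT <= M0
    got <- compute_mtr(m0, msat)
    # brute-force voxel loop oracle
    want <- array(NA_real_, d)
    for (i in seq_len(prod(d))) want[i] <- (m0[i] - msat[i]) / m0[i]
    expect_equal(got, want)
    expect_true(all(got >= 0 & got < 1))
  }
  expect_error(compute_mtr(toy_volume(c(2, 2, 2)), toy_volume(d)), "shape")
})

test_that("T1 subtraction is voxelwise post minus pre", {
  d <- c(5, 5, 2)
  pre <- array(stats::runif(prod(d)), d)
  expect_equal(t1_subtraction(pre, pre), toy_volume(d, 0))
  lesion <- array(FALSE, d); lesion[2:3, 2:3, 1] <- TRUE
  post <- pre + 0.2 * lesion
  s <- t1_subtraction(pre, post)
  expect_equal(unique(round(s[lesion], 10)), 0.2)
  expect_equal(unique(round(s[!lesion], 10)), 0)
  post2 <- array(stats::rnorm(prod(d)), d)
  expect_equal(t1_subtraction(pre, post2), post2 - pre)
  expect_error(t1_subtraction(pre, toy_volume(c(2, 2, 2))), "shape")
})

test_that("enhancement calls compare lesion mean to background mean + k*SD", {
  d <- c(8, 8, 4)
  lesion <- array(FALSE, d); lesion[3:4, 3:4, 2] <- TRUE
  bg <- !lesion

  expect_false(detect_enhancement(toy_volume(d, 0), lesion, bg)$enhancing)

  set.seed(7)
  s <- array(stats::rnorm(prod(d), 0, 0.01), d)
  s[lesion] <- s[lesion] + 0.2
  res <- detect_enhancement(s, lesion, bg)
  expect_true(res$enhancing)
  expect_equal(res$mean_enhancement, mean(s[lesion]))

  # lesion offset equal to the background mean is not a call
  s2 <- array(0.1, d)
  expect_false(detect_enhancement(s2, lesion, bg)$enhancing)
  expect_error(detect_enhancement(s, array(FALSE, d), bg), "empty")
})

test_that("lesion segmentation drops components below the 4-voxel floor", {
  d <- c(10, 10, 3)
  wm <- array(TRUE, d)
  v <- toy_volume(d, 0.7)

  # a 3-voxel suprathreshold component is below threshold -> removed
  v3 <- v; v3[2, 2:4, 1] <- 0.9
  expect_equal(max(segment_lesions(v3, wm)), 0)

  expect_equal(max(segment_lesions(v, wm)), 0)  # nothing above threshold

  # components of size 5 and 3: only the 5-voxel one survives
  v53 <- v
  v53[2, 2:6, 2] <- 0.9
  v53[8, 2:4, 2] <- 0.9
  lm <- segment_lesions(v53, wm)
  expect_equal(max(lm), 1)
  expect_equal(sum(lm == 1), 5)
  expect_true(all(which(lm == 1) %in% which(v53 > 0.8)))
})

test_that("component labeling matches a flood-fill oracle and is deterministic", {
  set.seed(13)
  for (rep in 1:8) {
    mask <- array(stats::runif(8 * 8 * 4) < 0.2, c(8, 8, 4))
    got <- label_components_3d(mask, connectivity = 26)
    want <- flood_fill_components(mask, connectivity = 26)
    # same partition: component voxel-sets agree regardless of label order
    expect_equal(max(got), max(want))
    if (max(got) > 0) {
      part <- function(lab) {
        s <- split(which(lab > 0), lab[lab > 0])
        unname(s[order(vapply(s, min, numeric(1)))])
      }
      expect_equal(part(got), part(want))
    }
    expect_identical(got, label_components_3d(mask, connectivity = 26))
  }
})

test_that("segmentation output never contains a component below min_voxels", {
  set.seed(99)
  wm <- array(TRUE, c(12, 12, 4))
  for (rep in 1:10) {
    v <- array(stats::runif(prod(dim(wm)), 0.6, 1.0), dim(wm))
    lm <- segment_lesions(v, wm, intensity_threshold = 0.9, min_voxels = 4)
    if (max(lm) > 0) expect_true(all(table(lm[lm > 0]) >= 4))
    expect_lte(sum(lm > 0), sum(v > 0.9))
  }
})

test_that("segmentation warns when the input does not look GM-normalized", {
  d <- c(6, 6, 3)
  wm <- array(TRUE, d); gm <- array(TRUE, d)
  expect_warning(segment_lesions(toy_volume(d, 5), wm, gm_mask = gm),
                 "normalized")
})
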
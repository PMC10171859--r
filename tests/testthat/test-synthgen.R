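test_that("config defaults satisfy the stated invariants", {
  cfg <- simulation_config()
  expect_lt(abs(sum(cfg$class_proportions) - 1), 1e-9)
  expect_equal(voxel_volume_ul(cfg$voxel_size_mm), 0.0225)
  expect_true(all(cfg$demyelination_duration_weeks_range > 0))
  expect_error(simulation_config(class_proportions = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(simulation_config(scan_interval_weeks = 0))
})

test_that("a lesion-free study stays in the NAWM band everywhere in WM", {
  st <- simulate_study(simulation_config(n_lesions = 0, seed = 5,
                                         n_timepoints = 6))
  expect_length(st$lesions, 0)
  cfg <- st$config
  wm <- st$timeline$wm_mask
  for (ti in seq_along(st$timeline$weeks)) {
    pdw <- normalize_to_gm(st$timeline$volumes$PDw[[ti]], st$timeline$gm_mask)
    expect_true(all(pdw[wm] <= cfg$nawm_intensity_band[2] + 5 * cfg$noise_sd))
    expect_true(all(pdw[wm] >= cfg$nawm_intensity_band[1] - 5 * cfg$noise_sd))
  }
})

test_that("noiseless remyelinated lesion returns exactly to baseline at terminal scan", {
  cfg <- simulation_config(n_lesions = 1, noise_sd = 0, seed = 21,
                           class_proportions = c(0, 0, 1))
  st <- simulate_study(cfg)
  L <- st$lesions[[1]]
  expect_equal(L$true_class, "remyelinated")
  nt <- length(st$timeline$weeks)
  pdw_first <- normalize_to_gm(st$timeline$volumes$PDw[[1]], st$timeline$gm_mask)
  pdw_last <- normalize_to_gm(st$timeline$volumes$PDw[[nt]], st$timeline$gm_mask)
  # ROI = the lesion's eventual full extent; the same voxels pre-lesion
  roi <- array(FALSE, dim(pdw_first))
  ctr <- L$center_voxel
  roi[ctr[1], ctr[2], ctr[3]] <- TRUE
  expect_equal(mean(pdw_last[roi]), mean(pdw_first[roi]), tolerance = 1e-12)
})

test_that("simulated class counts fall inside multinomial 95% intervals at n=40", {
  # oracle: per-class binomial quantiles at n=40 and p=(0.30, 0.25, 0.45)
  p <- c(early_active = 0.30, chronic_demyelinated = 0.25, remyelinated = 0.45)
  lo <- qbinom(0.025, 40, p); hi <- qbinom(0.975, 40, p)
  cfg <- simulation_config(seed = 1, n_lesions = 8)
  cls <- character(0)
  for (s in 1:5) {
    cfg$seed <- 1L + s
    st <- simulate_study(cfg)
    cls <- c(cls, vapply(st$lesions, function(L) L$true_class, character(1)))
  }
  counts <- table(factor(cls, levels = names(p)))
  expect_equal(sum(counts), 40)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("generator is deterministic: same config and seed give identical output", {
  cfg <- simulation_config(n_lesions = 3, seed = 77, n_timepoints = 22)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$timeline$volumes, b$timeline$volumes)
  expect_identical(a$lesions, b$lesions)
})

test_that("noiseless lesion intensity is monotone: rising then (remyelinated) falling", {
  cfg <- simulation_config(n_lesions = 4, noise_sd = 0, seed = 31)
  st <- simulate_study(cfg)
  d <- dim(st$timeline$gm_mask)
  for (L in st$lesions) {
    ctr <- L$center_voxel
    tr <- vapply(seq_along(st$timeline$weeks), function(ti) {
      pdw <- normalize_to_gm(st$timeline$volumes$PDw[[ti]], st$timeline$gm_mask)
      pdw[ctr[1], ctr[2], ctr[3]]
    }, numeric(1))
    weeks <- st$timeline$weeks
    peak_week <- L$onset_week + L$demyelination_duration_weeks
    demyel <- weeks >= L$onset_week & weeks <= peak_week
    expect_true(all(diff(tr[demyel]) >= -1e-12))
    if (L$true_class == "remyelinated") {
      expect_true(all(diff(tr[weeks >= peak_week]) <= 1e-12))
    } else {
      expect_equal(tr[length(tr)], max(tr))
    }
  }
})

test_that("enhancement ground truth follows the class rules at the terminal scan", {
  cfg <- simulation_config(n_lesions = 8, seed = 55)
  st <- simulate_study(cfg)
  term <- max(st$timeline$weeks)
  for (L in st$lesions) {
    if (L$true_class == "early_active")
      expect_true(term %in% L$enhancement_weeks)
    else
      expect_false(term %in% L$enhancement_weeks)
  }
})

test_that("rendered stains encode the truth: null pixels, disjoint channels, counts", {
  tr0 <- list(plp_unstained_pct = 0, lfb_unstained_pct = 10,
              oligo_count = 0L, opc_count = 7L, iba1_density = 0.1)
  s <- render_histology(tr0, roi_um = 1000, pixel_size_um = 5, seed = 2)
  expect_equal(sum(s$channels$PLP == 0), 0)
  pos <- function(ch) ch >= 0.5
  expect_false(any(pos(s$channels$ASPA) & pos(s$channels$Olig2)))
  cc <- count_cells(s$channels$ASPA, s$channels$Olig2)
  expect_equal(cc$oligo_count, 0L)
  expect_equal(cc$opc_count, 7L)

  # 25% unstained on a 200x200 image -> 10,000 +/- 400 null pixels
  tr1 <- list(plp_unstained_pct = 25, lfb_unstained_pct = 25,
              oligo_count = 3L, opc_count = 2L, iba1_density = 0.1)
  s1 <- render_histology(tr1, roi_um = 1000, pixel_size_um = 5, seed = 3)
  expect_equal(dim(s1$channels$PLP), c(200, 200))
  expect_lt(abs(sum(s1$channels$PLP == 0) - 10000), 400)

  expect_error(render_histology(list(plp_unstained_pct = 5, lfb_unstained_pct = 5,
                                     oligo_count = 5000L, opc_count = 0L,
                                     iba1_density = 0.1),
                                roi_um = 200, pixel_size_um = 5),
               "packed")
})

test_that("class-conditional histology truths have the published group ordering", {
  set.seed(8)
  draw <- function(cl, n = 200) replicate(n, histo_truth(cl, 10)$plp_unstained_pct)
  expect_gt(mean(draw("early_active")), mean(draw("chronic_demyelinated")))
  expect_gt(mean(draw("chronic_demyelinated")), mean(draw("remyelinated")))
  expect_lt(abs(mean(draw("remyelinated")) - 4.5), 1)
  expect_lt(abs(mean(draw("nawm")) - 2.6), 0.5)
})
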
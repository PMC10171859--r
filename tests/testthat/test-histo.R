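test_that("unstained percentage is the null-pixel fraction times 100", {
  ch <- matrix(0.8, 40, 25)
  expect_equal(quantify_unstained(ch), 0)
  expect_equal(quantify_unstained(matrix(0, 10, 10)), 100)

  set.seed(2)
  ch[sample.int(1000, 250)] <- 0
  expect_equal(quantify_unstained(ch), 25)
  # stained + unstained = 100 exactly
  pct_stained <- 100 * mean(ch != 0)
  expect_identical(quantify_unstained(ch) + pct_stained, 100)

  expect_error(quantify_unstained(ch, matrix(FALSE, 40, 25)), "empty")
})

test_that("cell counting separates double-positive oligodendrocytes from OPC", {
  blank <- matrix(0.1, 60, 60)
  expect_equal(count_cells(blank, blank, positivity_threshold = 0.5),
               list(oligo_count = 0L, opc_count = 0L))

  tr <- list(plp_unstained_pct = 10, lfb_unstained_pct = 10,
             oligo_count = 12L, opc_count = 5L, iba1_density = 0.1)
  s <- render_histology(tr, roi_um = 1000, pixel_size_um = 5, seed = 6)
  cc <- count_cells(s$channels$ASPA, s$channels$Olig2)
  expect_equal(cc$oligo_count, 12L)
  expect_equal(cc$opc_count, 5L)

  # every Olig2 cell fully ASPA-positive -> zero OPC
  tr2 <- list(plp_unstained_pct = 0, lfb_unstained_pct = 0,
              oligo_count = 9L, opc_count = 0L, iba1_density = 0)
  s2 <- render_histology(tr2, roi_um = 800, pixel_size_um = 5, seed = 7)
  cc2 <- count_cells(s2$channels$ASPA, s2$channels$Olig2)
  expect_equal(cc2$opc_count, 0L)

  expect_error(count_cells(blank, blank, positivity_threshold = 5), "range")
})

test_that("cell counting is invariant to placement and exact on renders", {
  tr <- list(plp_unstained_pct = 20, lfb_unstained_pct = 30,
             oligo_count = 8L, opc_count = 3L, iba1_density = 0.2)
  counts <- lapply(1:5, function(seed) {
    s <- render_histology(tr, roi_um = 1000, pixel_size_um = 5, seed = seed)
    count_cells(s$channels$ASPA, s$channels$Olig2)
  })
  for (cc in counts) expect_equal(cc, list(oligo_count = 8L, opc_count = 3L))
})

test_that("histological categorization follows the PLP/oligo/Iba1 rules", {
  m <- function(plp, lfb, oligo) list(plp_unstained_pct = plp,
                                      lfb_unstained_pct = lfb,
                                      oligo_count = oligo)
  r <- classify_histology(m(4.5, 15, 12), iba1_density = 0.05)
  expect_equal(r$category, "remyelinated"); expect_false(r$discordant)

  expect_equal(classify_histology(m(58, 63, 4), iba1_density = 0.45)$category,
               "early_active")
  expect_equal(classify_histology(m(38, 43, 3), iba1_density = 0.15)$category,
               "chronic_demyelinated")

  # remyelinated on PLP (<6%) but demyelinated on LFB (82%): flagged discordant
  dsc <- classify_histology(m(5, 82, 12), iba1_density = 0.05)
  expect_equal(dsc$category, "remyelinated")
  expect_true(dsc$discordant)
})

test_that("ROI construction supports side and literal-area conventions", {
  dimg <- c(400, 400)
  # side convention: 1500 um at 5 um/px -> 300x300 px
  roi <- roi_from_center(c(200, 200), dimg, pixel_size_um = 5, roi_spec = 1500)
  expect_equal(sum(roi), 301 * 301, tolerance = 0.01)
  # literal reading: 1500 um^2 -> ~38.7 um side -> ~8 px at 5 um/px
  roi2 <- roi_from_center(c(200, 200), dimg, pixel_size_um = 5,
                          roi_spec = 1500, spec_is_area = TRUE)
  side_px <- sqrt(sum(roi2))
  expect_lt(abs(side_px * 5 - sqrt(1500)), 5.01)
  # corner center: clipped with a warning
  expect_warning(roi3 <- roi_from_center(c(1, 1), dimg, 5, 1500), "clipped")
  expect_lt(sum(roi3), sum(roi))
  expect_error(roi_from_center(c(500, 200), dimg, 5, 1500), "outside")
})

test_that("render -> quantify round trip recovers truth within tolerance", {
  set.seed(17)
  for (rep in 1:15) {
    tr <- list(plp_unstained_pct = runif(1, 0, 80),
               lfb_unstained_pct = runif(1, 0, 80),
               oligo_count = sample(0:15, 1), opc_count = sample(0:10, 1),
               iba1_density = runif(1, 0, 0.5))
    s <- render_histology(tr, roi_um = 1000, pixel_size_um = 5, seed = rep)
    qm <- quantify_stains(s)
    expect_lt(abs(qm$plp_unstained_pct - tr$plp_unstained_pct), 1)
    expect_lt(abs(qm$lfb_unstained_pct - tr$lfb_unstained_pct), 1)
    expect_identical(qm$oligo_count, as.integer(tr$oligo_count))
    expect_identical(qm$opc_count, as.integer(tr$opc_count))
    expect_lt(abs(qm$iba1_density - tr$iba1_density), 0.02)
  }
})
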
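test_that("integrated density is the sum over the mask (mean x area)", {
  ch <- matrix(3, 5, 5)
  mask <- matrix(FALSE, 5, 5); mask[1:2, 1:5] <- TRUE
  expect_equal(integrated_density(ch, mask), 30)
  expect_equal(integrated_density(matrix(0, 5, 5), mask), 0)
  expect_equal(integrated_density(matrix(1:9, 3, 3), matrix(TRUE, 3, 3)), 45)
  expect_error(integrated_density(ch, matrix(FALSE, 5, 5)), "empty")
})

test_that("background adjustment subtracts mean background times area and clamps", {
  expect_equal(as.numeric(background_adjust(100, 10, 2)), 80)
  expect_equal(as.numeric(background_adjust(100, 10, 0)), 100)
  # uniform image at exactly the background level cancels to 0
  expect_equal(as.numeric(background_adjust(7 * 20, 20, 7)), 0)
  clamped <- background_adjust(5, 10, 2)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  expect_error(background_adjust(1, 0, 1), "mask_area")
})

test_that("cytoplasmic/nuclear arithmetic follows the definitions", {
  expect_equal(cytoplasmic_nuclear_ratio(300, 100), 2)
  expect_equal(cytoplasmic_nuclear_ratio(100, 100), 0)
  expect_equal(cytoplasmic_nuclear_ratio(150, 100), 0.5)
  expect_true(is.na(cytoplasmic_nuclear_ratio(100, 0)))

  expect_equal(dapi_normalized_level(500, 250), 2)
  expect_equal(dapi_normalized_level(0, 250), 0)
  expect_equal(dapi_normalized_level(3, 3), 1)
  expect_true(is.na(dapi_normalized_level(5, 0)))

  expect_equal(nuclear_polyA_concentration(100, 100, 10), 0.1)
  expect_equal(nuclear_polyA_concentration(0, 50, 10), 0)
  expect_equal(nuclear_polyA_concentration(100, 100, 20),
               nuclear_polyA_concentration(100, 100, 10) / 2)
})

test_that("cell_image_set validates shapes and mask containment", {
  img <- one_cell_image()
  expect_s3_class(img, "cell_image_set")
  lab <- img$cell_labels; nuc <- img$nucleus_labels
  nuc_bad <- nuc; nuc_bad[1, 1] <- 1L
  expect_error(cell_image_set(img$channels, lab, nuc_bad, img$background_roi),
               "inside its whole-cell mask")
  bg_bad <- img$background_roi; bg_bad[5, 5] <- TRUE
  expect_error(cell_image_set(img$channels, lab, nuc, bg_bad), "disjoint")
  expect_error(cell_image_set(list(a = matrix(0, 2, 2)), lab, nuc,
                              img$background_roi), "shape")
})

test_that("quantify_cells recovers the hand-computed ratio of a one-cell image", {
  # nucleus: 16 px at 10 -> 160; cytoplasm: 48 px at 5 -> 240; ratio 1.5
  img <- one_cell_image(nuclear = 10, cyto = 5)
  m <- quantify_cells(img, "signal", dapi_channel = "dapi")
  expect_equal(nrow(m), 1L)
  expect_equal(m$nuclear_id, 160)
  expect_equal(m$whole_id, 160 + 240)
  expect_equal(m$cn_ratio, 1.5)
  expect_equal(m$whole_id, m$nuclear_id + m$cyto_id)
  # DAPI: 16 px at 50 -> 800
  expect_equal(m$dapi_normalized_total, 400 / 800)
  expect_equal(m$nuclear_concentration, (160 / 800) / 16)
})

test_that("a constant offset recorded as background leaves adjusted quantities unchanged", {
  base <- quantify_cells(one_cell_image(offset = 0), "signal", dapi_channel = "dapi")
  for (offset in c(2, 7.5, 100)) {
    shifted <- quantify_cells(one_cell_image(offset = offset), "signal",
                              dapi_channel = "dapi")
    for (col in c("adjusted_whole_id", "adjusted_nuclear_id", "adjusted_cyto_id",
                  "cn_ratio", "dapi_normalized_total", "nuclear_concentration")) {
      expect_equal(shifted[[col]], base[[col]], tolerance = 1e-9)
    }
  }
})

test_that("rescaling a channel scales integrated densities but not the ratio", {
  img <- one_cell_image(nuclear = 10, cyto = 5, offset = 3)
  base <- quantify_cells(img, "signal")
  for (s in c(0.25, 4)) {
    img2 <- img
    img2$channels$signal <- img$channels$signal * s
    scaled <- quantify_cells(img2, "signal")
    expect_equal(scaled$whole_id, base$whole_id * s)
    expect_equal(scaled$adjusted_nuclear_id, base$adjusted_nuclear_id * s)
    expect_equal(scaled$cn_ratio, base$cn_ratio, tolerance = 1e-12)
  }
})

test_that("border-touching cells are excluded and empty masks warn", {
  img <- one_cell_image()
  lab <- img$cell_labels; nuc <- img$nucleus_labels
  lab[1:3, 1:3] <- 2L; nuc[2, 2] <- 2L       # second cell on the border
  img2 <- cell_image_set(img$channels, lab, nuc, img$background_roi)
  expect_message(m <- quantify_cells(img2, "signal"), "excluded 1 border")
  expect_equal(m$cell_id, 1L)

  empty <- cell_image_set(img$channels,
                          matrix(0L, 14, 14), matrix(0L, 14, 14),
                          img$background_roi)
  expect_warning(m0 <- quantify_cells(empty, "signal"), "no cells")
  expect_equal(nrow(m0), 0L)
})

test_that("negative adjusted signal is clamped and flagged per cell", {
  img <- one_cell_image(nuclear = 1, cyto = 1, offset = 0)
  # make the background ROI brighter than the cell
  img$channels$signal[img$background_roi] <- 50
  m <- quantify_cells(img, "signal")
  expect_true(m$clamped)
  expect_equal(m$adjusted_whole_id, 0)
  expect_true(is.na(m$cn_ratio))   # nuclear signal clamped to 0 -> undefined
})

test_that("DAPI normalization can use raw instead of adjusted densities", {
  img <- one_cell_image(nuclear = 10, cyto = 5, offset = 2)
  raw <- quantify_cells(img, "signal", dapi_channel = "dapi",
                        dapi_use_adjusted = FALSE)
  # raw whole ID includes the offset over 64 px; raw DAPI over 16 px
  expect_equal(raw$dapi_normalized_total,
               (160 + 240 + 2 * 64) / (16 * 50 + 2 * 16))
})

test_that("channel TIFFs and label masks round-trip through files", {
  img <- one_cell_image(nuclear = 10.25, cyto = 5.5, offset = 1.2)
  d <- withr::local_tempdir()
  write_cell_image_dir(img, d)
  back <- read_cell_image_dir(d)
  expect_identical(back$cell_labels, img$cell_labels)
  expect_identical(back$nucleus_labels, img$nucleus_labels)
  expect_identical(back$background_roi, img$background_roi)
  # 32-bit storage at full scale 65535 resolves ~1.5e-5 intensity units
  expect_lt(max(abs(back$channels$signal - img$channels$signal)), 1e-4)
  m_file <- quantify_cells(back, "signal")
  m_mem <- quantify_cells(img, "signal")
  expect_equal(m_file$cn_ratio, m_mem$cn_ratio, tolerance = 1e-4)
})

test_that("the DAPI threshold segmenter labels synthetic nuclei", {
  sim <- simulate_cell_image(cell_sim_config(n_cells = 5, image_shape = c(128L, 128L),
                                             noise_sd = 0, seed = 3))
  lab <- nucleus_mask_from_dapi(sim$images$channels$dapi)
  expect_equal(max(lab), 5)
  # every true nucleus is covered by exactly one segmented component
  for (k in 1:5) {
    seg <- lab[sim$images$nucleus_labels == k]
    expect_equal(length(unique(seg)), 1L)
    expect_gt(unique(seg), 0L)
  }
})
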
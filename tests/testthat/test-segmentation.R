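test_that("a constant frame is rejected with the external-mask hint", {
  frame <- matrix(40L, 96, 200)
  err <- expect_error(segment_pillars(frame, "type1"),
                      class = "pillartrack_segmentation_error")
  expect_match(conditionMessage(err), "external", ignore.case = TRUE)
})

test_that("automatic segmentation recovers both synthetic caps", {
  gen <- generate_movie(small_spec(noise_sd = 0.02, seed = 21L))
  frame <- get_frame(gen$movie, 1)
  masks <- segment_pillars(frame, "type1")
  truth <- gen$truth$masks
  for (side in c("left", "right")) {
    got <- masks[[side]]
    want <- truth[[side]]
    expect_gte(jaccard(got, want), 0.5)
    cen <- pillartrack:::mask_centroid(got)
    bb <- pillartrack:::mask_bbox(want)
    expect_true(cen[1] >= bb["rmin"] && cen[1] <= bb["rmax"])
    expect_true(cen[2] >= bb["cmin"] && cen[2] <= bb["cmax"])
  }
  # left/right assignment follows centroid columns
  expect_lt(pillartrack:::mask_centroid(masks$left)[2],
            pillartrack:::mask_centroid(masks$right)[2])
  # determinism: identical frame, identical masks
  again <- segment_pillars(frame, "type1")
  expect_identical(unclass(masks$left), unclass(again$left))
  expect_identical(unclass(masks$right), unclass(again$right))
})

test_that("external masks load from text grids and binary PNG", {
  grid <- matrix(0L, 64, 64)
  grid[30:34, 20:24] <- 1L
  path <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(grid, path, row.names = FALSE, col.names = FALSE)
  m <- load_external_mask(path, "left", dim = c(64, 64))
  expect_equal(sum(m), 25)
  expect_s3_class(m, "pt_mask")

  png_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(grid + 0.0, png_path)
  m2 <- load_external_mask(png_path, "left")
  expect_identical(unclass(m2)[TRUE], unclass(m)[TRUE])

  bad <- grid; bad[1, 1] <- 2L
  path2 <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(bad, path2, row.names = FALSE, col.names = FALSE)
  expect_error(load_external_mask(path2, "left"), "0 or 1")

  utils::write.table(matrix(0L, 8, 8), path2, row.names = FALSE,
                     col.names = FALSE)
  expect_error(load_external_mask(path2, "left"), "zero area")
  expect_error(load_external_mask(path, "left", dim = c(32, 32)), "32 x 32")
})

test_that("mask perturbation follows Minkowski arithmetic with a 5x5 kernel", {
  grid <- matrix(0L, 40, 40)
  grid[16:24, 16:24] <- 1L  # 9x9 block
  m <- pt_mask(grid, "left")
  er <- perturb_mask(m, "erode", 1)
  expect_equal(sum(er), 25)  # 5x5 survives
  expect_equal(unname(pillartrack:::mask_bbox(er)),
               c(18, 22, 18, 22))
  di <- perturb_mask(m, "dilate", 1)
  expect_equal(sum(di), 13 * 13)
  small <- matrix(0L, 40, 40); small[18:22, 18:22] <- 1L
  expect_error(perturb_mask(pt_mask(small, "left"), "erode", 4),
               class = "pillartrack_empty_mask_error")
  expect_error(perturb_mask(m, "erode", 0), "at least 1")
})

test_that("erosion and dilation satisfy morphological duality", {
  for (seed in 1:3) {
    set.seed(seed)
    z <- matrix(stats::rnorm(60 * 60), 60, 60)
    k <- c(1, 4, 6, 4, 1) / 16
    sm <- pillartrack:::conv_sep(pillartrack:::conv_sep(z, k), k)
    mask <- matrix(as.integer(sm > stats::quantile(sm, 0.8)), 60, 60)
    if (sum(mask) == 0) next
    m <- pt_mask(mask, "left", check_connected = FALSE)
    open_then <- tryCatch(
      perturb_mask(perturb_mask(m, "erode", 1), "dilate", 1),
      pillartrack_empty_mask_error = function(e) NULL
    )
    if (!is.null(open_then)) {
      expect_true(all(open_then <= m))  # opening shrinks
    }
    close_then <- perturb_mask(perturb_mask(m, "dilate", 1), "erode", 1)
    expect_true(all(close_then >= m))  # closing grows
  }
})
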
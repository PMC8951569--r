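# Normalized cross-correlation, frame association, sequence tracking.

test_that("NCC analytic cases: self, negation, affine invariance", {
  set.seed(31)
  a <- matrix(runif(144), 12, 12)
  expect_equal(normalized_cross_correlation(a, a), 1)
  expect_equal(normalized_cross_correlation(a, 1 - a), -1)
  b <- matrix(runif(144), 12, 12)
  r0 <- normalized_cross_correlation(a, b)
  expect_lt(abs(normalized_cross_correlation(2.7 * a + 0.3, b) - r0), 1e-12)
  expect_lt(abs(normalized_cross_correlation(a, 0.02 * b - 5) - r0), 1e-12)
  expect_equal(normalized_cross_correlation(a, b),
               normalized_cross_correlation(b, a))
})

test_that("NCC equals the brute-force Pearson loop, with and without masks", {
  set.seed(32)
  for (k in 1:25) {
    n <- sample(6:16, 1)
    a <- matrix(runif(n * n), n, n)
    b <- matrix(runif(n * n), n, n)
    expect_lt(abs(normalized_cross_correlation(a, b) - pearson_loop(a, b)), 1e-10)
    region <- matrix(runif(n * n) < 0.5, n, n)
    if (sum(region) >= 2) {
      expect_lt(abs(normalized_cross_correlation(a, b, region) -
                    pearson_loop(a, b, region)), 1e-10)
    }
  }
})

test_that("NCC stays within [-1, 1] and flags degenerate inputs", {
  set.seed(33)
  for (k in 1:300) {
    a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
    r <- normalized_cross_correlation(a, b)
    expect_true(r >= -1 && r <= 1)
  }
  flat <- matrix(1, 8, 8)
  expect_error(normalized_cross_correlation(flat, a),
               class = "corotrack_degenerate_error")
  region <- matrix(FALSE, 8, 8); region[1, 1] <- TRUE
  expect_error(normalized_cross_correlation(a, b, region),
               class = "corotrack_validation_error")
  expect_error(normalized_cross_correlation(a, matrix(0, 4, 4)),
               class = "corotrack_validation_error")
})

make_toy_bank <- function(images, masks, start, end, n) {
  seq <- cine_sequence(images)
  template_bank_from_masks(seq, contrast_window(start, end, n), masks,
                           dilation_radius_px = 0L)
}

test_that("a template matched against its own image wins with score 1", {
  set.seed(34)
  images <- lapply(1:4, function(i) matrix(runif(100), 10, 10))
  masks <- lapply(1:2, function(i) {
    m <- matrix(FALSE, 10, 10); m[3:6, 3:6] <- TRUE; m
  })
  bank <- make_toy_bank(images, masks, 2, 3, 4)
  res <- match_frame(images[[4]], bank, region_mode = "full", query_index = 3L)
  expect_identical(res$best_template_index, 3L)
  expect_equal(res$score, 1)
  expect_equal(unname(res$score), max(res$all_scores))
  expect_identical(res$transferred_contour$source_frame_index, 3L)
  expect_identical(res$transferred_contour$polylines,
                   bank$templates[[2]]$contour$polylines)
})

test_that("exact score ties resolve to the lowest template frame index", {
  set.seed(35)
  img <- matrix(runif(100), 10, 10)
  images <- list(img, img + 0, img + 0, matrix(runif(100), 10, 10))
  masks <- lapply(1:2, function(i) {
    m <- matrix(FALSE, 10, 10); m[2:4, 2:4] <- TRUE; m
  })
  bank <- make_toy_bank(images, masks, 0, 1, 4)  # identical template images
  res <- match_frame(images[[3]], bank, region_mode = "full", query_index = 2L)
  expect_identical(res$best_template_index, 0L)
  expect_equal(res$score, 1)
})

test_that("degenerate comparisons score 0 and never beat a real match", {
  set.seed(36)
  images <- list(matrix(0.5, 10, 10),            # constant template
                 matrix(runif(100), 10, 10),
                 matrix(runif(100), 10, 10))
  masks <- lapply(1:2, function(i) {
    m <- matrix(FALSE, 10, 10); m[2:4, 2:4] <- TRUE; m
  })
  bank <- make_toy_bank(images, masks, 0, 1, 3)
  res <- suppressMessages(match_frame(images[[2]], bank, region_mode = "full",
                                      query_index = 2L))
  expect_identical(res$best_template_index, 1L)
  expect_identical(unname(res$all_scores[1]), 0)
})

test_that("track_sequence validates indices and preserves order", {
  out <- generate_synthetic_cine(small_phantom_config())
  w <- out$truth$true_bolus_window
  bank <- suppressMessages(build_template_bank(out$sequence, w))
  expect_identical(track_sequence(out$sequence, bank, integer(0)), list())
  expect_error(track_sequence(out$sequence, bank, c(0L, 12L)),
               class = "corotrack_validation_error")
  expect_error(track_sequence(out$sequence, bank, 99L),
               class = "corotrack_validation_error")

  res <- track_sequence(out$sequence, bank, dye_free_indices(w, 30))
  expect_length(res, 10)
  expect_identical(vapply(res, function(r) r$query_frame_index, integer(1)), 0:9)
  for (r in res) {
    expect_gt(length(r$transferred_contour$polylines), 0)
    expect_true(r$best_template_index %in% bank_frame_indices(bank))
    expect_equal(unname(r$score), max(r$all_scores))
  }
})

test_that("matching recovers the cardiac phase on a synthetic cycle", {
  out <- generate_synthetic_cine(small_phantom_config(seed = 37L))
  w <- out$truth$true_bolus_window
  P <- out$truth$period_frames
  bank <- suppressMessages(build_template_bank(out$sequence, w))
  res <- track_sequence(out$sequence, bank, dye_free_indices(w, 30))
  for (r in res) {
    dphi <- abs(out$truth$true_phase[r$best_template_index + 1] -
                out$truth$true_phase[r$query_frame_index + 1]) %% P
    expect_lte(min(dphi, P - dphi), 1)
  }
})
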
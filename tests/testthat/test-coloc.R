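test_that("Pearson colocalization on exact channel relationships", {
  a <- matrix(runif(64, 10, 100), 8, 8)
  expect_equal(pearson_coloc(a, a)$r, 1)
  expect_equal(pearson_coloc(a, max(a) - a)$r, -1)
  expect_error(pearson_coloc(a, matrix(5, 8, 8)), "constant")
  expect_error(image_pair(a, matrix(1, 4, 4)), "identical shapes")
  expect_error(image_pair(matrix(1), matrix(1)), "degenerate")
  expect_error(image_pair(-a, a), ">= 0")
})

test_that("r is invariant to positive affine transforms of either channel", {
  p <- simulate_image_pair(0.4, shape = c(16, 16), seed = 21)
  r0 <- pearson_coloc(p)$r
  expect_equal(pearson_coloc(3 * p$channel_a + 7, p$channel_b)$r, r0,
               tolerance = 1e-12)
  expect_equal(pearson_coloc(p$channel_a, 0.5 * p$channel_b + 100)$r, r0,
               tolerance = 1e-12)
})

test_that("masking restricts the pixel set without failing", {
  p <- simulate_image_pair(0.3, shape = c(16, 16), seed = 22)
  mask <- matrix(FALSE, 16, 16); mask[1:8, ] <- TRUE
  r <- pearson_coloc(p, mask = mask)
  expect_equal(r$n_pixels, 128L)
  two <- matrix(FALSE, 16, 16); two[1, 1:2] <- TRUE
  expect_equal(pearson_coloc(p, mask = two)$n_pixels, 2L)
  expect_error(image_pair(p$channel_a, p$channel_b,
                          mask = matrix(FALSE, 16, 16)), "2 pixels")
  thr <- pearson_coloc(p, threshold = stats::median(p$channel_a +
                                                      p$channel_b))
  expect_lt(thr$n_pixels, 256L)
})

test_that("replicate summaries average within experiment first", {
  s <- summarize_coloc(c(0.25, 0.27, 0.26))
  expect_equal(s$mean, 0.26)
  expect_equal(s$sd, 0.01)
  expect_equal(s$n, 3L)
  expect_equal(summarize_coloc(c(0.3, 0.3, 0.3))$sd, 0)
  # unbalanced 2-experiment toy, checked by hand: experiment means are
  # (0.2+0.4)/2 = 0.3 and (0.1+0.2+0.3+0.8)/4 = 0.35 -> nested mean 0.325,
  # while the flat mean of all six values is 0.3333...
  r <- c(0.2, 0.4, 0.1, 0.2, 0.3, 0.8)
  ex <- c(1, 1, 2, 2, 2, 2)
  nested <- summarize_coloc(r, ex)
  expect_equal(nested$mean, 0.325)
  expect_equal(nested$n, 2L)
  expect_false(isTRUE(all.equal(nested$mean, mean(r))))
  expect_error(summarize_coloc(0.5), "insufficient")
  # list-of-results input
  p <- lapply(1:3, function(s) {
    pearson_coloc(simulate_image_pair(0.5, c(16, 16), seed = s))
  })
  expect_type(summarize_coloc(p)$mean, "double")
})

test_that("image matrices round-trip through text files", {
  p <- simulate_image_pair(0.7, shape = c(12, 9), seed = 30)
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  write_image_matrix(p$channel_a, f)
  back <- read_image_matrix(f)
  expect_equal(dim(back), c(12L, 9L))
  expect_equal(unname(back), unname(p$channel_a), tolerance = 1e-8)
})
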
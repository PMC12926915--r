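test_that("FFT cross-correlation equals the nested-loop oracle", {
  set.seed(60)
  a <- matrix(runif(256), 16)
  b <- matrix(runif(256), 16)
  gr <- proxitome:::cross_correlation_grid(a, b)
  for (dx in c(-5, -1, 0, 2, 6)) {
    for (dy in c(-4, 0, 3)) {
      idx <- which(gr$dx == dx & gr$dy == dy)
      expect_lt(abs(gr$g[idx] - ccf_loop_oracle(a, b, dx, dy)), 1e-9)
    }
  }
})

test_that("G(0) is maximal for identical channels; shifts are located", {
  set.seed(61)
  a <- matrix(runif(1024), 32)
  p <- proxitome:::as_image_pair(a, a, 1)
  prof <- cross_correlation_profile(p, max_d = 10, bin_width = 1)
  expect_equal(which.max(prof$G), 1)
  # translated copy: unaveraged argmax sits at the planted displacement
  a2 <- matrix(0, 32, 32); a2[10:14, 12:16] <- matrix(runif(25), 5)
  b2 <- matrix(0, 32, 32); b2[13:17, 14:18] <- a2[10:14, 12:16]
  g2 <- proxitome:::cross_correlation_grid(a2 + 0.1, b2 + 0.1)
  best <- which.max(ifelse(g2$valid, g2$g, -Inf))
  expect_equal(c(g2$dx[best], g2$dy[best]), c(3, 2))
})

test_that("independent noise decorrelates G at every displacement", {
  set.seed(62)
  a <- matrix(runif(64 * 64), 64)
  b <- matrix(runif(64 * 64), 64)
  prof <- cross_correlation_profile(proxitome:::as_image_pair(a, b, 1),
                                    max_d = 20, bin_width = 2)
  expect_true(all(abs(prof$G) < 0.05))
})

test_that("pearson colocalization respects linear relations", {
  set.seed(63)
  a <- matrix(runif(400), 20)
  expect_equal(pearson_colocalization(proxitome:::as_image_pair(a, 2 * a, 1)),
               1, tolerance = 1e-9)
  expect_equal(pearson_colocalization(
    proxitome:::as_image_pair(a, max(a) - a, 1)), -1, tolerance = 1e-9)
  expect_error(pearson_colocalization(
    proxitome:::as_image_pair(matrix(1, 20, 20), a, 1)), "constant")
  # independent large noise fields are uncorrelated
  set.seed(64)
  n1 <- matrix(runif(256^2), 256); n2 <- matrix(runif(256^2), 256)
  expect_lt(abs(pearson_colocalization(proxitome:::as_image_pair(n1, n2, 1))),
            0.05)
})

test_that("radius delta supports both area and radius readings", {
  rd <- radius_delta(200, 100)
  expect_equal(rd$delta, 50)
  expect_equal(rd$equivalent_radius, sqrt(200 / pi) - sqrt(100 / pi),
               tolerance = 1e-12)
  expect_equal(radius_delta(200, 100, mode = "equivalent_radius")$delta,
               2.3369, tolerance = 1e-4)
  expect_equal(radius_delta(7, 7)$delta, 0)
  expect_equal(radius_delta(7, 7, mode = "equivalent_radius")$delta, 0)
  expect_error(radius_delta(-1, 5), "negative")
})

test_that("the randomized null averages exactly 7 symmetry profiles", {
  set.seed(65)
  a <- matrix(runif(32 * 32), 32)
  b <- matrix(runif(32 * 32), 32)
  pr <- proxitome:::as_image_pair(a, b, 1)
  nul <- randomized_null_profile(pr, max_d = 8, bin_width = 1)
  expect_equal(ncol(attr(nul, "per_transform")), 7)
  expect_equal(nul$G_RAND, rowMeans(attr(nul, "per_transform")))
  # a fully symmetric channel B: every transform leaves it unchanged
  xs <- matrix(seq_len(32), 32, 32)
  r2 <- (xs - 16.5)^2 + (t(xs) - 16.5)^2
  sym <- exp(-r2 / 60)
  pr_sym <- proxitome:::as_image_pair(a, sym, 1)
  g <- cross_correlation_profile(pr_sym, max_d = 8, bin_width = 1)
  nul_sym <- randomized_null_profile(pr_sym, max_d = 8, bin_width = 1)
  expect_equal(nul_sym$G_RAND, g$G, tolerance = 1e-12)
})

test_that("C is scale-invariant and equals 1 for symmetric structure", {
  set.seed(66)
  cfg <- sim_config(seed = 7)
  pr <- simulate_image_pair(cfg, halo = FALSE)
  c1 <- coloc_profile(pr, max_d = 1.2, bin_width = 0.06)
  pr_scaled <- proxitome:::as_image_pair(pr$a * 3.7, pr$b, pr$pixel_size)
  c2 <- coloc_profile(pr_scaled, max_d = 1.2, bin_width = 0.06)
  expect_equal(c1$C, c2$C, tolerance = 1e-9)
  # colocalized spots: C(0) above 1, approaching 1 at large displacement
  expect_gt(c1$C[1], 1)
  expect_lt(abs(tail(c1$C, 1) - 1), 0.1)
})

test_that("condition summary flags colocalized sets but not noise", {
  pos <- lapply(1:6, function(i) {
    coloc_profile(simulate_image_pair(sim_config(seed = 100 + i),
                                      halo = FALSE),
                  max_d = 1.2, bin_width = 0.06)
  })
  set.seed(67)
  neg <- lapply(1:6, function(i) {
    a <- matrix(runif(128^2), 128); b <- matrix(runif(128^2), 128)
    coloc_profile(proxitome:::as_image_pair(a, b, 0.03),
                  max_d = 1.2, bin_width = 0.06)
  })
  st_pos <- coloc_condition_stats(pos)
  st_neg <- coloc_condition_stats(neg)
  expect_lt(st_pos$test_above_1, 0.05)
  expect_gt(st_neg$test_above_1, 0.05)
  expect_true(all(c("lo80", "hi80") %in% names(st_pos$summary)))
  expect_lt(st_pos$test_vs_reference <-
              coloc_condition_stats(pos, reference = neg)$test_vs_reference,
            0.05)
  expect_warning(coloc_condition_stats(pos[1:2]), "fewer than 3")
})

test_that("max_d beyond the half-image is truncated with a warning", {
  set.seed(68)
  a <- matrix(runif(16 * 16), 16)
  pr <- proxitome:::as_image_pair(a, a, 1)
  expect_warning(prof <- cross_correlation_profile(pr, max_d = 50,
                                                   bin_width = 1),
                 "truncated")
  expect_lte(max(prof$d), 9)
})
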
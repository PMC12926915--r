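test_that("design encoding is treatment-coded and drops absent/aliased columns", {
  des <- rbind(
    expand.grid(bait = "A_UP", labtime = c(1, 5, 15)),
    expand.grid(bait = "A_DOWN", labtime = c(1, 3, 5, 15)),
    expand.grid(bait = "ITS2", labtime = c(1, 5, 15)))
  des$bait <- as.character(des$bait)
  x <- build_lasso_design(des)
  # main effects for non-reference labtimes; interactions for non-ref baits
  expect_true(all(c("labtime3", "labtime5", "labtime15",
                    "labtime1:baitA_DOWN", "labtime1:baitITS2") %in%
                    colnames(x)))
  # labtime 3 exists only for A_DOWN: its interaction aliases the main
  # effect and must not appear twice
  expect_false("labtime3:baitA_DOWN" %in% colnames(x))
  expect_equal(qr(cbind(1, x))$rank, ncol(x) + 1)
  expect_error(build_lasso_design(data.frame(bait = "b", labtime = 1),
                                  bait_ref = "missing"), "reference")
})

test_that("lasso at lambda=0 equals the normal-equations solution", {
  set.seed(11)
  x <- matrix(rnorm(50 * 4), 50, 4)
  y <- rnorm(50)
  cf <- lasso_at_lambda(y, x, 0)
  ls <- unname(coef(lm(y ~ x)))
  expect_lt(max(abs(unname(cf) - ls)), 1e-6)
})

test_that("single-predictor solutions follow the soft threshold", {
  x <- matrix(c(1, -1, 1, -1), ncol = 1)
  y <- c(2, -2, 2, -2)
  expect_equal(unname(lasso_at_lambda(y, x, 0.5)[2]), 1.5)
  expect_equal(unname(lasso_at_lambda(y, x, 2.5)[2]), 0)
})

test_that("l1 norm is monotone along the lambda path", {
  set.seed(12)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- x[, 1] * 2 + rnorm(40)
  fit <- lasso_fit_cv(y, x, nfolds = 5, seed = 1)
  l1 <- colSums(abs(as.matrix(fit$glmnet_fit$beta)))
  # glmnet path is decreasing in lambda: l1 norms must be non-decreasing
  expect_true(all(diff(l1) >= -1e-8))
})

test_that("sigma estimate is calibrated and shift-invariant", {
  set.seed(13)
  x <- matrix(rnorm(200 * 5), 200, 5)
  sigs <- replicate(10, {
    y <- rnorm(200)
    estimate_sigma(y, x, seed = sample.int(1e6, 1))
  })
  expect_true(mean(sigs > 0.8 & sigs < 1.2) >= 0.9)
  # exact linear signal, no noise: only the shrinkage bias of the
  # cross-validated lambda remains (a few percent of sd(y))
  y_lin <- as.numeric(x %*% c(1, -2, 0.5, 0, 0))
  expect_lt(estimate_sigma(y_lin, x, seed = 1), 0.05 * sd(y_lin))
  # adding a constant is absorbed by the intercept
  y <- rnorm(200)
  expect_equal(estimate_sigma(y, x, seed = 5),
               estimate_sigma(y + 7, x, seed = 5), tolerance = 1e-8)
})

test_that("selective p-values: empty active set yields an empty result", {
  set.seed(14)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- rnorm(30)
  pv <- selective_pvalues(sigma = 1, y = y, x = x,
                          beta = setNames(rep(0, 3), paste0("V", 1:3)),
                          lambda = 10)
  expect_length(pv, 0)
})

test_that("selective p matches a truncated-normal quadrature oracle", {
  set.seed(3)
  n <- 100
  xo <- matrix(rnorm(n), ncol = 1)
  xo <- (xo - mean(xo)) / sqrt(mean((xo - mean(xo))^2))
  lam <- 0.05
  checked <- 0
  for (s in 1:40) {
    set.seed(s)
    y <- rnorm(n)
    bet <- lasso_at_lambda(y, xo, lam)[-1]
    if (bet == 0) next
    pv <- selective_pvalues(sigma = 1, y = y, x = xo, beta = bet,
                            lambda = lam)
    yc <- y - mean(y)
    stat <- sum(xo * yc) / sum(xo^2)
    tau <- 1 / sqrt(sum(xo^2))
    vl <- attr(pv, "vlims")
    # orient the (one-sided) truncation onto the positive axis
    if (is.finite(vl[2])) { a <- -vl[2]; z <- -stat } else {
      a <- vl[1]; z <- stat
    }
    b <- a + 30 * tau
    den <- integrate(function(t) dnorm(t, 0, tau), a, b)$value
    num <- integrate(function(t) dnorm(t, 0, tau),
                     min(max(z, a), b), b)$value
    f <- 1 - num / den
    expect_equal(as.numeric(pv), 2 * min(f, 1 - f), tolerance = 1e-4)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("interactome calls follow the sign and significance rules", {
  mk_fit <- function(beta, pv) {
    structure(list(beta = beta, selective_p = pv), class = "prox_lasso")
  }
  fits <- list(
    in_down = mk_fit(c(`labtime5:baitA_DOWN` = 2),
                     c(`labtime5:baitA_DOWN` = 0.01)),
    not_sig = mk_fit(c(`labtime5:baitA_DOWN` = 2),
                     c(`labtime5:baitA_DOWN` = 0.2)),
    in_up = mk_fit(c(`labtime5:baitA_DOWN` = -2),
                   c(`labtime5:baitA_DOWN` = 0.01)),
    multi = mk_fit(c(`labtime5:baitITS2` = 0.5, `labtime15:baitITS2` = -3),
                   c(`labtime5:baitITS2` = 0.03, `labtime15:baitITS2` = 0.01)))
  calls <- interactome_calls(fits, p_cut = 0.05)
  expect_true("in_down" %in% calls$sets$A_DOWN)
  expect_false("not_sig" %in% unlist(calls$sets))
  expect_true("in_up" %in% calls$sets$A_UP)
  # largest-magnitude significant interaction decides the sign
  expect_true("multi" %in% calls$sets$A_UP)
  expect_false("multi" %in% unlist(calls$sets["ITS2"]))
})
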
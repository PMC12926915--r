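#' Treatment-coded design matrix for labelling-time x bait models
#'
#' Encodes `log2(LFQ) ~ labtime + labtime:bait`: labelling time as a
#' categorical main effect with the earliest time as reference, plus one
#' interaction indicator per (labtime, bait) combination for every
#' non-reference bait. Combinations never sampled (e.g. a labelling time
#' measured for one bait only) produce structurally absent columns, which
#' are dropped.
#'
#' @param design Data frame with `bait` and `labtime` columns (one row per
#'   sample, in sample order).
#' @param bait_ref Reference bait (default `"A_UP"`).
#' @return Numeric design matrix (samples x terms, no intercept column);
#'   main effects named `labtime<t>`, interactions `labtime<t>:bait<b>`.
#' @export
build_lasso_design <- function(design, bait_ref = "A_UP") {
  stopifnot(all(c("bait", "labtime") %in% names(design)))
  if (!bait_ref %in% design$bait) stop("reference bait not in design")
  times <- sort(unique(design$labtime))
  baits <- setdiff(unique(design$bait), bait_ref)
  cols <- list()
  for (t in times[-1]) {
    cols[[sprintf("labtime%g", t)]] <- as.numeric(design$labtime == t)
  }
  for (t in times) {
    for (b in baits) {
      cols[[sprintf("labtime%g:bait%s", t, b)]] <-
        as.numeric(design$labtime == t & design$bait == b)
    }
  }
  x <- do.call(cbind, cols)
  x <- x[, colSums(x) > 0, drop = FALSE]
  # a labelling time sampled for exactly one bait makes that bait's
  # interaction an exact duplicate of the main effect; keep the first
  # (main-effect) copy so the design stays identifiable
  x[, !duplicated(t(x)), drop = FALSE]
}

#' LASSO fit with cross-validated lambda
#'
#' Coordinate-descent LASSO (via glmnet) on the objective
#' `(1/2n) ||y - Xb||^2 + lambda ||b||_1` with column standardization and
#' an unpenalized intercept. The lambda path descends from the smallest
#' lambda with all coefficients zero over `nlambda` log-spaced values;
#' `lambda_min` minimizes the cross-validated mean squared error over
#' `nfolds` plain-random seeded folds.
#'
#' @param y Numeric response (log2 LFQ for one protein).
#' @param x Design matrix from [build_lasso_design()] (or any numeric
#'   matrix).
#' @param nfolds CV folds (default 11).
#' @param thresh,maxit Coordinate-descent convergence tolerance and
#'   iteration cap (defaults 1e-28 and 1e7).
#' @param seed Seed for fold assignment.
#' @param nlambda,lambda.min.ratio Path length and depth (100 values over
#'   4 decades).
#' @return Object of class `prox_lasso`: list with `beta` (named, original
#'   scale, no intercept), `intercept`, `lambda_min`, `lambda_path`,
#'   `cv_mse`, `active` (names of nonzero terms), `y`, `x`, `foldid`.
#' @export
lasso_fit_cv <- function(y, x, nfolds = 11, thresh = 1e-28, maxit = 1e7,
                         seed = 1L, nlambda = 100, lambda.min.ratio = 1e-4) {
  n <- length(y)
  stopifnot(nrow(x) == n, n >= nfolds)
  set.seed(derive_seed(seed, "cvfolds"))
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  cv <- glmnet::cv.glmnet(x, y, nfolds = nfolds, foldid = foldid,
                          thresh = thresh, maxit = maxit, nlambda = nlambda,
                          lambda.min.ratio = lambda.min.ratio,
                          standardize = TRUE, intercept = TRUE)
  cf <- as.matrix(coef(cv, s = "lambda.min"))
  beta <- setNames(cf[-1, 1], rownames(cf)[-1])
  structure(list(beta = beta, intercept = cf[1, 1],
                 lambda_min = cv$lambda.min, lambda_path = cv$lambda,
                 cv_mse = cv$cvm, active = names(beta)[beta != 0],
                 y = y, x = x, foldid = foldid, glmnet_fit = cv$glmnet.fit),
            class = "prox_lasso")
}

#' @export
print.prox_lasso <- function(x, ...) {
  cat(sprintf("<prox_lasso> n = %d, p = %d, lambda_min = %.4g, active = {%s}\n",
              length(x$y), ncol(x$x), x$lambda_min,
              paste(x$active, collapse = ", ")))
  if (!is.null(x$selective_p)) {
    cat("selective p-values:\n"); print(round(x$selective_p, 4))
  }
  invisible(x)
}

#' LASSO coefficients at a fixed lambda
#'
#' Fits the same standardized, intercept-including LASSO at one given
#' lambda (0 allowed: the full least-squares limit).
#'
#' @inheritParams lasso_fit_cv
#' @param lambda Penalty value on the `(1/2n)` objective scale.
#' @return Named coefficient vector including `(Intercept)`.
#' @export
lasso_at_lambda <- function(y, x, lambda, thresh = 1e-28, maxit = 1e7) {
  x <- as.matrix(x)
  if (ncol(x) == 1) {
    # single-column case in closed form (soft threshold on the
    # standardized column; coordinate descent would do the same update)
    sdev <- sqrt(mean((x - mean(x))^2))
    xs <- (x - mean(x)) / sdev
    yc <- y - mean(y)
    rho <- mean(xs * yc)
    bt <- sign(rho) * max(abs(rho) - lambda, 0)
    beta <- bt / sdev
    return(setNames(c(mean(y) - beta * mean(x), beta),
                    c("(Intercept)", colnames(x) %||% "V1")))
  }
  sdev <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  lam_max <- max(abs(crossprod(scale(x, scale = ifelse(sdev > 0, sdev, 1)),
                               y - mean(y)))) / length(y)
  path <- sort(unique(c(lam_max * 10^seq(0, -4, length.out = 60), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, lambda = path, thresh = thresh, maxit = maxit,
                        standardize = TRUE, intercept = TRUE)
  cf <- as.matrix(coef(fit))  # lambda is on the fitted path by construction
  j <- which.min(abs(fit$lambda - lambda))
  setNames(cf[, j], rownames(cf))
}

#' Residual noise estimate at the cross-validated lambda
#'
#' `sigma = sqrt(RSS / (n - df - 1))` where RSS is the residual sum of
#' squares of the cross-validated-lambda LASSO fit and `df` is the active-
#' set size.
#'
#' @inheritParams lasso_fit_cv
#' @param fit Optionally a precomputed [lasso_fit_cv()] object (then `y`,
#'   `x` are taken from it).
#' @return Numeric sigma estimate.
#' @export
estimate_sigma <- function(y = NULL, x = NULL, fit = NULL, nfolds = 11,
                           thresh = 1e-28, maxit = 1e7, seed = 1L) {
  if (is.null(fit)) fit <- lasso_fit_cv(y, x, nfolds = nfolds, thresh = thresh,
                                        maxit = maxit, seed = seed)
  n <- length(fit$y)
  df <- length(fit$active)
  if (df >= n - 1) stop("active set too large to estimate sigma (df >= n-1)")
  res <- fit$y - (fit$intercept + as.vector(fit$x %*% fit$beta))
  sqrt(sum(res^2) / (n - df - 1))
}

## CDF of a standard normal truncated to (a, b), evaluated at x; computed
## through upper-tail logs when the interval lies in a far tail
tnorm_cdf <- function(x, a, b) {
  if (!(a < b)) return(NA_real_)
  x <- min(max(x, a), b)
  if (b <= 0) return(1 - tnorm_cdf(-x, -b, -a))
  if (a >= 0) {
    la <- pnorm(a, lower.tail = FALSE, log.p = TRUE)
    lx <- pnorm(x, lower.tail = FALSE, log.p = TRUE)
    lb <- pnorm(b, lower.tail = FALSE, log.p = TRUE)
    den <- -expm1(lb - la)
    if (den <= 0) return(if (x >= (a + b) / 2) 1 else 0)
    return(max(0, min(1, -expm1(lx - la) / den)))
  }
  den <- pnorm(b) - pnorm(a)
  if (den <= 0) return(if (x >= (a + b) / 2) 1 else 0)
  max(0, min(1, (pnorm(x) - pnorm(a)) / den))
}

#' Fixed-lambda selective inference for LASSO-active coefficients
#'
#' Polyhedral-lemma p-values conditional on the LASSO selection event at a
#' fixed lambda: conditioned on the active set and signs, each active
#' coefficient's least-squares statistic follows a Gaussian truncated to
#' the interval implied by the KKT constraints; the reported p-value is the
#' two-sided truncated-Gaussian tail probability. No multiple-testing
#' correction is applied.
#'
#' The computation works in the standardized coordinates glmnet penalizes
#' (columns centred and scaled by their root-mean-square deviation,
#' response centred), so the selection event matches the fitted model.
#'
#' @param fit A [lasso_fit_cv()] object, or `NULL` to supply `y`, `x`,
#'   `beta`, `lambda` directly.
#' @param sigma Noise SD (e.g. from [estimate_sigma()]).
#' @param y,x,beta,lambda Used when `fit` is `NULL`: response, design,
#'   coefficient vector on the original scale (no intercept) and the fixed
#'   lambda.
#' @param tol_beta Active-set threshold on standardized coefficients.
#' @return Named numeric p-values for active terms (length 0 when the
#'   active set is empty). Attribute `vlims` holds the truncation
#'   intervals.
#' @export
selective_pvalues <- function(fit = NULL, sigma, y = NULL, x = NULL,
                              beta = NULL, lambda = NULL, tol_beta = 1e-8) {
  if (!is.null(fit)) {
    y <- fit$y; x <- fit$x; beta <- fit$beta; lambda <- fit$lambda_min
  }
  stopifnot(sigma > 0)
  n <- length(y)
  sdev <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  ok <- sdev > 0
  xs <- scale(x[, ok, drop = FALSE], center = TRUE,
              scale = sdev[ok])
  yc <- y - mean(y)
  bt <- beta[ok] * sdev[ok]  # coefficients in standardized coordinates
  act <- which(abs(bt) > tol_beta)
  if (!length(act)) {
    out <- numeric(0)
    attr(out, "vlims") <- matrix(numeric(0), 0, 2)
    return(out)
  }
  lam <- n * lambda  # constraints on the (1/2)||.||^2 + lam||.||_1 scale
  xa <- xs[, act, drop = FALSE]
  s <- sign(bt[act])
  m <- solve(crossprod(xa))
  xplus <- m %*% t(xa)                      # |A| x n
  u1 <- -(s * xplus)                        # sign constraints: u1 %*% y <= b1
  b1 <- -lam * as.vector(s * (m %*% s))
  gam <- u1; bvec <- b1
  if (length(act) < ncol(xs)) {
    xi <- xs[, -act, drop = FALSE]
    p_mat <- xa %*% xplus
    w <- t(xi) %*% (diag(n) - p_mat) / lam   # p0 x n
    u0 <- as.vector(t(xi) %*% t(xplus) %*% s)
    gam <- rbind(gam, w, -w)
    bvec <- c(bvec, 1 - u0, 1 + u0)
  }
  pv <- numeric(length(act))
  vlims <- matrix(NA_real_, length(act), 2)
  for (k in seq_along(act)) {
    eta <- xplus[k, ]
    eta2 <- sum(eta^2)
    stat <- sum(eta * yc)
    tau <- sigma * sqrt(eta2)
    cvec <- eta / eta2
    z0 <- yc - cvec * stat
    alpha <- as.vector(gam %*% cvec)
    resid <- bvec - as.vector(gam %*% z0)
    neg <- alpha < -1e-12; pos <- alpha > 1e-12
    vlo <- if (any(neg)) max(resid[neg] / alpha[neg]) else -Inf
    vhi <- if (any(pos)) min(resid[pos] / alpha[pos]) else Inf
    vlims[k, ] <- c(vlo, vhi)
    if (!(vlo < vhi)) {
      warning("numerically empty truncation interval; p set to 1")
      pv[k] <- 1
    } else {
      f <- tnorm_cdf(stat / tau, vlo / tau, vhi / tau)
      pv[k] <- 2 * min(f, 1 - f)
    }
  }
  names(pv) <- colnames(xs)[act]
  rownames(vlims) <- colnames(xs)[act]
  attr(pv, "vlims") <- vlims
  pv
}

#' Sign-based compartment calls from per-protein LASSO fits
#'
#' Assigns proteins to baits from the selective p-values of their
#' labelling-time x bait interaction terms: a protein is assigned to a
#' non-reference bait when that bait's modelled effect is positive with
#' p below `p_cut`, and to the reference bait when a bait effect is
#' negative with p below `p_cut`. When several interaction terms for one
#' bait are significant, the modelled effect is, by default, the
#' largest-magnitude significant interaction coefficient (configurable).
#' A protein may satisfy several baits.
#'
#' @param fits Named list (by protein) of [lasso_fit_cv()] objects, each
#'   with a `selective_p` element (named p-values) and `beta`.
#' @param p_cut Significance threshold (default 0.05).
#' @param bait_ref Reference bait collecting negative effects.
#' @param aggregation `"max_abs"` (largest-magnitude significant
#'   interaction) or `"sum"` (sum of significant interactions).
#' @return List with `sets` (bait -> character vector of proteins) and
#'   `table` (data.frame `protein`, `bait`, `effect`, `p_value`, `call`).
#' @export
interactome_calls <- function(fits, p_cut = 0.05, bait_ref = "A_UP",
                              aggregation = c("max_abs", "sum")) {
  aggregation <- match.arg(aggregation)
  rows <- NULL
  for (prot in names(fits)) {
    fit <- fits[[prot]]
    pv <- fit$selective_p
    if (is.null(pv) || !length(pv)) next
    terms <- names(pv)
    inter <- grepl(":bait", terms, fixed = TRUE)
    if (!any(inter)) next
    bait_of <- sub("^.*:bait", "", terms[inter])
    for (b in unique(bait_of)) {
      tb <- terms[inter][bait_of == b]
      sig <- tb[pv[tb] < p_cut]
      if (!length(sig)) next
      eff <- switch(aggregation,
                    max_abs = fit$beta[sig][which.max(abs(fit$beta[sig]))],
                    sum = sum(fit$beta[sig]))
      p_eff <- min(pv[sig])
      target <- if (eff > 0) b else bait_ref
      rows <- rbind(rows, data.frame(protein = prot, bait = target,
                                     effect = unname(eff), p_value = p_eff))
    }
  }
  if (is.null(rows)) rows <- data.frame(protein = character(),
                                        bait = character(),
                                        effect = numeric(),
                                        p_value = numeric())
  sets <- split(rows$protein, rows$bait)
  list(sets = lapply(sets, unique), table = rows)
}

#' Per-protein LASSO differential-interactome pipeline
#'
#' Runs, for every protein of a complete (imputed) log2 matrix, the
#' cross-validated LASSO over the labelling-time x bait design, the sigma
#' estimate and the fixed-lambda selective p-values, then derives the
#' sign-based compartment calls.
#'
#' @param x Complete log2 matrix (proteins x samples) or `lfq_matrix`.
#' @param design Sample design (`bait`, `labtime` per sample, sample
#'   order matching columns of `x`).
#' @inheritParams lasso_fit_cv
#' @inheritParams interactome_calls
#' @return List with `fits` (per protein) and the [interactome_calls()]
#'   result under `calls`.
#' @export
lasso_interactome <- function(x, design, nfolds = 11, thresh = 1e-28,
                              maxit = 1e7, seed = 1L, p_cut = 0.05,
                              bait_ref = "A_UP") {
  if (inherits(x, "lfq_matrix")) { design <- x$design; x <- x$log2 }
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  xd <- build_lasso_design(design, bait_ref = bait_ref)
  fits <- vector("list", nrow(x))
  names(fits) <- rownames(x)
  for (i in seq_len(nrow(x))) {
    fit <- lasso_fit_cv(x[i, ], xd, nfolds = nfolds, thresh = thresh,
                        maxit = maxit, seed = seed + i)
    fit$sigma <- tryCatch(estimate_sigma(fit = fit), error = function(e) NA)
    fit$selective_p <- if (is.finite(fit$sigma) && fit$sigma > 0 &&
                           length(fit$active)) {
      tryCatch(suppressWarnings(selective_pvalues(fit, sigma = fit$sigma)),
               error = function(e) numeric(0))
    } else numeric(0)
    fits[[i]] <- fit
  }
  list(fits = fits, calls = interactome_calls(fits, p_cut = p_cut,
                                              bait_ref = bait_ref))
}
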
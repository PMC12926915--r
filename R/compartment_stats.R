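## exact Mann-Whitney by enumeration of all group assignments; handles ties
## (U counts tied cross-pairs as one half)
mw_u_stat <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

mw_exact_p <- function(a, b, alternative) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_obs <- mw_u_stat(a, b)
  combs <- combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) {
    mw_u_stat(pooled[idx], pooled[-idx])
  })
  eps <- 1e-9
  mu <- n1 * length(b) / 2
  switch(alternative,
         less = mean(us <= u_obs + eps),
         greater = mean(us >= u_obs - eps),
         two.sided = mean(abs(us - mu) >= abs(u_obs - mu) - eps))
}

#' Two-group scalar comparison
#'
#' Mann-Whitney U test of two value groups (e.g. pI or molecular weight of
#' two compartment proteomes). Small samples (both groups <= `exact_max`)
#' use exact enumeration of all group assignments, which also handles
#' ties; larger samples use the normal approximation with tie correction
#' (via [stats::wilcox.test()]). A Student's t path is also available.
#'
#' @param a,b Numeric value vectors (at least 1 value per group).
#' @param test `"mann-whitney"` (default) or `"t"`.
#' @param alternative `"two.sided"`, `"less"` (first group lower) or
#'   `"greater"`.
#' @param exact_max Per-group size up to which the exact path is used
#'   (default 8).
#' @return Object of class `stat_result`: list with `test`, `alternative`,
#'   `statistic` (U for Mann-Whitney), `p_value`, `method` (`"exact"` or
#'   `"normal-approx"`), group summaries.
#' @export
scalar_group_test <- function(a, b, test = c("mann-whitney", "t"),
                              alternative = c("two.sided", "less", "greater"),
                              exact_max = 8) {
  test <- match.arg(test); alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("empty group")
  if (test == "t") {
    ht <- t.test(a, b, alternative = alternative)
    stat <- unname(ht$statistic); p <- ht$p.value; method <- "welch"
  } else if (length(a) <= exact_max && length(b) <= exact_max) {
    stat <- mw_u_stat(a, b)
    p <- mw_exact_p(a, b, alternative)
    method <- "exact"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                       exact = FALSE, correct = TRUE))
    stat <- unname(ht$statistic); p <- ht$p.value; method <- "normal-approx"
  }
  structure(list(test = test, alternative = alternative, statistic = stat,
                 p_value = p, method = method,
                 groups = data.frame(group = c("a", "b"),
                                     n = c(length(a), length(b)),
                                     median = c(median(a), median(b)),
                                     mean = c(mean(a), mean(b)))),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s (%s, %s): statistic %.4g, p = %.4g\n",
              x$test, x$method, x$alternative, x$statistic, x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Per-residue amino-acid usage comparison
#'
#' Per protein, the usage fraction of each of the 20 residues; the
#' comparison reports the difference of mean usage (set minus background)
#' with a two-sided Welch t-test per residue, and flags the `top_k`
#' residues with the largest absolute mean difference.
#'
#' @param set_records,background_records Lists of [protein_record()]s
#'   (at least 2 per side).
#' @param top_k Residues flagged by |mean difference| (default 5).
#' @return Data frame `residue`, `mean_set`, `mean_background`,
#'   `difference`, `t`, `p_value`, `top`.
#' @export
aa_usage_comparison <- function(set_records, background_records, top_k = 5) {
  stopifnot(length(set_records) >= 2, length(background_records) >= 2)
  usage <- function(records) {
    t(vapply(records, function(r) {
      f <- compositional_features(r)
      f[paste0("frac_", AA20)]
    }, numeric(20)))
  }
  us <- usage(set_records); ub <- usage(background_records)
  res <- do.call(rbind, lapply(seq_len(20), function(j) {
    d <- mean(us[, j]) - mean(ub[, j])
    if (d == 0 && sd(us[, j]) == 0 && sd(ub[, j]) == 0) {
      tt <- 0; p <- 1
    } else {
      ht <- tryCatch(t.test(us[, j], ub[, j]),
                     error = function(e) NULL)
      if (is.null(ht)) { tt <- 0; p <- 1 } else {
        tt <- unname(ht$statistic); p <- ht$p.value
      }
    }
    data.frame(residue = AA20[j], mean_set = mean(us[, j]),
               mean_background = mean(ub[, j]), difference = d,
               t = tt, p_value = p)
  }))
  res$top <- rank(-abs(res$difference), ties.method = "first") <= top_k
  res
}

#' Domain content across compartment groups
#'
#' Per-protein coverage of one annotation category (reusing
#' [annotation_coverage()]), summarized per group as the fraction of
#' proteins carrying the category at all (prevalence) and the mean
#' coverage.
#'
#' @param records List of labelled [protein_record()]s.
#' @param category Annotation category (default `"RRM"`).
#' @param groups Optional grouping vector; defaults to record labels.
#' @return List with `per_protein` (data.frame `protein`, `group`,
#'   `coverage`) and `per_group` (`group`, `n`, `prevalence`,
#'   `mean_coverage`). Unknown category gives an all-zero result with a
#'   warning.
#' @export
domain_content <- function(records, category = "RRM", groups = NULL) {
  if (is.null(groups)) groups <- record_labels(records)
  cov <- vapply(records, function(r) {
    unname(annotation_coverage(r, category))
  }, numeric(1))
  if (all(cov == 0)) {
    seen <- unique(unlist(lapply(records, function(r) r$annotations$category)))
    if (!category %in% seen) {
      warning("category not present in any record: ", category)
    }
  }
  per_protein <- data.frame(protein = record_ids(records), group = groups,
                            coverage = cov)
  per_group <- do.call(rbind, lapply(split(per_protein, per_protein$group),
                                     function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               prevalence = mean(d$coverage > 0),
               mean_coverage = mean(d$coverage))
  }))
  rownames(per_group) <- NULL
  list(per_protein = per_protein, per_group = per_group)
}
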
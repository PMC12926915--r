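#' Load and filter a protein-groups table
#'
#' Reads a MaxQuant-style protein-groups TSV (columns `Protein IDs`,
#' `Peptides`, `Reverse`, `Potential contaminant`, `Only identified by
#' site`, and one `LFQ intensity <sample>` column per sample), applies the
#' standard quality filters, log2-transforms intensities and marks zeros as
#' missing.
#'
#' Filters, in order: rows flagged `+` in Reverse / Potential contaminant /
#' Only identified by site; rows with fewer than `min_peptides` peptides;
#' rows not quantified in at least `k` replicates of any single condition
#' (`min_quant_rule = "k3"` uses k = 3; `"all"` requires every replicate of
#' some condition).
#'
#' @param path TSV path (or an already-read data.frame).
#' @param design Data frame `sample_id`, `bait`, `labtime`, `replicate`;
#'   must cover every `LFQ intensity` column.
#' @param min_peptides Minimum distinct peptides (default 2).
#' @param min_quant_rule `"k3"` or `"all"`.
#' @return Object of class `lfq_matrix`: list with `log2` (proteins x
#'   samples, `NA` = missing), `design`, `meta` (per-protein peptide counts
#'   and flags).
#' @export
load_protein_groups <- function(path, design, min_peptides = 2,
                                min_quant_rule = c("k3", "all")) {
  min_quant_rule <- match.arg(min_quant_rule)
  tab <- if (is.data.frame(path)) path else
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Protein IDs", "Peptides", "Reverse", "Potential contaminant",
            "Only identified by site")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  lfq_cols <- grep("^LFQ intensity ", names(tab), value = TRUE)
  samples <- sub("^LFQ intensity ", "", lfq_cols)
  unknown <- setdiff(samples, design$sample_id)
  if (length(unknown)) {
    stop("LFQ columns not in design: ", paste(unknown, collapse = ", "))
  }
  design <- design[match(samples, design$sample_id), , drop = FALSE]
  x <- as.matrix(tab[, lfq_cols, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- which(!stats::complete.cases(suppressWarnings(
      apply(x, 2, as.numeric))))
    stop("malformed intensity values at row(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  colnames(x) <- samples
  rownames(x) <- tab[["Protein IDs"]]
  flagged <- tab$Reverse == "+" | tab[["Potential contaminant"]] == "+" |
    tab[["Only identified by site"]] == "+"
  flagged[is.na(flagged)] <- FALSE
  keep <- !flagged & tab$Peptides >= min_peptides
  x <- x[keep, , drop = FALSE]
  log2x <- log2(x)
  log2x[x == 0] <- NA  # zero intensity = not quantified
  cond <- interaction(design$bait, design$labtime, drop = TRUE)
  quant_ok <- apply(!is.na(log2x), 1, function(q) {
    per_cond <- tapply(q, cond, sum)
    n_cond <- tapply(rep(TRUE, length(q)), cond, sum)
    if (min_quant_rule == "all") any(per_cond == n_cond)
    else any(per_cond >= pmin(3, n_cond))
  })
  log2x <- log2x[quant_ok, , drop = FALSE]
  meta <- data.frame(protein = rownames(log2x),
                     peptides = tab$Peptides[keep][quant_ok])
  structure(list(log2 = log2x, design = design, meta = meta),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("<lfq_matrix> %d proteins x %d samples, %.1f%% missing\n",
              nrow(x$log2), ncol(x$log2), 100 * mean(is.na(x$log2))))
  invisible(x)
}

#' Impute missing LFQ values from a down-shifted normal
#'
#' Per sample column, missing values are drawn from
#' `Normal(mean_obs - downshift * sd_obs, (width * sd_obs)^2)`, the
#' Perseus-style convention emulating low-abundance dropout. Observed
#' values are untouched.
#'
#' @param x Numeric matrix with `NA` for missing values (or an
#'   `lfq_matrix`, in which case its `log2` slot is imputed in place).
#' @param downshift Down-shift in observed-column SDs (default 1.8).
#' @param width Imputed SD as a fraction of the observed SD (default 0.3).
#' @param seed Integer seed; fixed seed gives identical imputations.
#' @return Same type as `x` with no missing values.
#' @export
impute_missing <- function(x, downshift = 1.8, width = 0.3, seed = 1L) {
  if (inherits(x, "lfq_matrix")) {
    x$log2 <- impute_missing(x$log2, downshift, width, seed)
    return(x)
  }
  set.seed(derive_seed(seed, "impute"))
  for (j in seq_len(ncol(x))) {
    obs <- x[!is.na(x[, j]), j]
    n_miss <- sum(is.na(x[, j]))
    if (!n_miss) next
    if (length(obs) < 2) stop("column ", j, " has fewer than 2 observed values")
    x[is.na(x[, j]), j] <- rnorm(n_miss, mean(obs) - downshift * sd(obs),
                                 width * sd(obs))
  }
  x
}

#' Enrichment of a target bait over control baits by Student's t-test
#'
#' Per protein: effect = mean(target) - mean(control) in log2; two-sided
#' pooled-variance Student's t-test; Benjamini-Hochberg adjustment across
#' proteins; a protein is called when `effect > lfc_cut` and
#' `fdr < fdr_cut` (both thresholds required).
#'
#' @param x Complete (imputed) log2 matrix, proteins x samples, or an
#'   `lfq_matrix` whose values are complete.
#' @param target_samples,control_samples Column names (or indices) of the
#'   two groups; at least 2 samples each.
#' @param lfc_cut,fdr_cut Call thresholds (defaults 1 and 0.05).
#' @return Object of class `diff_result`: data.frame `protein`, `effect`,
#'   `t`, `p_value`, `fdr`, `call`, plus a `degenerate` flag for
#'   zero-pooled-variance rows with nonzero effect.
#' @export
ttest_enrichment <- function(x, target_samples, control_samples,
                             lfc_cut = 1, fdr_cut = 0.05) {
  if (inherits(x, "lfq_matrix")) x <- x$log2
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  a <- x[, target_samples, drop = FALSE]
  b <- x[, control_samples, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  effect <- m1 - m2
  tstat <- effect / se
  df <- n1 + n2 - 2
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0
  # zero pooled variance: identical values in both groups; p = 1 iff the
  # means also agree, otherwise surfaced as a degenerate-variance flag
  p[degenerate & effect == 0] <- 1
  tstat[degenerate & effect == 0] <- 0
  fdr <- p.adjust(p, method = "BH")
  res <- data.frame(protein = rownames(x) %||% seq_len(nrow(x)),
                    effect = effect, t = tstat, p_value = p, fdr = fdr,
                    call = effect > lfc_cut & fdr < fdr_cut,
                    degenerate = degenerate & effect != 0,
                    row.names = NULL)
  class(res) <- c("diff_result", "data.frame")
  res
}

#' @export
summary.diff_result <- function(object, ...) {
  cat(sprintf("<diff_result> %d proteins, %d called enriched\n",
              nrow(object), sum(object$call)))
  invisible(object)
}
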
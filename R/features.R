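#' Compositional sequence features
#'
#' Per-residue fractions over the 20 canonical amino acids, eight
#' residue-class fractions, charge summaries and mean hydropathy. Unknown
#' residues (`X`) are excluded from both numerator and denominator, so the
#' 20 canonical fractions always sum to 1.
#'
#' FCR (fraction of charged residues) is `f(D)+f(E)+f(K)+f(R)`; NCPR (net
#' charge per residue) is `f(K)+f(R)-f(D)-f(E)`. Histidine carries a pKa in
#' the isoelectric-point calculation but counts as uncharged here, matching
#' the usual sequence-feature toolkit convention.
#'
#' @param record A [protein_record()].
#' @return Named numeric vector: `frac_<AA>` (20), `class_<name>` (8),
#'   `FCR`, `NCPR`, `mean_hydropathy`, `length`.
#' @export
compositional_features <- function(record) {
  chars <- seq_chars(record)
  chars <- chars[chars != "X"]
  if (!length(chars)) stop("sequence is empty or all-X: ", record$id)
  n <- length(chars)
  counts <- table(factor(chars, levels = AA20))
  frac <- as.numeric(counts) / n
  names(frac) <- paste0("frac_", AA20)
  sc <- aa_scales()
  classes <- vapply(sc$residue_classes,
                    function(res) sum(frac[paste0("frac_", res)]),
                    numeric(1))
  names(classes) <- paste0("class_", names(sc$residue_classes))
  fcr <- sum(frac[paste0("frac_", c("D", "E", "K", "R"))])
  ncpr <- sum(frac[paste0("frac_", c("K", "R"))]) -
    sum(frac[paste0("frac_", c("D", "E"))])
  hyd <- mean(sc$hydropathy[chars])
  c(frac, classes, FCR = fcr, NCPR = ncpr, mean_hydropathy = hyd,
    length = n)
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water mass. `X` contributes the
#' mean of the 20 residue masses.
#'
#' @param record A [protein_record()].
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(record) {
  chars <- seq_chars(record)
  sc <- aa_scales()
  m <- sc$residue_mass[chars]
  m[chars == "X"] <- mean(sc$residue_mass)
  sum(m) + sc$water_mass
}

## Henderson-Hasselbalch net charge at a given pH (termini + ionizable
## side chains, EMBOSS pKa table); monotone decreasing in pH
protein_net_charge <- function(chars, pH, pka = aa_scales()$pka) {
  counts <- table(factor(chars, levels = names(pka)))
  pos_groups <- c(Nterm = 1, counts[c("K", "R", "H")])
  pos_pka <- pka[c("Nterm", "K", "R", "H")]
  neg_groups <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  neg_pka <- pka[c("Cterm", "D", "E", "C", "Y")]
  sum(pos_groups / (1 + 10^(pH - pos_pka))) -
    sum(neg_groups / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the protein (free
#' N- and C-terminus plus D, E, C, Y, H, K, R side chains, EMBOSS pKa
#' values) is zero, located by bisection on (0, 14) until the residual
#' charge is below `tol`.
#'
#' @param record A [protein_record()].
#' @param tol Convergence tolerance on the net charge (elementary charges).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(record, tol = 1e-4) {
  chars <- seq_chars(record)
  chars <- chars[chars != "X"]
  if (!length(chars)) stop("sequence is empty or all-X: ", record$id)
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- protein_net_charge(chars, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Annotation coverage fractions
#'
#' Fraction of the sequence covered by the union of a record's intervals,
#' per category. Overlapping intervals of one category are merged before
#' measuring. Categories missing from the record score 0.
#'
#' @param record A [protein_record()].
#' @param vocabulary Character vector of categories to report.
#' @return Named numeric vector `cov_<category>` in `[0, 1]`.
#' @export
annotation_coverage <- function(record, vocabulary) {
  n <- nchar(record$sequence)
  ann <- record$annotations
  out <- setNames(numeric(length(vocabulary)), paste0("cov_", vocabulary))
  for (categ in vocabulary) {
    iv <- ann[ann$category == categ, , drop = FALSE]
    if (!nrow(iv)) next
    covered <- logical(n)
    for (i in seq_len(nrow(iv))) covered[iv$start[i]:iv$end[i]] <- TRUE
    out[paste0("cov_", categ)] <- sum(covered) / n
  }
  out
}

#' Blockiness z-scores against a composition-matched scramble null
#'
#' Quantifies non-random clustering (blockiness) of eight residue classes
#' along the sequence. For an off-diagonal class pair (X, Y) residues are
#' mapped to +1 (class X), -1 (class Y), 0 (other); the patterning statistic
#' is the mean over sliding windows (sizes 5 and 6, averaged) of
#' `(sigma_win - sigma_seq)^2` with `sigma = (f+ - f-)^2 / (f+ + f-)`
#' (0 where the window holds neither class). On the diagonal the map is
#' binary and `sigma` is the class fraction. The observed statistic is
#' z-scored against `n_scrambles` uniform permutations of the sequence;
#' degenerate nulls (zero spread) map to z = 0.
#'
#' @param record A [protein_record()].
#' @param n_scrambles Number of composition-matched scrambles (default
#'   100000; reduce for exploratory work).
#' @param seed Integer seed for the scramble stream.
#' @param window_sizes Sliding-window sizes, averaged. Windows longer than
#'   the sequence are skipped; if all are skipped an error is raised.
#' @return Object of class `blockiness_matrix`: list with `z` (symmetric
#'   8 x 8 matrix, rows/cols named by class), `classes`, `n_scrambles`,
#'   `window_sizes`, `seed`.
#' @export
blockiness_zscores <- function(record, n_scrambles = 100000L, seed = 1L,
                               window_sizes = c(5L, 6L)) {
  chars <- seq_chars(record)
  sc <- aa_scales()
  cls_names <- names(sc$residue_classes)
  keep <- window_sizes[window_sizes <= length(chars)]
  if (!length(keep)) {
    stop("sequence shorter than every window size: ", record$id)
  }
  ## class index per position, 0 = unclassified (X)
  idx <- integer(length(chars))
  for (k in seq_along(cls_names)) {
    idx[chars %in% sc$residue_classes[[k]]] <- k
  }
  set.seed(derive_seed(seed, "blockiness"))
  z <- blockiness_core(idx, as.integer(n_scrambles), as.integer(keep))
  dimnames(z) <- list(cls_names, cls_names)
  structure(list(z = z, classes = cls_names,
                 n_scrambles = as.integer(n_scrambles),
                 window_sizes = as.integer(keep), seed = as.integer(seed)),
            class = "blockiness_matrix")
}

#' @export
print.blockiness_matrix <- function(x, ...) {
  cat(sprintf("<blockiness_matrix> %d scrambles, windows %s\n",
              x$n_scrambles, paste(x$window_sizes, collapse = "/")))
  print(round(x$z, 2))
  invisible(x)
}

## flatten the upper triangle + diagonal to named features
blockiness_features <- function(bm) {
  cls <- bm$classes
  out <- numeric(0)
  for (i in seq_along(cls)) {
    for (j in i:length(cls)) {
      out[paste0("block_", cls[i], "_", cls[j])] <- bm$z[i, j]
    }
  }
  out
}

#' MinMax normalization
#'
#' Maps each column's observed minimum to 0 and maximum to 1; constant
#' columns map to 0. Idempotent.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  x <- as.matrix(x)
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  out <- sweep(x, 2, rng[1, ], "-")
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/")
  out[, span == 0] <- 0
  out
}

#' Assemble the per-protein feature matrix
#'
#' Computes the curated feature set for a list of records: composition and
#' charge features, molecular weight, isoelectric point, annotation-coverage
#' fractions, and (optionally) blockiness z-scores, then MinMax-normalizes
#' every column.
#'
#' @param records List of [protein_record()]s with unique ids.
#' @param vocabulary Annotation categories to report as coverage features;
#'   defaults to the union of categories seen in `records`.
#' @param blockiness Logical; include blockiness z-score features (costly).
#' @param n_scrambles,seed,window_sizes Passed to [blockiness_zscores()].
#' @param normalize Logical; MinMax-normalize columns (default `TRUE`).
#' @return Object of class `feature_matrix`: a numeric matrix (proteins x
#'   features, rownames = ids) with attributes `labels` (named character)
#'   and `normalized`.
#' @export
assemble_feature_matrix <- function(records, vocabulary = NULL,
                                    blockiness = FALSE, n_scrambles = 1000L,
                                    seed = 1L, window_sizes = c(5L, 6L),
                                    normalize = TRUE) {
  if (length(records) < 2) stop("need at least 2 records")
  ids <- record_ids(records)
  if (anyDuplicated(ids)) stop("duplicate protein ids")
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(lapply(records,
                                            function(r) r$annotations$category))))
  }
  rows <- lapply(records, function(r) {
    v <- c(compositional_features(r),
           MW = molecular_weight(r),
           pI = isoelectric_point(r))
    if (length(vocabulary)) v <- c(v, annotation_coverage(r, vocabulary))
    if (blockiness) {
      bm <- blockiness_zscores(r, n_scrambles = n_scrambles, seed = seed,
                               window_sizes = window_sizes)
      v <- c(v, blockiness_features(bm))
    }
    v
  })
  x <- do.call(rbind, rows)
  rownames(x) <- ids
  if (normalize) x <- minmax_normalize(x)
  structure(x, labels = setNames(record_labels(records), ids),
            normalized = normalize, class = c("feature_matrix", "matrix"))
}
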
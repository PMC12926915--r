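## shared fixtures, all generated in code

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_sequence <- function(n) paste(sample(AA, n, replace = TRUE),
                                     collapse = "")

## sequences of length `len` carrying one planted 10-mer motif per class
make_motif_records <- function(motifs, n_per_class, len = 48) {
  recs <- list()
  for (m in names(motifs)) {
    for (i in seq_len(n_per_class)) {
      chars <- sample(AA, len, replace = TRUE)
      at <- sample(seq_len(len - nchar(motifs[[m]]) + 1), 1)
      chars[at:(at + nchar(motifs[[m]]) - 1)] <-
        strsplit(motifs[[m]], "")[[1]]
      recs[[length(recs) + 1]] <- protein_record(
        paste0(m, "_", i), paste(chars, collapse = ""), label = m)
    }
  }
  recs
}

## brute-force O(n^2) pair-counting AUROC oracle (ties count one half)
auroc_pairs_oracle <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## direct nested-loop fluctuation cross-correlation oracle
ccf_loop_oracle <- function(a, b, dx, dy) {
  da <- a - mean(a); db <- b - mean(b); n <- nrow(a)
  s <- 0; cnt <- 0
  for (i in 1:n) for (j in 1:n) {
    ii <- i + dx; jj <- j + dy
    if (ii >= 1 && ii <= n && jj >= 1 && jj <= n) {
      s <- s + da[i, j] * db[ii, jj]; cnt <- cnt + 1
    }
  }
  s / cnt / (mean(a) * mean(b))
}

## toy protein-groups table: each quality filter removes exactly one row;
## P6 is missing one replicate in every condition, so it separates the
## k = 3 rule (kept) from the k = all rule (dropped)
toy_protein_groups <- function(design) {
  samples <- design$sample_id
  intens <- matrix(2^rnorm(6 * length(samples), 25, 1), 6)
  intens[6, design$replicate == 1] <- 0
  tab <- data.frame(`Protein IDs` = paste0("P", 1:6),
                    Peptides = c(5, 5, 5, 1, 5, 5),
                    Reverse = c("+", "", "", "", "", ""),
                    `Potential contaminant` = c("", "+", "", "", "", ""),
                    `Only identified by site` = c("", "", "+", "", "", ""),
                    check.names = FALSE)
  colnames(intens) <- paste("LFQ intensity", samples)
  cbind(tab, as.data.frame(intens, check.names = FALSE))
}

small_design <- function(n_rep = 4) {
  d <- expand.grid(bait = c("A_UP", "A_DOWN"), labtime = c(1, 5),
                   replicate = seq_len(n_rep), stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_t%g_r%d", d$bait, d$labtime, d$replicate)
  d[, c("sample_id", "bait", "labtime", "replicate")]
}
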
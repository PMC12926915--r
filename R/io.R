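#' Write protein records to FASTA
#'
#' @param records List of [protein_record()]s.
#' @param path Output FASTA path.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- record_ids(records)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read protein records from FASTA (plus optional annotations/labels)
#'
#' @param path FASTA path.
#' @param annotations Optional annotation table (data.frame or TSV path:
#'   `protein_id`, `category`, `start`, `end`, 1-based inclusive).
#' @param labels Optional named character vector of class labels.
#' @return List of [protein_record()]s.
#' @export
read_fasta <- function(path, annotations = NULL, labels = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    ann <- NULL
    if (!is.null(annotations)) {
      sel <- annotations[annotations$protein_id == id,
                         c("category", "start", "end"), drop = FALSE]
      if (nrow(sel)) ann <- sel
    }
    protein_record(id, as.character(seqs[[i]]), annotations = ann,
                   label = if (!is.null(labels) && id %in% names(labels))
                     labels[[id]] else NA_character_)
  })
}

#' Write / read an annotation-interval table (TSV)
#'
#' Columns `protein_id`, `category`, `start`, `end` (1-based inclusive).
#' @param records List of [protein_record()]s.
#' @param path TSV path.
#' @export
write_annotations <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    if (!nrow(r$annotations)) return(NULL)
    cbind(protein_id = r$id, r$annotations)
  }))
  if (is.null(rows)) {
    rows <- data.frame(protein_id = character(), category = character(),
                       start = integer(), end = integer())
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a simulated LFQ set in the protein-groups TSV dialect
#'
#' Produces the MaxQuant-style table ([load_protein_groups()] reads it
#' back) plus the sample-design and planted-truth TSVs.
#'
#' @param sim An [simulate_lfq()] result.
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_protein_groups <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  intens <- 2^sim$lfq
  intens[is.na(intens)] <- 0  # zero intensity = missing
  tab <- data.frame(`Protein IDs` = rownames(sim$lfq),
                    Peptides = sim$peptides,
                    Reverse = "", `Potential contaminant` = "",
                    `Only identified by site` = "",
                    check.names = FALSE)
  colnames(intens) <- paste("LFQ intensity", sim$design$sample_id)
  tab <- cbind(tab, as.data.frame(intens, check.names = FALSE))
  groups_path <- file.path(dir, "proteinGroups.txt")
  design_path <- file.path(dir, "design.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  write.table(tab, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(groups = groups_path, design = design_path,
              truth = truth_path))
}

#' Read / write a two-channel image pair as TIFF
#'
#' Channels are stored as 32-bit float TIFFs scaled to the data range.
#'
#' @param pair An `image_pair`.
#' @param path_a,path_b Per-channel TIFF paths.
#' @param pixel_size um/px recorded on the pair when reading.
#' @export
write_image_pair <- function(pair, path_a, path_b) {
  scale01 <- function(m) if (max(m) > 0) m / max(m) else m
  tiff::writeTIFF(scale01(pair$a), path_a, bits.per.sample = 32L)
  tiff::writeTIFF(scale01(pair$b), path_b, bits.per.sample = 32L)
  invisible(c(path_a, path_b))
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(path_a, path_b, pixel_size) {
  a <- tiff::readTIFF(path_a)
  b <- tiff::readTIFF(path_b)
  if (length(dim(a)) == 3) a <- a[, , 1]
  if (length(dim(b)) == 3) b <- b[, , 1]
  as_image_pair(a, b, pixel_size)
}

#' Write a feature matrix to TSV
#'
#' @param features A `feature_matrix` (or any matrix with rownames).
#' @param path TSV path; one row per protein, first column `protein`.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(protein = rownames(features),
                   unclass(features)[, , drop = FALSE],
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
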
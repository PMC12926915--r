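#' Construct a protein record
#'
#' The basic unit handled by the feature engine and the classifiers: an
#' identifier, an upper-case amino-acid sequence over the 20-letter alphabet
#' (plus optional `X` for unknown residues), optional annotation intervals
#' (1-based, inclusive) and an optional class label.
#'
#' @param id Character scalar, unique protein identifier.
#' @param sequence Character scalar; upper-case amino acids, `X` allowed.
#' @param annotations `NULL` or a data.frame with columns `category`,
#'   `start`, `end` (1-based inclusive, within the sequence).
#' @param label Optional class label (character scalar or `NA`).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, annotations = NULL, label = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(AA20, "X"))
  if (length(bad)) {
    stop("non-canonical residues in '", id, "': ", paste(bad, collapse = ", "))
  }
  n <- nchar(sequence)
  if (is.null(annotations)) {
    annotations <- data.frame(category = character(), start = integer(),
                              end = integer(), stringsAsFactors = FALSE)
  } else {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("category", "start", "end") %in% names(annotations)))
    if (nrow(annotations)) {
      ok <- annotations$start >= 1 & annotations$start <= annotations$end &
        annotations$end <= n
      if (!all(ok)) stop("annotation interval outside sequence for '", id, "'")
    }
  }
  structure(list(id = id, sequence = sequence, annotations = annotations,
                 label = label),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d aa%s, %d annotation interval(s)\n",
              x$id, nchar(x$sequence),
              if (is.na(x$label)) "" else paste0(", class ", x$label),
              nrow(x$annotations)))
  invisible(x)
}

seq_chars <- function(record) strsplit(record$sequence, "", fixed = TRUE)[[1]]

record_labels <- function(records) vapply(records, `[[`, character(1), "label")
record_ids <- function(records) vapply(records, `[[`, character(1), "id")
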
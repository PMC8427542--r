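# FASTA input and tabular report output.

#' Read a FASTA file of nucleotide sequences
#'
#' Reads plain or gzip-compressed FASTA. Sequences are upper-cased,
#' whitespace is stripped and multi-line records are concatenated. Record
#' ids are the first whitespace-delimited token of each header; duplicate
#' ids are disambiguated by appending an ordinal suffix (with a warning) so
#' that ids can key a prediction report.
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return A data frame with columns `id`, `bases` and `length` (bp), one
#'   row per record in file order. An empty file yields a zero-row data
#'   frame with a warning.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)

  first <- .first_nonempty_line(path)
  if (is.null(first)) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), bases = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(first$text), ">")) {
    stop("malformed FASTA: sequence data before any header at line ",
         first$line, " of ", path)
  }

  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  ids[!nzchar(ids)] <- paste0("seq", which(!nzchar(ids)))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids in ", path, "; appending ordinal suffixes")
    occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    dup <- occ > 1L
    ids[dup] <- paste0(ids[dup], "_", occ[dup])
  }
  bases <- toupper(as.character(set))
  data.frame(id = ids, bases = unname(bases),
             length = nchar(bases), stringsAsFactors = FALSE)
}

.first_nonempty_line <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    x <- readLines(con, n = 1L, warn = FALSE)
    if (length(x) == 0L) return(NULL)
    i <- i + 1L
    if (nzchar(trimws(x))) return(list(text = x, line = i))
  }
}

#' Write sequences to a FASTA file
#'
#' @param seqs Data frame with columns `id` and `bases` (as returned by
#'   [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "bases") %in% names(seqs)))
  set <- Biostrings::DNAStringSet(stats::setNames(seqs$bases, seqs$id))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Write a tab-separated prediction report
#'
#' One row per scored sequence, in input order, with columns `id`,
#' `length`, `score` (fixed four decimal places) and `label`
#' (virulent/temperate/uncertain). The score column is always reported,
#' including for uncertain calls.
#'
#' @param records Data frame with columns `id`, `length`, `score`, `label`.
#'   May have zero rows, in which case a header-only file is written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(records, path) {
  cols <- c("id", "length", "score", "label")
  stopifnot(is.data.frame(records), all(cols %in% names(records)))
  out <- data.frame(id = as.character(records$id),
                    length = as.integer(records$length),
                    score = sprintf("%.4f", records$score),
                    label = as.character(records$label),
                    stringsAsFactors = FALSE)
  write.table(out, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a prediction report written by [write_prediction_report()]
#'
#' @param path Path to a TSV report.
#' @return Data frame with columns `id`, `length`, `score`, `label`.
#' @export
read_prediction_report <- function(path) {
  x <- read.delim(path, sep = "\t", header = TRUE,
                  colClasses = c("character", "integer", "numeric", "character"),
                  stringsAsFactors = FALSE)
  stopifnot(identical(names(x), c("id", "length", "score", "label")))
  x
}

#' Read a genome lifestyle label table
#'
#' Expects a TSV with columns `genome_id`, `lifestyle`
#' (`virulent`/`temperate`) and `dataset` (`curated`/`auto`). Curated
#' genomes participate in cross-validation folds; auto-labelled genomes are
#' training-only.
#'
#' @param path Path to a TSV label table.
#' @return A validated data frame.
#' @export
read_label_table <- function(path) {
  x <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_label_table(x)
}

#' Write a genome lifestyle label table
#' @param labels Data frame with columns `genome_id`, `lifestyle`, `dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  labels <- validate_label_table(labels)
  write.table(labels, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate a lifestyle label table
#' @param labels Data frame to validate.
#' @return The data frame, with columns coerced to character.
#' @export
validate_label_table <- function(labels) {
  cols <- c("genome_id", "lifestyle", "dataset")
  if (!is.data.frame(labels) || !all(cols %in% names(labels)))
    stop("label table must have columns genome_id, lifestyle, dataset")
  labels <- labels[, cols]
  labels[] <- lapply(labels, as.character)
  if (anyDuplicated(labels$genome_id))
    stop("duplicate genome_id in label table: ",
         paste(unique(labels$genome_id[duplicated(labels$genome_id)]),
               collapse = ", "))
  if (!all(labels$lifestyle %in% c("virulent", "temperate")))
    stop("lifestyle must be 'virulent' or 'temperate'")
  if (!all(labels$dataset %in% c("curated", "auto")))
    stop("dataset must be 'curated' or 'auto'")
  if (any(is.na(labels$lifestyle)))
    stop("missing lifestyle labels")
  labels
}
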
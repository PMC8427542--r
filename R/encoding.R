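# Numeric sequence representations: one-hot matrices and k-mer frequencies.

# Column order of the one-hot matrix. A base maps to the indicator vector
# with a 1 in its column: T=[1,0,0,0], G=[0,1,0,0], C=[0,0,1,0], A=[0,0,0,1].
.onehot_cols <- c("T", "G", "C", "A")

#' One-hot encode a nucleotide sequence
#'
#' Encodes a sequence as an `L x 4` indicator matrix with column order
#' T, G, C, A, so that A = (0,0,0,1), C = (0,0,1,0), G = (0,1,0,0) and
#' T = (1,0,0,0). Ambiguous bases (N and other IUPAC codes) become all-zero
#' rows, contributing nothing to any convolution kernel. Optional padding
#' appends all-zero rows on the 3' (right) end up to `target_length`.
#'
#' @param seq Character scalar of bases (case-insensitive), or a one-row
#'   data frame with a `bases` column.
#' @param target_length Optional integer `>= nchar(seq)`; rows beyond the
#'   sequence end are all-zero padding.
#' @return Numeric matrix of 0/1 with `target_length` (or sequence length)
#'   rows and 4 columns named T, G, C, A.
#' @examples
#' one_hot_encode("ACGT")
#' @export
one_hot_encode <- function(seq, target_length = NULL) {
  bases <- .seq_chr(seq)
  L <- nchar(bases)
  out_len <- if (is.null(target_length)) L else as.integer(target_length)
  if (out_len < L)
    stop("target_length (", out_len, ") is shorter than the sequence (", L, ")")
  codes <- .encode_codes(bases)
  mat <- matrix(0, nrow = out_len, ncol = 4,
                dimnames = list(NULL, .onehot_cols))
  known <- which(codes < 4L)
  mat[cbind(known, codes[known] + 1L)] <- 1
  mat
}

#' Decode a one-hot matrix back to bases
#'
#' Inverse of [one_hot_encode()] on unambiguous rows; all-zero rows
#' (ambiguity or padding) decode to `"N"`.
#'
#' @param matrix An `L x 4` matrix whose rows are one-hot or all-zero.
#' @return Character scalar of bases.
#' @export
one_hot_decode <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 4)
  nz <- rowSums(matrix != 0)
  if (any(nz > 1))
    stop("row ", which(nz > 1)[1], " has more than one nonzero entry")
  idx <- max.col(matrix, ties.method = "first")
  chars <- ifelse(nz == 0, "N", .onehot_cols[idx])
  paste0(chars, collapse = "")
}

#' k-mer frequency vector of a sequence
#'
#' Counts every overlapping window of length `k` consisting only of
#' A/C/G/T (windows containing ambiguity codes are skipped, not imputed)
#' and normalizes by the number of counted windows. Entries follow the
#' canonical lexicographic k-mer order (AA...A first). A sequence with no
#' valid window returns the all-zero vector.
#'
#' @param seq Character scalar of bases, or a one-row data frame with a
#'   `bases` column.
#' @param k Integer word length, `>= 1`.
#' @return Named numeric vector of length `4^k` summing to 1 (or 0).
#' @examples
#' kmer_frequencies("ACGT", 1)
#' @export
kmer_frequencies <- function(seq, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer")
  k <- as.integer(k)
  bases <- .seq_chr(seq)
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  if (nchar(bases) < k)
    return(stats::setNames(numeric(4^k), words))
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(bases), width = k)
  counts <- counts[words]
  tot <- sum(counts)
  if (tot == 0) return(stats::setNames(numeric(4^k), words))
  counts / tot
}

# Accept either a bases string or a read_fasta()-style row.
.seq_chr <- function(seq) {
  if (is.data.frame(seq)) {
    stopifnot("bases" %in% names(seq), nrow(seq) == 1L)
    seq <- seq$bases
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  toupper(seq)
}

# Integer codes in one-hot column order: T=0, G=1, C=2, A=3; anything else
# (ambiguity) = 4. Used as the compact input to the C++ kernels.
.encode_codes <- function(bases) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  idx <- match(chars, .onehot_cols)
  idx[is.na(idx)] <- 5L
  as.integer(idx - 1L)
}

# Batch-encode sequences into an L x n integer matrix (one column per
# sequence, matching the compute kernels' layout), right-padded with the
# all-zero code 4.
.encode_batch <- function(bases_vec, L) {
  n <- length(bases_vec)
  out <- matrix(4L, nrow = L, ncol = n)
  splits <- strsplit(toupper(bases_vec), "", fixed = TRUE)
  for (i in seq_len(n)) {
    chars <- splits[[i]]
    if (length(chars) > L)
      stop("sequence ", i, " is longer (", length(chars),
           ") than the model input length ", L)
    idx <- match(chars, .onehot_cols)
    idx[is.na(idx)] <- 5L
    out[seq_along(chars), i] <- as.integer(idx - 1L)
  }
  out
}
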
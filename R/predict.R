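# Length-aware prediction: routing to group models, long-sequence
# splitting, length-weighted score combination and the uncertainty cut-off.

#' Split a long sequence into model-sized pieces
#'
#' Sequences longer than 1,800 bp are split into consecutive
#' non-overlapping 1,800 bp pieces plus a final remainder piece (when the
#' length is not an exact multiple); concatenating the pieces reproduces
#' the input.
#'
#' @param seq Character scalar of bases (> 1,800 bp), or a one-row data
#'   frame with a `bases` column.
#' @return Data frame with columns `start` (0-based), `length`, `bases`.
#' @examples
#' nchar(split_long_sequence(strrep("A", 4000))$bases)
#' @export
split_long_sequence <- function(seq) {
  bases <- .seq_chr(seq)
  L <- nchar(bases)
  if (L <= 1800)
    stop("split_long_sequence() requires a sequence longer than 1800 bp; got ", L)
  starts <- seq(0L, L - 1L, by = 1800L)
  lens <- pmin(1800L, L - starts)
  data.frame(start = as.integer(starts), length = as.integer(lens),
             bases = substring(bases, starts + 1L, starts + lens),
             stringsAsFactors = FALSE)
}

#' Combine piece scores by length weighting
#'
#' The score of a split sequence is the length-weighted mean of its piece
#' scores: `sum(length_i * score_i) / sum(length_i)`.
#'
#' @param lengths Piece lengths in bp (> 0).
#' @param scores Piece scores.
#' @return The combined score.
#' @examples
#' combine_scores(c(1800, 1800, 400), c(0.8, 0.8, 0.2))  # 0.74
#' @export
combine_scores <- function(lengths, scores) {
  if (length(lengths) == 0L) stop("no piece scores to combine")
  if (length(lengths) != length(scores)) stop("lengths/scores mismatch")
  if (any(lengths <= 0)) stop("piece lengths must be positive")
  weighted.mean(scores, lengths)
}

#' Uncertainty cut-off policy
#'
#' Scores inside the open band `(0.5 - t/2, 0.5 + t/2)` are labelled
#' `"uncertain"`. The default `t = 0` reports every call; `t = 0.5`
#' (ignore scores in (0.25, 0.75)) is the recommended setting for
#' conservative use.
#'
#' @param t Cut-off width in `[0, 1)`.
#' @return An object of class `cutoff_policy`.
#' @export
cutoff_policy <- function(t = 0) {
  if (t < 0 || t >= 1) stop("cut-off t must be in [0, 1)")
  structure(list(t = t), class = "cutoff_policy")
}

#' Label scores under a cut-off policy
#'
#' Scores above `0.5 + t/2` are `"virulent"`, below `0.5 - t/2`
#' `"temperate"`, anything else `"uncertain"`. A score of exactly 0.5 is
#' `"uncertain"` at any `t`, including `t = 0`: the decision rule is
#' defined by strict inequalities, and an undefined case is never silently
#' coerced.
#'
#' @param score Numeric scores in `[0, 1]`.
#' @param policy A [cutoff_policy()].
#' @return Character vector of labels.
#' @examples
#' classify(c(0.9, 0.6, 0.2), cutoff_policy(0.5))
#' @export
classify <- function(score, policy = cutoff_policy(0)) {
  stopifnot(inherits(policy, "cutoff_policy"),
            all(score >= 0 & score <= 1))
  hi <- 0.5 + policy$t / 2
  lo <- 0.5 - policy$t / 2
  ifelse(score > hi, "virulent", ifelse(score < lo, "temperate", "uncertain"))
}

#' Route sequences to group models and score them
#'
#' Each sequence is scored by the model of its length group: lengths
#' within 100-1,800 bp go to their group (padded to the group's input
#' length), lengths under 100 bp to the group A model, and longer
#' sequences are split into 1,800 bp pieces, each piece scored by its own
#' length's model (a remainder shorter than 100 bp also falls to group A)
#' and combined by length weighting. Inference is deterministic and
#' per-sequence: batch composition cannot change a score.
#'
#' @param sequences Character vector of sequences, or a data frame with a
#'   `bases` column (e.g. from [read_fasta()]).
#' @param models A `phage_model_set` with models for groups A-D.
#' @return Numeric vector of scores in (0, 1), one per input sequence.
#' @export
route_and_score <- function(sequences, models) {
  bases <- if (is.data.frame(sequences)) sequences$bases else sequences
  stopifnot(is.character(bases))
  if (length(bases) == 0L) return(numeric(0))
  missing_groups <- setdiff(length_groups()$name, names(models))
  if (length(missing_groups) > 0)
    stop("missing model for group(s): ", paste(missing_groups, collapse = ", "))

  # expand into pieces: one row per (sequence, piece)
  piece_parent <- integer(0)
  piece_bases <- character(0)
  for (i in seq_along(bases)) {
    b <- toupper(bases[i])
    if (nchar(b) > 1800) {
      sp <- split_long_sequence(b)
      piece_parent <- c(piece_parent, rep(i, nrow(sp)))
      piece_bases <- c(piece_bases, sp$bases)
    } else {
      piece_parent <- c(piece_parent, i)
      piece_bases <- c(piece_bases, b)
    }
  }
  piece_len <- nchar(piece_bases)
  grp <- assign_length_group(pmax(piece_len, 1L))
  grp[grp == "short"] <- "A"

  piece_score <- numeric(length(piece_bases))
  for (g in unique(grp)) {
    sel <- grp == g
    model <- models[[g]]
    piece_score[sel] <- .score_batch(piece_bases[sel], model$config,
                                     model$weights)
  }
  vapply(seq_along(bases), function(i) {
    sel <- piece_parent == i
    combine_scores(piece_len[sel], piece_score[sel])
  }, numeric(1))
}

#' Predict a FASTA file and write a report
#'
#' Reads sequences, scores them with [route_and_score()], labels them
#' under the cut-off policy and writes a TSV report via
#' [write_prediction_report()] preserving input order.
#'
#' @param fasta_path Input FASTA (optionally `.gz`).
#' @param models A `phage_model_set`.
#' @param policy A [cutoff_policy()] (default reports every call).
#' @param out_path Output TSV path.
#' @return Summary list with `n`, `n_virulent`, `n_temperate`,
#'   `n_uncertain` and the report `records` data frame, invisibly.
#' @export
predict_file <- function(fasta_path, models, policy = cutoff_policy(0),
                         out_path) {
  seqs <- read_fasta(fasta_path)
  if (nrow(seqs) == 0L) {
    records <- data.frame(id = character(), length = integer(),
                          score = numeric(), label = character(),
                          stringsAsFactors = FALSE)
  } else {
    scores <- route_and_score(seqs, models)
    records <- data.frame(id = seqs$id, length = seqs$length,
                          score = scores,
                          label = classify(scores, policy),
                          stringsAsFactors = FALSE)
  }
  write_prediction_report(records, out_path)
  invisible(list(n = nrow(records),
                 n_virulent = sum(records$label == "virulent"),
                 n_temperate = sum(records$label == "temperate"),
                 n_uncertain = sum(records$label == "uncertain"),
                 records = records))
}
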
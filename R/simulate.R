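# Fragment simulation, genome-level cross-validation planning, and the
# Markov-chain synthetic genome generator.

#' Fragment length groups
#'
#' The four length strata, with half-open ranges \[100,400), \[400,800),
#' \[800,1200) and the closed top group \[1200,1800\], so that every length
#' maps to exactly one group and 1,800 bp itself is predictable without
#' splitting. `L` is the model input length of each group.
#'
#' @return Data frame with columns `name`, `min`, `max_incl` and `L`.
#' @export
length_groups <- function() {
  data.frame(name = c("A", "B", "C", "D"),
             min = c(100L, 400L, 800L, 1200L),
             max_incl = c(399L, 799L, 1199L, 1800L),
             L = c(400L, 800L, 1200L, 1800L),
             stringsAsFactors = FALSE)
}

#' Assign sequence lengths to a length group or routing directive
#'
#' Lengths within 100-1,800 bp map to groups A-D. Lengths under 100 bp
#' return `"short"` (such sequences are scored with the group A model);
#' lengths over 1,800 bp return `"split"` (the sequence is split into
#' 1,800 bp pieces before scoring).
#'
#' @param length Integer vector of sequence lengths in bp, all `>= 1`.
#' @return Character vector over `{"A","B","C","D","short","split"}`.
#' @examples
#' assign_length_group(c(250, 1500, 99, 1801))
#' @export
assign_length_group <- function(length) {
  if (any(length < 1)) stop("lengths must be >= 1")
  lg <- length_groups()
  out <- character(length(length))
  out[length < 100] <- "short"
  out[length > 1800] <- "split"
  for (i in seq_len(nrow(lg))) {
    sel <- length >= lg$min[i] & length <= lg$max_incl[i]
    out[sel] <- lg$name[i]
  }
  out
}

.group_row <- function(group) {
  lg <- length_groups()
  row <- lg[lg$name == group, ]
  if (nrow(row) != 1L) stop("unknown length group: ", group)
  row
}

#' Extract random fragments from a genome
#'
#' Draws `n` artificial contigs from one genome, emulating MetaSim-style
#' fragment extraction: each fragment length is uniform over the group's
#' range (integer bp) and each start position uniform over all valid
#' offsets. Fragments are exact substrings; no sequencing-error model is
#' applied.
#'
#' @param genome Character scalar of bases, or a one-row data frame with
#'   columns `id` and `bases`.
#' @param lifestyle `"virulent"` or `"temperate"`.
#' @param group Length group name, one of `"A"`-`"D"`.
#' @param n Number of fragments (`n = 0` gives an empty result).
#' @param seed Optional integer; when given, the draw is deterministic and
#'   does not disturb the caller's RNG state.
#' @param genome_id Identifier recorded with each fragment (defaults to the
#'   data frame's `id` or `"genome"`).
#' @return Data frame with columns `fragment_id`, `genome_id`, `lifestyle`,
#'   `group`, `start` (0-based), `length`, `bases`.
#' @export
extract_fragments <- function(genome, lifestyle, group, n, seed = NULL,
                              genome_id = NULL) {
  if (is.data.frame(genome)) {
    stopifnot(nrow(genome) == 1L, "bases" %in% names(genome))
    if (is.null(genome_id) && "id" %in% names(genome)) genome_id <- genome$id
    genome <- genome$bases
  }
  if (is.null(genome_id)) genome_id <- "genome"
  stopifnot(is.character(genome), length(genome) == 1L)
  lifestyle <- match.arg(lifestyle, c("virulent", "temperate"))
  row <- .group_row(group)
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  empty <- data.frame(fragment_id = character(), genome_id = character(),
                      lifestyle = character(), group = character(),
                      start = integer(), length = integer(),
                      bases = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  glen <- nchar(genome)
  if (glen < row$max_incl) {
    warning("genome ", genome_id, " (", glen, " bp) is shorter than the ",
            "maximum fragment length of group ", group, "; skipped")
    return(empty)
  }
  draw <- function() {
    lens <- row$min + floor(runif(n) * (row$max_incl - row$min + 1L))
    lens <- pmin(as.integer(lens), row$max_incl)
    starts <- floor(runif(n) * (glen - lens + 1L))
    list(lens = as.integer(lens), starts = as.integer(starts))
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(
    fragment_id = paste0(genome_id, "_f", seq_len(n)),
    genome_id = genome_id,
    lifestyle = lifestyle,
    group = row$name,
    start = d$starts,
    length = d$lens,
    bases = substring(genome, d$starts + 1L, d$starts + d$lens),
    stringsAsFactors = FALSE)
}

#' Plan genome-level cross-validation folds
#'
#' Partitions the curated genomes into `n_folds` folds, stratified by
#' lifestyle so each fold holds a near-equal share of each class.
#' Auto-labelled (non-curated) genomes are never held out: they go to
#' `always_train`. Splitting by complete genome (never by fragment)
#' guarantees that no genome contributes fragments to both the training
#' and test side of any rotation.
#'
#' @param labels Label table (see [validate_label_table()]).
#' @param n_folds Number of folds, `>= 2` (default 5).
#' @param seed Optional integer for a deterministic, RNG-state-preserving
#'   shuffle.
#' @return An object of class `cv_fold_plan`: a list with `n_folds`,
#'   `assignments` (named integer vector, curated genome -> fold) and
#'   `always_train` (character vector of auto genomes).
#' @export
make_cv_folds <- function(labels, n_folds = 5L, seed = NULL) {
  labels <- validate_label_table(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  curated <- labels[labels$dataset == "curated", ]
  assign_class <- function(ids) {
    ids <- sample(ids)
    stats::setNames(rep_len(seq_len(n_folds), length(ids)), ids)
  }
  plan_fun <- function() {
    out <- integer(0)
    for (cls in c("virulent", "temperate")) {
      ids <- curated$genome_id[curated$lifestyle == cls]
      if (length(ids) < n_folds)
        stop("class '", cls, "' has only ", length(ids),
             " curated genomes; need at least ", n_folds)
      out <- c(out, assign_class(ids))
    }
    out
  }
  assignments <- if (is.null(seed)) plan_fun() else withr::with_seed(seed, plan_fun())
  structure(list(n_folds = n_folds,
                 assignments = assignments,
                 always_train = labels$genome_id[labels$dataset == "auto"]),
            class = "cv_fold_plan")
}

#' @export
print.cv_fold_plan <- function(x, ...) {
  cat("Genome-level cross-validation plan:", x$n_folds, "folds,",
      length(x$assignments), "curated genomes,",
      length(x$always_train), "always-train genomes\n")
  invisible(x)
}

#' Build a leakage-free train/test fragment benchmark for one fold
#'
#' Draws `n_train` training and `n_test` test fragments for one rotation of
#' the fold plan and one length group. Test fragments come only from the
#' fold's held-out curated genomes; training fragments come from the
#' remaining curated genomes plus all auto-labelled genomes. Fragment
#' counts are balanced per lifestyle within one fragment, and spread
#' near-evenly over the split's genomes.
#'
#' @param genomes Data frame with columns `id`, `bases` (e.g. from
#'   [read_fasta()]).
#' @param labels Label table covering every genome id.
#' @param plan A `cv_fold_plan` from [make_cv_folds()].
#' @param fold Fold index in `1..plan$n_folds` to hold out.
#' @param group Length group name.
#' @param n_train,n_test Total fragment counts for each side.
#' @param seed Optional integer for a deterministic draw.
#' @return List with data frames `train` and `test` of labelled fragments.
#' @export
build_benchmark <- function(genomes, labels, plan, fold, group,
                            n_train = 8000L, n_test = 2000L, seed = NULL) {
  stopifnot(inherits(plan, "cv_fold_plan"))
  labels <- validate_label_table(labels)
  fold <- as.integer(fold)
  if (fold < 1L || fold > plan$n_folds) stop("fold must be in 1..", plan$n_folds)
  test_ids <- names(plan$assignments)[plan$assignments == fold]
  train_ids <- c(names(plan$assignments)[plan$assignments != fold],
                 plan$always_train)
  build <- function() {
    list(train = .draw_split(genomes, labels, train_ids, group, n_train),
         test = .draw_split(genomes, labels, test_ids, group, n_test))
  }
  out <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  leaked <- intersect(unique(out$train$genome_id), unique(out$test$genome_id))
  if (length(leaked) > 0)  # defensive; impossible by construction
    stop("genome leakage between train and test: ", paste(leaked, collapse = ", "))
  out
}

# Draw `n` fragments from the given genome ids, balanced per lifestyle
# within +/-1 and spread near-evenly over each class's genomes.
.draw_split <- function(genomes, labels, ids, group, n) {
  row <- .group_row(group)
  labels <- labels[match(ids, labels$genome_id), ]
  if (any(is.na(labels$genome_id)))
    stop("label table is missing genomes: ",
         paste(ids[is.na(labels$genome_id)], collapse = ", "))
  gb <- genomes$bases[match(ids, genomes$id)]
  if (any(is.na(gb)))
    stop("genome sequences missing for: ", paste(ids[is.na(gb)], collapse = ", "))
  too_short <- nchar(gb) < row$max_incl
  if (any(too_short)) {
    warning("skipping ", sum(too_short), " genome(s) shorter than ",
            row$max_incl, " bp in group ", group)
    gb <- gb[!too_short]
    labels <- labels[!too_short, ]
    ids <- ids[!too_short]
  }
  n <- as.integer(n)
  per_class <- c(virulent = ceiling(n / 2), temperate = floor(n / 2))
  parts <- list()
  for (cls in names(per_class)) {
    cls_ids <- ids[labels$lifestyle == cls]
    if (length(cls_ids) == 0L)
      stop("no ", cls, " genomes available in this split")
    cn <- per_class[[cls]]
    counts <- rep(cn %/% length(cls_ids), length(cls_ids))
    extra <- cn - sum(counts)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    for (j in seq_along(cls_ids)) {
      if (counts[j] == 0L) next
      parts[[length(parts) + 1L]] <- extract_fragments(
        gb[match(cls_ids[j], ids)], lifestyle = cls, group = group,
        n = counts[j], genome_id = cls_ids[j])
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Define a synthetic genome class model
#'
#' An order-`k` Markov chain over A/C/G/T used to generate genomes of one
#' lifestyle class with a controlled compositional signature. Rows and
#' columns of `transition` follow A, C, G, T order; row `i` gives the
#' distribution of the next base given the current length-`k` context.
#'
#' @param transition A `4^order x 4` row-stochastic matrix.
#' @param genome_length Genome length in bp.
#' @param label `"virulent"` or `"temperate"`.
#' @param order Markov order (default 1).
#' @return An object of class `synthetic_class_model`.
#' @export
synthetic_class_model <- function(transition, genome_length = 50000L,
                                  label = c("virulent", "temperate"),
                                  order = 1L) {
  label <- match.arg(label)
  order <- as.integer(order)
  transition <- as.matrix(transition)
  if (nrow(transition) != 4^order || ncol(transition) != 4L)
    stop("transition must be a ", 4^order, " x 4 matrix for order ", order)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stop("each transition row must be non-negative and sum to 1")
  structure(list(order = order, transition = transition,
                 genome_length = as.integer(genome_length), label = label),
            class = "synthetic_class_model")
}

#' Default two-class benchmark models
#'
#' The study conditions of the built-in parameter-recovery benchmark: the
#' virulent class is an order-1 chain with every transition row
#' (A,C,G,T) = (0.30, 0.20, 0.20, 0.30) (AT-rich, GC content 0.40, typical
#' of virulent phage genomes); each temperate row is the virulent row mixed
#' `1 - gc_mix` : `gc_mix` with the GC-biased row (0.05, 0.45, 0.45, 0.05),
#' emulating the amelioration of temperate phage composition toward a
#' GC-richer host chromosome.
#'
#' @param gc_mix Mixing weight of the GC-biased row in the temperate class
#'   (default 0.15).
#' @param genome_length Genome length in bp (default 50,000).
#' @return Named list with elements `virulent` and `temperate`.
#' @export
benchmark_class_models <- function(gc_mix = 0.15, genome_length = 50000L) {
  vir_row <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  gc_row <- c(A = 0.05, C = 0.45, G = 0.45, T = 0.05)
  vir <- matrix(vir_row, nrow = 4, ncol = 4, byrow = TRUE,
                dimnames = list(names(vir_row), names(vir_row)))
  tem <- (1 - gc_mix) * vir +
    gc_mix * matrix(gc_row, nrow = 4, ncol = 4, byrow = TRUE)
  list(virulent = synthetic_class_model(vir, genome_length, "virulent"),
       temperate = synthetic_class_model(tem, genome_length, "temperate"))
}

#' Generate synthetic genomes from a class model
#'
#' Samples genomes from the model's Markov chain (uniform initial state).
#'
#' @param model A [synthetic_class_model()].
#' @param n_genomes Number of genomes.
#' @param seed Optional integer for a deterministic, RNG-state-preserving
#'   draw.
#' @param prefix Genome id prefix (default the model's label).
#' @return Data frame with columns `id`, `bases`, `length`, `lifestyle`.
#' @export
generate_synthetic_genomes <- function(model, n_genomes, seed = NULL,
                                       prefix = NULL) {
  stopifnot(inherits(model, "synthetic_class_model"))
  if (is.null(prefix)) prefix <- model$label
  alpha <- c("A", "C", "G", "T")
  gen <- function() {
    vapply(seq_len(n_genomes), function(i) {
      codes <- cpp_markov_chain(model$transition, model$genome_length,
                                model$order)
      paste0(alpha[codes + 1L], collapse = "")
    }, character(1))
  }
  bases <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  data.frame(id = paste0(prefix, "_g", seq_len(n_genomes)),
             bases = bases, length = nchar(bases),
             lifestyle = model$label, stringsAsFactors = FALSE)
}

#' Generate the self-contained two-class benchmark corpus
#'
#' Convenience wrapper: generates `n_per_class` genomes from each of the
#' [benchmark_class_models()] and the matching curated label table.
#'
#' @param n_per_class Genomes per lifestyle class (default 20).
#' @param genome_length Genome length in bp (default 50,000).
#' @param seed Optional integer seed.
#' @param gc_mix Passed to [benchmark_class_models()].
#' @return List with `genomes` (data frame) and `labels` (label table).
#' @export
synthetic_benchmark <- function(n_per_class = 20L, genome_length = 50000L,
                                seed = NULL, gc_mix = 0.15) {
  models <- benchmark_class_models(gc_mix = gc_mix,
                                   genome_length = genome_length)
  gen <- function() {
    rbind(generate_synthetic_genomes(models$virulent, n_per_class),
          generate_synthetic_genomes(models$temperate, n_per_class))
  }
  genomes <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  labels <- data.frame(genome_id = genomes$id,
                       lifestyle = genomes$lifestyle,
                       dataset = "curated", stringsAsFactors = FALSE)
  list(genomes = genomes[, c("id", "bases", "length")],
       labels = validate_label_table(labels))
}
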
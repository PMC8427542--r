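# Shared fixtures, built in code at test time.

# A model set with freshly initialized (untrained) weights: routing and
# report tests need valid models, not accurate ones.
tiny_model_set <- function(seed = 1, F = 8) {
  lg <- length_groups()
  models <- lapply(seq_len(nrow(lg)), function(i) {
    cfg <- network_config(L = lg$L[i], F = F)
    structure(list(weights = init_weights(cfg, seed = seed + i), config = cfg),
              class = "phage_cnn")
  })
  names(models) <- lg$name
  structure(models, class = "phage_model_set")
}

# A small separable two-class fragment set: virulent fragments are drawn
# GC-poor, temperate fragments GC-rich.
separable_fragments <- function(n_per_class = 32, len = 300, n_genomes = 4,
                                seed = 7) {
  withr::with_seed(seed, {
    make <- function(cls, p_gc) {
      do.call(rbind, lapply(seq_len(n_per_class), function(i) {
        g <- (i - 1L) %% n_genomes + 1L
        bases <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                               prob = c((1 - p_gc) / 2, p_gc / 2,
                                        p_gc / 2, (1 - p_gc) / 2)),
                        collapse = "")
        data.frame(fragment_id = paste0(cls, "_", i),
                   genome_id = paste0(cls, "_g", g),
                   lifestyle = cls, group = "A", start = 0L,
                   length = len, bases = bases, stringsAsFactors = FALSE)
      }))
    }
    rbind(make("virulent", 0.25), make("temperate", 0.75))
  })
}

write_tmp_fasta <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".fasta.gz" else ".fasta")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}
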
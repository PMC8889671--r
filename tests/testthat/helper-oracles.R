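# Independent oracles and tiny generators used across the suite.

all_kmers_for_test <- function(k) {
  apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1, paste,
        collapse = "")
}

random_sequence <- function(n, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

random_spacer <- function() random_sequence(28)

toy_transcriptome <- function(lengths, seed = 1, gc = 0.5) {
  set.seed(seed)
  data.frame(
    transcript_id = paste0("TX", seq_along(lengths)),
    gene_id = paste0("G", seq_along(lengths)),
    gene_symbol = paste0("Sym", seq_along(lengths)),
    strand = "+",
    length = lengths,
    sequence = vapply(lengths, random_sequence, character(1), gc = gc),
    stringsAsFactors = FALSE
  )
}

# brute-force Hamming scan over every window of every transcript
brute_hamming_search <- function(guides, transcripts, max_mismatches) {
  targets <- guide_target_seq(guides$spacer)
  rows <- list()
  for (g in seq_len(nrow(guides))) {
    gv <- utf8ToInt(targets[g])
    for (t in seq_len(nrow(transcripts))) {
      iv <- utf8ToInt(transcripts$sequence[t])
      n_win <- length(iv) - 28L + 1L
      if (n_win < 1L) next
      for (p in seq_len(n_win) - 1L) {
        mm <- sum(iv[(p + 1L):(p + 28L)] != gv)
        if (mm <= max_mismatches) {
          rows[[length(rows) + 1L]] <- data.frame(
            guide_id = guides$guide_id[g],
            reference_id = transcripts$transcript_id[t],
            position = p, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(guide_id = character(), reference_id = character(),
                      position = integer(), mismatches = integer()))
  }
  out <- out[order(out$guide_id, out$reference_id, out$position), ]
  rownames(out) <- NULL
  out
}

# Kruskal-Wallis H from the textbook rank-sum formula with tie correction
manual_kruskal_H <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# AUC by explicit concordance counting over all (positive, negative) pairs
brute_auc <- function(score, is_pos) {
  pos <- score[is_pos]
  neg <- score[!is_pos]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# small planted-signal dataset shared by model/evaluation tests:
# class is driven by the nucleotide at spacer position 8
planted_dataset <- function(seed = 11, noise_sd = 0.02,
                            n_transcripts = 3,
                            length_range = c(120, 220),
                            k_values = 1) {
  cfg <- fixture_config(n_transcripts = n_transcripts,
                        length_range = length_range,
                        planted_rule = planted_rule(
                          position = 8,
                          effects = c(A = 0.1, C = -0.1, G = -0.35,
                                      T = 0.38),
                          mid_effect = 0, occ_effect = 0),
                        replicate_noise_sd = noise_sd,
                        peaks_per_transcript = 0,
                        seed = seed)
  suppressWarnings(
    make_guide_dataset(cfg, feature_space = default_feature_space(k_values),
                       max_mismatches = 0))
}
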
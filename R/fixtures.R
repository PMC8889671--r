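#' Configuration for the synthetic fixture generator
#'
#' Bundles the knobs of the synthetic-data generator that emulates the
#' study conditions end to end: a small multi-transcript transcriptome, a
#' three-replicate guide/expression table with a plantable
#' sequence/position/occupancy signal and controllable replicate noise,
#' and occupancy peaks emitted in both peak-file dialects.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Transcript length range in nt (min must be >= 28).
#' @param gc_content Target GC fraction in (0, 1).
#' @param n_guides_per_transcript `"all"` or a count of windows sampled
#'   per transcript for the knockdown table.
#' @param planted_rule A [planted_rule()] mapping (spacer, relative
#'   position, occupancy overlap) to expected expression.
#' @param replicate_noise_sd Gaussian noise SD added independently per
#'   replicate (on the expression scale).
#' @param replicate_disagreement_rate Optional target fraction of
#'   replicate pairs crossing a quartile boundary; when set, the noise SD
#'   is calibrated analytically to hit it and `replicate_noise_sd` is
#'   ignored.
#' @param peaks_per_transcript Occupancy peaks per transcript.
#' @param peak_length_range Peak length range in nt.
#' @param avoid_window Optional relative interval `c(lo, hi)`; when set,
#'   peaks are kept out of it so the window is protein-free ("open").
#' @param seed Integer seed; all generators are fully deterministic
#'   given it.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_transcripts = 6L,
                           length_range = c(300L, 800L),
                           gc_content = 0.5,
                           n_guides_per_transcript = "all",
                           planted_rule = default_planted_rule(),
                           replicate_noise_sd = 0.05,
                           replicate_disagreement_rate = NULL,
                           peaks_per_transcript = 2L,
                           peak_length_range = c(20L, 60L),
                           avoid_window = NULL,
                           seed = 1L) {
  stopifnot(n_transcripts >= 1L, gc_content > 0, gc_content < 1,
            peaks_per_transcript >= 0L, replicate_noise_sd >= 0)
  if (length_range[1L] < 28L) {
    stop("minimum transcript length must be at least 28 nt")
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    length_range = as.integer(length_range),
    gc_content = gc_content,
    n_guides_per_transcript = n_guides_per_transcript,
    planted_rule = planted_rule,
    replicate_noise_sd = replicate_noise_sd,
    replicate_disagreement_rate = replicate_disagreement_rate,
    peaks_per_transcript = as.integer(peaks_per_transcript),
    peak_length_range = as.integer(peak_length_range),
    avoid_window = avoid_window,
    seed = as.integer(seed)
  ), class = "fixture_config")
}

#' A compositional planted efficacy rule
#'
#' Expected normalized expression is a sum of three independent terms,
#' mirroring the three feature sources the pipeline extracts, so each
#' family can be validated in isolation: a sequence term keyed on the
#' nucleotide the spacer carries at one position, a positional term that
#' lowers expression (better knockdown) for guides in the mid-transcript
#' window, and an occupancy term that raises expression proportionally to
#' protein-occupancy overlap. The result is clipped to `[0, 1]`.
#'
#' @param position 0-based spacer position carrying the sequence signal.
#' @param effects Named additive effects per nucleotide at that position.
#' @param mid_window Relative-position interval treated as accessible.
#' @param mid_effect Expression reduction inside `mid_window`.
#' @param occ_effect Expression increase at 100% occupancy overlap.
#' @param base Baseline expression.
#' @return A list of class `planted_rule`.
#' @export
planted_rule <- function(position = 8L,
                         effects = c(A = 0.2, C = 0, G = -0.3, T = 0.3),
                         mid_window = c(0.3, 0.7),
                         mid_effect = 0.15,
                         occ_effect = 0.2,
                         base = 0.5) {
  stopifnot(position >= 0L, position < SPACER_LEN,
            all(sort(names(effects)) == BASES))
  structure(list(position = as.integer(position), effects = effects,
                 mid_window = mid_window, mid_effect = mid_effect,
                 occ_effect = occ_effect, base = base),
            class = "planted_rule")
}

# default-argument helper: avoids self-reference of the planted_rule
# argument in fixture_config()
default_planted_rule <- function() planted_rule()

# uniform integer draw on [lo, hi], safe when lo == hi (unlike sample())
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Expected expression under a planted rule
#'
#' @param rule A [planted_rule()].
#' @param spacers Character vector of 28-nt spacers.
#' @param relpos Relative target positions in `[0, 1]`.
#' @param occ Occupancy overlap percentages in `[0, 100]`.
#' @return Expected expression values clipped to `[0, 1]`.
#' @export
planted_expected <- function(rule, spacers, relpos, occ = 0) {
  nt <- substring(spacers, rule$position + 1L, rule$position + 1L)
  e <- rule$base + unname(rule$effects[nt]) +
    ifelse(relpos >= rule$mid_window[1L] & relpos <= rule$mid_window[2L],
           -rule$mid_effect, 0) +
    rule$occ_effect * occ / 100
  pmin(pmax(e, 0), 1)
}

#' Generate a synthetic transcriptome
#'
#' Random sequences with the configured GC content (each base drawn
#' independently, G and C at `gc_content / 2` each), one per transcript,
#' with gene IDs and symbols attached so the annotation-driven entry
#' points can be exercised.
#'
#' @param config A [fixture_config()].
#' @param fasta_path Optional path; when given the transcriptome is also
#'   written as FASTA.
#' @return Transcriptome data frame in [read_transcriptome()] layout.
#' @export
make_transcriptome <- function(config, fasta_path = NULL) {
  set.seed(config$seed + 1L)
  gc <- config$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  lens <- sample_range(config$length_range[1L], config$length_range[2L],
                       config$n_transcripts)
  seqs <- vapply(lens, function(L) {
    paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  idx <- seq_len(config$n_transcripts)
  df <- data.frame(
    transcript_id = sprintf("ENSTFIX%05d", idx),
    gene_id = sprintf("ENSGFIX%05d", idx),
    gene_symbol = sprintf("FIXG%d", idx),
    strand = "+",
    length = lens,
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  if (!is.null(fasta_path)) {
    out <- Biostrings::BStringSet(df$sequence)
    names(out) <- paste(df$transcript_id, df$gene_symbol)
    Biostrings::writeXStringSet(out, fasta_path)
  }
  df
}

#' Write a transcript annotation table
#'
#' Delimited text with gene ID, transcript ID, symbol, chromosome, gene
#' start/end, strand, transcript length and the full sequence (one row
#' per transcript), the layout [read_transcriptome()] consumes as
#' `format = "table"`.
#'
#' @param transcripts Transcriptome data frame.
#' @param path Output path.
#' @export
write_annotation_table <- function(transcripts, path) {
  df <- data.frame(
    gene_id = transcripts$gene_id,
    transcript_id = transcripts$transcript_id,
    gene_symbol = transcripts$gene_symbol,
    chromosome = "1",
    gene_start = 1L,
    gene_end = transcripts$length,
    strand = transcripts$strand,
    length = transcripts$length,
    sequence = transcripts$sequence,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate occupancy peaks for a synthetic transcriptome
#'
#' Uniformly placed non-degenerate peaks per transcript, optionally kept
#' out of a relative "open" window (used when the planted rule ties
#' efficacy to low occupancy). When paths are given the same intervals
#' are written in both the BED and macs2-xls dialects, which must parse
#' back to identical internal peaks.
#'
#' @param config A [fixture_config()].
#' @param transcripts Transcriptome data frame.
#' @param bed_path,xls_path Optional output paths.
#' @return Peak data frame in [read_peaks()] layout.
#' @export
make_peaks <- function(config, transcripts, bed_path = NULL,
                       xls_path = NULL) {
  set.seed(config$seed + 2L)
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    len <- transcripts$length[i]
    for (p in seq_len(config$peaks_per_transcript)) {
      for (try in 1:50) {
        w <- sample_range(config$peak_length_range[1L],
                          config$peak_length_range[2L])
        if (w >= len) w <- max(1L, len - 1L)
        s <- sample.int(len - w, 1L) - 1L
        if (!is.null(config$avoid_window)) {
          lo <- config$avoid_window[1L] * len
          hi <- config$avoid_window[2L] * len
          if (s < hi && (s + w) > lo) next  # overlaps the open window
        }
        rows[[length(rows) + 1L]] <- data.frame(
          reference_id = transcripts$transcript_id[i], start = s,
          end = s + w, score = round(stats::runif(1, 5, 50), 2),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reference_id = character(), start = integer(),
               end = integer(), score = numeric())
  if (!is.null(bed_path)) {
    writeLines(paste(peaks$reference_id, peaks$start, peaks$end,
                     sprintf("peak_%d", seq_len(nrow(peaks))),
                     peaks$score, "+", sep = "\t"), bed_path)
  }
  if (!is.null(xls_path)) {
    con <- file(xls_path, "w")
    writeLines(c("# This file is generated by the fixture generator",
                 "# macs2-xls dialect: 1-based inclusive start",
                 paste("chr", "start", "end", "length", "abs_summit",
                       "pileup", "-log10(pvalue)", "fold_enrichment",
                       "-log10(qvalue)", "name", sep = "\t")), con)
    if (nrow(peaks)) {
      writeLines(paste(peaks$reference_id, peaks$start + 1L, peaks$end,
                       peaks$end - peaks$start,
                       peaks$start + (peaks$end - peaks$start) %/% 2L,
                       peaks$score, 5, 2, 3,
                       sprintf("peak_%d", seq_len(nrow(peaks))),
                       sep = "\t"), con)
    }
    close(con)
  }
  peaks
}

# expected quartile-disagreement probability for one expected value and
# noise sd, under clipping to [0, 1]
pair_disagreement_prob <- function(expected, sd) {
  cuts <- c(0.25, 0.5, 0.75)
  vapply(expected, function(e) {
    p <- diff(c(0, stats::pnorm(cuts, mean = e, sd = sd), 1))
    1 - sum(p^2)
  }, numeric(1))
}

#' Calibrate replicate noise to a target disagreement rate
#'
#' Solves for the Gaussian noise SD at which the expected fraction of
#' replicate pairs falling in different expression quartiles equals the
#' target, given the planted expected expressions. The relation is
#' computed analytically from the normal CDF (no simulation), so the
#' calibration itself is deterministic.
#'
#' @param expected Planted expected expression values.
#' @param target_rate Target disagreement fraction in (0, 1).
#' @return Noise SD.
#' @export
calibrate_noise_sd <- function(expected, target_rate) {
  stopifnot(target_rate > 0, target_rate < 1)
  f <- function(s) mean(pair_disagreement_prob(expected, s)) - target_rate
  lo <- 1e-4
  hi <- 1
  if (f(lo) >= 0) return(lo)
  if (f(hi) <= 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Generate a three-replicate knockdown table
#'
#' Each guide's planted expected expression receives independent
#' Gaussian noise per replicate, clipped to `[0, 1]`; exactly three
#' replicates are emitted per guide. With a
#' `replicate_disagreement_rate` configured, the noise SD is first
#' calibrated so the empirical replicate-pair quartile disagreement
#' matches the target.
#'
#' @param config A [fixture_config()].
#' @param guides Guide data frame enumerated from the fixture
#'   transcriptome.
#' @param transcripts The fixture transcriptome.
#' @param peaks Optional peak data frame feeding the occupancy term.
#' @return Data frame of observations: `guide_id`, `replicate_id` (1-3),
#'   `expression`, `expected`, `class` (quartile code of `expression`).
#' @export
make_knockdown_table <- function(config, guides, transcripts,
                                 peaks = NULL) {
  tlen <- transcripts$length[match(guides$source_transcript,
                                   transcripts$transcript_id)]
  relpos <- relative_position_feature(guides$target_start, tlen)
  occ <- if (is.null(peaks) || !nrow(peaks)) rep(0, nrow(guides)) else {
    peak_split <- split(peaks[, c("start", "end")], peaks$reference_id)
    vapply(seq_len(nrow(guides)), function(i) {
      occupancy_overlap_feature(guides$target_start[i],
                                guides$target_end[i],
                                peak_split[[guides$source_transcript[i]]])
    }, numeric(1))
  }
  expected <- planted_expected(config$planted_rule, guides$spacer, relpos,
                               occ)
  sd <- if (!is.null(config$replicate_disagreement_rate)) {
    calibrate_noise_sd(expected, config$replicate_disagreement_rate)
  } else {
    config$replicate_noise_sd
  }
  set.seed(config$seed + 3L)
  n <- nrow(guides)
  obs <- data.frame(
    guide_id = rep(guides$guide_id, each = 3L),
    replicate_id = rep(1:3, times = n),
    expected = rep(expected, each = 3L),
    stringsAsFactors = FALSE
  )
  obs$expression <- pmin(pmax(obs$expected +
                                stats::rnorm(nrow(obs), 0, sd), 0), 1)
  obs$class <- assign_class(obs$expression)
  attr(obs, "noise_sd") <- sd
  obs
}

#' Generate a complete synthetic guide dataset
#'
#' End-to-end convenience wrapper: transcriptome, guide enumeration
#' (optionally down-sampled per transcript), transcriptome-wide mismatch
#' search, occupancy peaks, three-replicate knockdown table, and the
#' replicate-expanded feature matrix with its labels. Fully deterministic
#' given `config$seed`.
#'
#' @param config A [fixture_config()].
#' @param feature_space Descriptor table (default: full pre-selection
#'   space).
#' @param max_mismatches Mismatch budget for the transcriptome search.
#' @return List with `transcripts`, `guides`, `peaks`, `hits`,
#'   `observations`, `guide_features` (per guide), `features` (per
#'   guide x replicate), `expression`, `labels`, `replicate_id`.
#' @export
make_guide_dataset <- function(config,
                               feature_space = default_feature_space(),
                               max_mismatches = 3L) {
  transcripts <- make_transcriptome(config)
  guides <- enumerate_guides(transcripts)
  if (!identical(config$n_guides_per_transcript, "all")) {
    set.seed(config$seed + 4L)
    keep <- unlist(lapply(split(seq_len(nrow(guides)),
                                guides$source_transcript), function(idx) {
      sort(sample(idx, min(config$n_guides_per_transcript, length(idx))))
    }))
    guides <- guides[sort(keep), , drop = FALSE]
  }
  peaks <- make_peaks(config, transcripts)
  hits <- search_transcriptome(guides, transcripts, max_mismatches)
  suppressWarnings(
    guide_features <- build_feature_matrix(guides, transcripts, hits,
                                           peaks, feature_space))
  observations <- make_knockdown_table(config, guides, transcripts, peaks)
  features <- expand_to_replicates(guide_features, observations)
  list(transcripts = transcripts, guides = guides, peaks = peaks,
       hits = hits, observations = observations,
       guide_features = guide_features, features = features,
       expression = observations$expression,
       labels = observations$class,
       replicate_id = observations$replicate_id)
}
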
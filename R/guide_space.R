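SPACER_LEN <- 28L

#' Reverse complement of DNA strings
#'
#' @param x Character vector over the `{A,C,G,T,N}` alphabet.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Target sequence bound by a spacer
#'
#' The stored spacer is the reverse complement of the transcript window it
#' base-pairs with; this returns the window (target-side) sequence. The
#' orientation convention is isolated here so it can be flipped in one
#' place.
#'
#' @param spacer Character vector of 28-nt spacers.
#' @return Character vector of target-side window sequences.
#' @export
guide_target_seq <- function(spacer) {
  revcomp(spacer)
}

#' Enumerate all candidate guides over transcripts
#'
#' Slides a 28-nt window along each transcript and emits one candidate per
#' window, ordered by target start. The spacer stored for each candidate is
#' the reverse complement of the transcript window (the guide hybridizes to
#' the transcript). Windows containing `N` are skipped because an undefined
#' base cannot parameterize sequence features; transcripts shorter than
#' 28 nt yield no candidates, with a warning.
#'
#' @param transcripts Transcriptome data frame from [read_transcriptome()]
#'   (one or more rows).
#' @return Data frame with columns `guide_id` (`transcript|start`),
#'   `spacer`, `source_transcript`, `target_start` (0-based) and
#'   `target_end` (exclusive).
#' @export
enumerate_guides <- function(transcripts) {
  pieces <- lapply(seq_len(nrow(transcripts)), function(i) {
    id <- transcripts$transcript_id[i]
    seq <- transcripts$sequence[i]
    len <- nchar(seq)
    n_win <- len - SPACER_LEN + 1L
    if (n_win < 1L) {
      warning("transcript ", id, " is shorter than 28 nt; no candidates")
      return(NULL)
    }
    starts <- seq_len(n_win) - 1L
    windows <- substring(seq, starts + 1L, starts + SPACER_LEN)
    ok <- !grepl("N", windows, fixed = TRUE)
    if (!any(ok)) {
      return(NULL)
    }
    starts <- starts[ok]
    data.frame(
      guide_id = paste0(id, "|", starts),
      spacer = revcomp(windows[ok]),
      source_transcript = id,
      target_start = starts,
      target_end = starts + SPACER_LEN,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(guide_id = character(), spacer = character(),
                      source_transcript = character(),
                      target_start = integer(), target_end = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# k-mer seed index over all transcript windows of length `width`:
# environment mapping k-mer -> matrix of (transcript index, 0-based pos).
build_seed_index <- function(sequences, width) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(sequences)) {
    seq <- sequences[[i]]
    n <- nchar(seq) - width + 1L
    if (n < 1L) next
    starts <- seq_len(n) - 1L
    kmers <- substring(seq, starts + 1L, starts + width)
    by_kmer <- split(starts, kmers)
    for (k in names(by_kmer)) {
      entry <- get0(k, envir = env)
      add <- cbind(i, by_kmer[[k]])
      assign(k, if (is.null(entry)) add else rbind(entry, add), envir = env)
    }
  }
  env
}

#' Search guides against a transcriptome with bounded mismatches
#'
#' Finds every transcript window whose Hamming distance to a guide's
#' target-side sequence is at most `max_mismatches`. Only the sense strand
#' is searched (transcripts are single-stranded RNA) and no indels are
#' modeled. The search uses pigeonhole seeding: the 28-mer target is split
#' into `max_mismatches + 1` exact seed blocks, candidate windows are
#' located through a k-mer index of the transcriptome, and each candidate
#' is verified by a full Hamming comparison, so at least one seed block
#' must match exactly in any window within the mismatch budget.
#'
#' @param guides Guide data frame from [enumerate_guides()].
#' @param transcripts Transcriptome data frame.
#' @param max_mismatches Integer in `[0, 3]`; 3 is the maximum mismatch
#'   count tolerated by the Cas13 system and the default.
#' @return Data frame of hits with columns `guide_id`, `reference_id`,
#'   `position` (0-based start of the complementary window) and
#'   `mismatches`, sorted by guide, reference, position. A guide's own
#'   source window always appears with 0 mismatches.
#' @export
search_transcriptome <- function(guides, transcripts, max_mismatches = 3L) {
  stopifnot(max_mismatches >= 0L, max_mismatches <= 3L)
  if (!nrow(transcripts)) {
    stop("transcriptome is empty")
  }
  if (any(nchar(guides$spacer) != SPACER_LEN)) {
    stop("all spacers must be exactly 28 nt")
  }
  seed_len <- SPACER_LEN %/% (max_mismatches + 1L)
  seqs <- transcripts$sequence
  ids <- transcripts$transcript_id
  ivecs <- lapply(seqs, utf8ToInt)
  lens <- nchar(seqs)
  index <- build_seed_index(seqs, seed_len)
  n_blocks <- max_mismatches + 1L
  targets <- guide_target_seq(guides$spacer)

  res <- vector("list", nrow(guides))
  for (g in seq_len(nrow(guides))) {
    target <- targets[g]
    gv <- utf8ToInt(target)
    cand_t <- integer(0)
    cand_p <- integer(0)
    for (b in seq_len(n_blocks) - 1L) {
      off <- b * seed_len
      kmer <- substr(target, off + 1L, off + seed_len)
      entry <- get0(kmer, envir = index)
      if (is.null(entry)) next
      ws <- entry[, 2L] - off
      ok <- ws >= 0L & ws <= lens[entry[, 1L]] - SPACER_LEN
      cand_t <- c(cand_t, entry[ok, 1L])
      cand_p <- c(cand_p, ws[ok])
    }
    if (!length(cand_t)) {
      res[[g]] <- NULL
      next
    }
    dedup <- !duplicated(cand_t * 2^31 + cand_p)
    cand_t <- cand_t[dedup]
    cand_p <- cand_p[dedup]
    mm <- integer(length(cand_t))
    for (j in seq_along(cand_t)) {
      iv <- ivecs[[cand_t[j]]]
      p <- cand_p[j]
      mm[j] <- sum(iv[(p + 1L):(p + SPACER_LEN)] != gv)
    }
    keep <- mm <= max_mismatches
    if (!any(keep)) {
      res[[g]] <- NULL
      next
    }
    res[[g]] <- data.frame(
      guide_id = guides$guide_id[g],
      reference_id = ids[cand_t[keep]],
      position = cand_p[keep],
      mismatches = mm[keep],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(guide_id = character(), reference_id = character(),
                      position = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$guide_id, out$reference_id, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count transcriptome hits per guide
#'
#' @param guides Guide data frame.
#' @param hits Hit data frame from [search_transcriptome()].
#' @return Integer vector of hit counts, one per guide, in guide order.
#' @export
count_hits <- function(guides, hits) {
  counts <- table(factor(hits$guide_id, levels = guides$guide_id))
  as.integer(counts)
}

#' Export alignment hits as BED6
#'
#' One line per hit: reference, start, end, guide ID, mismatch count as the
#' score, and `+` strand (only the sense strand is ever searched). Lines
#' are sorted by reference then position.
#'
#' @param hits Hit data frame from [search_transcriptome()].
#' @param path Output path.
#' @export
hits_to_bed <- function(hits, path) {
  if (!nrow(hits)) {
    cat("", file = path)
    return(invisible(path))
  }
  ord <- order(hits$reference_id, hits$position)
  h <- hits[ord, , drop = FALSE]
  lines <- paste(h$reference_id, h$position, h$position + SPACER_LEN,
                 h$guide_id, h$mismatches, "+", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
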
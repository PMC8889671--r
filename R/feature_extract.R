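BASES <- c("A", "C", "G", "T")

all_kmers <- function(k) {
  if (k == 1L) return(BASES)
  sub <- all_kmers(k - 1L)
  as.vector(t(outer(sub, BASES, paste0)))
}

#' The default guide feature space
#'
#' Builds the ordered descriptor table for the pre-selection feature
#' space: one-hot positional k-mer indicators for every k-mer at every
#' position it fits in the 28-nt spacer, per-base composition percentages,
#' the relative target position, the protein-occupancy overlap percentage
#' and the transcriptome hit count. With `k_values = 1:3` the space has
#' `28*4 + 27*16 + 26*64 + 4 + 1 + 1 + 1 = 2215` columns.
#'
#' @param k_values Integer vector of k-mer sizes, subset of `1:3`.
#' @param extras Which non-k-mer feature families to append.
#' @return Data frame of descriptors with columns `name`, `kind`, `k`,
#'   `kmer`, `position`. Positions are 0-based from the 5' end of the
#'   spacer.
#' @export
default_feature_space <- function(k_values = 1:3,
                                  extras = c("composition", "position",
                                             "occupancy", "multiplicity")) {
  stopifnot(all(k_values %in% 1:3))
  if (length(extras)) {
    extras <- match.arg(extras, several.ok = TRUE)
  }
  blocks <- lapply(sort(k_values), function(k) {
    kmers <- all_kmers(k)
    positions <- 0:(SPACER_LEN - k)
    data.frame(
      name = paste("kmer", k, rep(kmers, times = length(positions)),
                   rep(positions, each = length(kmers)), sep = "|"),
      kind = "positional_kmer",
      k = k,
      kmer = rep(kmers, times = length(positions)),
      position = rep(positions, each = length(kmers)),
      stringsAsFactors = FALSE
    )
  })
  extra_rows <- list()
  if ("composition" %in% extras) {
    extra_rows$comp <- data.frame(
      name = paste0("comp|", BASES), kind = "composition",
      k = NA_integer_, kmer = BASES, position = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if ("position" %in% extras) {
    extra_rows$pos <- data.frame(
      name = "relpos", kind = "position", k = NA_integer_,
      kmer = NA_character_, position = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if ("occupancy" %in% extras) {
    extra_rows$occ <- data.frame(
      name = "occ_overlap", kind = "occupancy", k = NA_integer_,
      kmer = NA_character_, position = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if ("multiplicity" %in% extras) {
    extra_rows$hits <- data.frame(
      name = "n_hits", kind = "multiplicity", k = NA_integer_,
      kmer = NA_character_, position = NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(blocks, unname(extra_rows)))
  rownames(out) <- NULL
  out
}

#' One-hot positional k-mer indicators for one spacer
#'
#' For each k and each 0-based position `p` in `[0, 28 - k]`, the
#' indicator of the k-mer actually present at `p` is 1 and its `4^k - 1`
#' siblings at the same position are 0.
#'
#' @param spacer A single 28-nt string over `{A,C,G,T}`.
#' @param k_values Integer vector of k-mer sizes, subset of `1:3`.
#' @return Named 0/1 vector over all `kmer|k|KMER|p` descriptors.
#' @export
positional_kmer_features <- function(spacer, k_values = 1:3) {
  check_spacer(spacer)
  space <- default_feature_space(k_values, extras = character(0))
  out <- numeric(nrow(space))
  names(out) <- space$name
  for (k in sort(k_values)) {
    positions <- 0:(SPACER_LEN - k)
    present <- substring(spacer, positions + 1L, positions + k)
    out[paste("kmer", k, present, positions, sep = "|")] <- 1
  }
  out
}

check_spacer <- function(spacer) {
  if (length(spacer) != 1L || nchar(spacer) != SPACER_LEN) {
    stop("spacer must be a single 28-nt string")
  }
  if (grepl("[^ACGT]", spacer)) {
    stop("spacer contains characters outside {A,C,G,T}")
  }
  invisible(spacer)
}

#' Per-base composition percentages of a spacer
#'
#' @param spacer A single 28-nt string over `{A,C,G,T}`.
#' @return Named vector `comp|A`, `comp|C`, `comp|G`, `comp|T`, each
#'   `100 * count / 28`; the four values sum to 100.
#' @export
composition_features <- function(spacer) {
  check_spacer(spacer)
  chars <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  counts <- vapply(BASES, function(b) sum(chars == b), numeric(1))
  out <- 100 * counts / SPACER_LEN
  names(out) <- paste0("comp|", BASES)
  out
}

#' Relative position of a guide target on its transcript
#'
#' The midpoint of the 28-nt complementary region normalized by transcript
#' length, so 0 is the 5' end and 1 the 3' end. Transcript ends are
#' believed to be highly structured and less accessible, which makes this
#' a candidate efficacy feature.
#'
#' @param target_start 0-based target start (vectorized).
#' @param transcript_length Positive transcript length in nt.
#' @return Value(s) in `[0, 1]`: `(target_start + 14) / transcript_length`.
#' @export
relative_position_feature <- function(target_start, transcript_length) {
  if (any(transcript_length <= 0)) {
    stop("transcript_length must be positive")
  }
  if (any(target_start + SPACER_LEN > transcript_length)) {
    stop("guide window extends past the transcript end")
  }
  (target_start + SPACER_LEN / 2) / transcript_length
}

# total length of the union of [start, end) intervals
interval_union_length <- function(start, end) {
  if (!length(start)) return(0L)
  ord <- order(start)
  start <- start[ord]
  end <- end[ord]
  total <- 0L
  cur_s <- start[1L]
  cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]
      cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Protein-occupancy overlap of a guide window
#'
#' Percentage of the 28-nt target window covered by the union of
#' occupancy peaks on the same transcript. Overlapping peaks are unioned
#' before measuring, so the result does not depend on how the occupied
#' region was split into peaks.
#'
#' @param target_start,target_end 0-based half-open guide window.
#' @param peaks Data frame of peaks on the guide's transcript (columns
#'   `start`, `end`, 0-based half-open); may be empty.
#' @return Overlap percentage in `[0, 100]`.
#' @export
occupancy_overlap_feature <- function(target_start, target_end, peaks) {
  if (is.null(peaks) || !nrow(peaks)) return(0)
  s <- pmax(peaks$start, target_start)
  e <- pmin(peaks$end, target_end)
  keep <- s < e
  if (!any(keep)) return(0)
  100 * interval_union_length(s[keep], e[keep]) / (target_end - target_start)
}

#' Build the guides x features matrix
#'
#' Assembles the full feature matrix for a set of guides: positional
#' k-mer indicators are computed on the spacer as stored, composition on
#' the spacer, relative position and occupancy overlap on the target
#' window, and the hit count from the transcriptome search. Feature
#' extraction is a pure function of its inputs: identical inputs give
#' bit-identical rows.
#'
#' @param guides Guide data frame from [enumerate_guides()].
#' @param transcripts Transcriptome data frame resolving every
#'   `source_transcript`.
#' @param hits Hit data frame from [search_transcriptome()]; required when
#'   the feature space contains `n_hits`.
#' @param peaks Peak data frame from [read_peaks()] or `NULL`. Transcripts
#'   with no occupancy data get overlap 0 with a warning (occupancy files
#'   are cell-line-dependent and sparse).
#' @param feature_space Ordered descriptor table, by default
#'   [default_feature_space()].
#' @return Numeric matrix, rows in guide input order (rownames
#'   `guide_id`), columns exactly in `feature_space` order.
#' @export
build_feature_matrix <- function(guides, transcripts, hits = NULL,
                                 peaks = NULL,
                                 feature_space = default_feature_space()) {
  unknown <- setdiff(guides$source_transcript, transcripts$transcript_id)
  if (length(unknown)) {
    bad <- guides$guide_id[guides$source_transcript %in% unknown]
    stop("guide(s) reference unknown transcript(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  n <- nrow(guides)
  mat <- matrix(0, nrow = n, ncol = nrow(feature_space),
                dimnames = list(guides$guide_id, feature_space$name))
  kinds <- feature_space$kind

  for (k in unique(feature_space$k[kinds == "positional_kmer"])) {
    positions <- unique(
      feature_space$position[kinds == "positional_kmer" &
                               feature_space$k == k])
    for (p in positions) {
      present <- substring(guides$spacer, p + 1L, p + k)
      cols <- paste("kmer", k, present, p, sep = "|")
      mat[cbind(seq_len(n), match(cols, feature_space$name))] <- 1
    }
  }

  if (any(kinds == "composition")) {
    chars <- strsplit(guides$spacer, "", fixed = TRUE)
    for (b in BASES) {
      col <- paste0("comp|", b)
      if (col %in% feature_space$name) {
        mat[, col] <- 100 *
          vapply(chars, function(ch) sum(ch == b), numeric(1)) / SPACER_LEN
      }
    }
  }

  tlen <- transcripts$length[match(guides$source_transcript,
                                   transcripts$transcript_id)]
  if ("relpos" %in% feature_space$name) {
    mat[, "relpos"] <- relative_position_feature(guides$target_start, tlen)
  }

  if ("occ_overlap" %in% feature_space$name) {
    if (is.null(peaks)) {
      peaks <- data.frame(reference_id = character(), start = integer(),
                          end = integer())
    }
    peak_split <- split(peaks[, c("start", "end")], peaks$reference_id)
    no_peaks <- setdiff(unique(guides$source_transcript), names(peak_split))
    if (length(no_peaks)) {
      warning("no occupancy peaks for transcript(s) ",
              paste(no_peaks, collapse = ", "), "; overlap set to 0")
    }
    mat[, "occ_overlap"] <- vapply(seq_len(n), function(i) {
      occupancy_overlap_feature(
        guides$target_start[i], guides$target_end[i],
        peak_split[[guides$source_transcript[i]]])
    }, numeric(1))
  }

  if ("n_hits" %in% feature_space$name) {
    if (is.null(hits)) {
      stop("feature space includes n_hits but no hits were supplied")
    }
    mat[, "n_hits"] <- count_hits(guides, hits)
  }
  mat
}

#' Expand a per-guide feature matrix to guide x replicate rows
#'
#' Replicates of one guide share its sequence, so they share the feature
#' vector; each observation contributes one training row with possibly a
#' different label. This duplication is deliberate: it is exactly what
#' makes the replicate-noise ceiling on accuracy bind.
#'
#' @param features Per-guide feature matrix (rownames = `guide_id`).
#' @param observations Knockdown observation data frame with columns
#'   `guide_id` and `replicate_id`.
#' @return Feature matrix with one row per observation, rownames
#'   `guide_id.replicate_id`, in observation order.
#' @export
expand_to_replicates <- function(features, observations) {
  idx <- match(observations$guide_id, rownames(features))
  if (anyNA(idx)) {
    stop("observation(s) reference guides absent from the feature matrix: ",
         paste(utils::head(observations$guide_id[is.na(idx)], 5L),
               collapse = ", "))
  }
  out <- features[idx, , drop = FALSE]
  rownames(out) <- paste0(observations$guide_id, ".",
                          observations$replicate_id)
  out
}
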
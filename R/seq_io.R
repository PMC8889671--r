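#' Read a reference transcriptome
#'
#' Loads transcript sequences either from a FASTA file or from an
#' annotation table (delimited text with one row per transcript carrying
#' gene/transcript identifiers, symbol, coordinates, strand, length and the
#' full transcript sequence). Sequences are normalized to the uppercase DNA
#' alphabet: lowercase letters are raised and `U` is mapped to `T`, so RNA
#' input is accepted transparently. Records with an empty sequence are
#' dropped with a warning.
#'
#' @param path Path to the input file.
#' @param format `"fasta"` (headers carry the transcript ID as the first
#'   whitespace-delimited token) or `"table"` (tab-delimited with at least
#'   the columns `gene_id`, `transcript_id`, `gene_symbol`, `strand`,
#'   `length`, `sequence`).
#' @return A data frame with columns `transcript_id`, `gene_id`,
#'   `gene_symbol`, `strand`, `length` and `sequence`. Transcript IDs are
#'   unique; `length` always equals `nchar(sequence)`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">T1 demo", "acguACGU"), fa)
#' read_transcriptome(fa)$sequence  # "ACGTACGT"
#' @export
read_transcriptome <- function(path, format = c("fasta", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read transcriptome file: ", path)
  }
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, character(1), 1L)
    if (anyNA(ids) || any(!nzchar(ids))) {
      bad <- which(is.na(ids) | !nzchar(ids))[1L]
      stop("FASTA header without an ID token at entry ", bad)
    }
    df <- data.frame(
      transcript_id = ids,
      gene_id = NA_character_,
      gene_symbol = NA_character_,
      strand = "+",
      length = 0L,
      sequence = as.character(seqs),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    needed <- c("gene_id", "transcript_id", "gene_symbol", "strand",
                "length", "sequence")
    missing <- setdiff(needed, names(tab))
    if (length(missing)) {
      stop("annotation table is missing column(s): ",
           paste(missing, collapse = ", "))
    }
    df <- data.frame(
      transcript_id = as.character(tab$transcript_id),
      gene_id = as.character(tab$gene_id),
      gene_symbol = as.character(tab$gene_symbol),
      strand = as.character(tab$strand),
      length = as.integer(tab$length),
      sequence = as.character(tab$sequence),
      stringsAsFactors = FALSE
    )
  }
  df$sequence <- normalize_sequence(df$sequence)
  bad <- grepl("[^ACGTN]", df$sequence)
  if (any(bad)) {
    stop("sequence with characters outside {A,C,G,T,N,U} in record(s): ",
         paste(df$transcript_id[bad], collapse = ", "))
  }
  if (format == "table") {
    mismatch <- df$length != nchar(df$sequence)
    if (any(mismatch)) {
      stop("declared length differs from sequence length for: ",
           paste(df$transcript_id[mismatch], collapse = ", "))
    }
  }
  empty <- !nzchar(df$sequence)
  if (any(empty)) {
    warning("dropping ", sum(empty), " record(s) with empty sequence: ",
            paste(df$transcript_id[empty], collapse = ", "))
    df <- df[!empty, , drop = FALSE]
  }
  df$length <- nchar(df$sequence)
  if (anyDuplicated(df$transcript_id)) {
    stop("duplicated transcript_id: ",
         paste(unique(df$transcript_id[duplicated(df$transcript_id)]),
               collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

normalize_sequence <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Read protein-occupancy peaks
#'
#' Parses peak intervals in transcript-space coordinates from either BED
#' (0-based half-open) or the macs2 `.xls` dialect (tab-delimited with `#`
#' comment lines and a header row, 1-based inclusive start). All peaks are
#' normalized to 0-based half-open internal coordinates; overlapping peaks
#' are kept as-is (no merging at parse time).
#'
#' @param path Path to the peak file.
#' @param dialect `"bed"` or `"macs2"`.
#' @return A data frame with columns `reference_id`, `start`, `end`
#'   (0-based half-open) and `score` (0 when the file carries none).
#' @export
read_peaks <- function(path, dialect = c("bed", "macs2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("cannot read peak file: ", path)
  }
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (dialect == "macs2" && length(body)) {
    # first non-comment line is the macs2 header row
    body <- body[-1L]
    line_no <- line_no[-1L]
  }
  if (!length(body)) {
    warning("no peaks found in ", path)
    return(data.frame(reference_id = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3L)) {
    stop("peak line with fewer than 3 columns at line ",
         line_no[which(nfield < 3L)[1L]])
  }
  ref <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric peak coordinate at line ",
         line_no[which(is.na(start) | is.na(end))[1L]])
  }
  if (dialect == "macs2") {
    start <- start - 1L  # macs2 .xls starts are 1-based inclusive
  }
  score <- rep(0, length(ref))
  if (dialect == "bed") {
    has5 <- nfield >= 5L
    score[has5] <- suppressWarnings(
      as.numeric(vapply(fields[has5], `[`, character(1), 5L)))
  } else {
    # macs2 .xls: pileup is column 6 when present
    has6 <- nfield >= 6L
    score[has6] <- suppressWarnings(
      as.numeric(vapply(fields[has6], `[`, character(1), 6L)))
  }
  score[is.na(score)] <- 0
  if (any(start < 0L)) {
    stop("negative peak coordinate at line ", line_no[which(start < 0L)[1L]])
  }
  if (any(start >= end)) {
    stop("peak with start >= end (after normalization) at line ",
         line_no[which(start >= end)[1L]])
  }
  data.frame(reference_id = ref, start = start, end = end, score = score,
             stringsAsFactors = FALSE)
}

#' Read a gene-symbol list
#'
#' Accepts plain text (one symbol per line) or comma-separated symbols;
#' both may be mixed. Duplicates are removed keeping the first occurrence.
#'
#' @param path Path to the gene list file.
#' @return Character vector of unique gene symbols in input order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read gene list: ", path)
  }
  raw <- readLines(path)
  symbols <- trimws(unlist(strsplit(raw, ",", fixed = TRUE)))
  symbols <- symbols[nzchar(symbols)]
  unique(symbols)
}

#' Write guide candidates to FASTA
#'
#' Headers encode the source transcript and the 0-based target start as
#' `transcript|start`, and entries are emitted in deterministic order
#' (source transcript, then offset).
#'
#' @param guides Guide data frame from [enumerate_guides()].
#' @param path Output path.
#' @export
write_guide_fasta <- function(guides, path) {
  if (!nrow(guides)) {
    warning("writing empty guide FASTA: ", path)
    cat("", file = path)
    return(invisible(path))
  }
  if (any(nchar(guides$spacer) != 28L)) {
    stop("all spacers must be exactly 28 nt")
  }
  ord <- order(guides$source_transcript, guides$target_start)
  g <- guides[ord, , drop = FALSE]
  out <- Biostrings::BStringSet(g$spacer)
  names(out) <- g$guide_id
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read a guide FASTA written by [write_guide_fasta()]
#'
#' @param path FASTA path with `transcript|start` headers.
#' @return Guide data frame with columns `guide_id`, `spacer`,
#'   `source_transcript`, `target_start`, `target_end`.
#' @export
read_guide_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[`, character(1), 1L)
  parts <- strsplit(ids, "|", fixed = TRUE)
  src <- vapply(parts, function(p) paste(p[-length(p)], collapse = "|"),
                character(1))
  start <- as.integer(vapply(parts, function(p) p[length(p)], character(1)))
  data.frame(
    guide_id = ids,
    spacer = as.character(seqs),
    source_transcript = src,
    target_start = start,
    target_end = start + 28L,
    stringsAsFactors = FALSE
  )
}

#' Write a training table
#'
#' Serializes a feature matrix plus its response column as tab-delimited
#' text: a header row of feature names, one row per guide x replicate, and
#' the response (normalized expression or class label) as the final column.
#'
#' @param features Numeric matrix (rows = guide x replicate observations,
#'   columns named by feature).
#' @param response Numeric or integer vector, one value per row.
#' @param path Output path.
#' @param row_ids Optional row identifiers written as a leading `row_id`
#'   column (defaults to `rownames(features)`).
#' @param response_name Name of the final column.
#' @export
write_training_table <- function(features, response, path,
                                 row_ids = rownames(features),
                                 response_name = "expression") {
  stopifnot(nrow(features) == length(response))
  df <- as.data.frame(features, check.names = FALSE)
  df[[response_name]] <- response
  if (!is.null(row_ids)) {
    df <- cbind(data.frame(row_id = row_ids, stringsAsFactors = FALSE), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a training table written by [write_training_table()]
#'
#' @param path Path to the tab-delimited training table.
#' @param response_name Name of the response column (last column by
#'   convention).
#' @return List with `features` (numeric matrix), `response` (numeric
#'   vector) and `row_ids` (character or `NULL`).
#' @export
read_training_table <- function(path, response_name = "expression") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!response_name %in% names(df)) {
    stop("training table is missing the response column '", response_name,
         "'")
  }
  row_ids <- NULL
  if ("row_id" %in% names(df)) {
    row_ids <- as.character(df$row_id)
    df$row_id <- NULL
  }
  response <- df[[response_name]]
  df[[response_name]] <- NULL
  features <- as.matrix(df)
  if (!is.numeric(features)) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  }
  rownames(features) <- row_ids
  list(features = features, response = response, row_ids = row_ids)
}
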
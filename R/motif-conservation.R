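AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

validate_sequences <- function(seqs, allow_gaps = FALSE) {
  if (!is.data.frame(seqs) || !all(c("id", "sequence") %in% names(seqs))) {
    abort("sequences must be a data frame with columns `id` and `sequence`",
          class = "rck_usage_error")
  }
  if (nrow(seqs) == 0L || any(!nzchar(seqs$sequence))) {
    abort("empty sequence(s) present", class = "rck_validation_error")
  }
  ok <- c(AA_ALPHABET, if (allow_gaps) "-")
  for (i in seq_len(nrow(seqs))) {
    chars <- unique(strsplit(toupper(seqs$sequence[i]), "")[[1]])
    bad <- setdiff(chars, ok)
    if (length(bad) > 0L) {
      abort(paste0("invalid character(s) in sequence '", seqs$id[i], "': ",
                   paste(bad, collapse = " ")),
            class = "rck_validation_error")
    }
  }
  invisible(seqs)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Tibble with columns `id`, `sequence` (upper case).
#' @export
read_sequences <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           set.attributes = FALSE)
  tibble(id = names(fa), sequence = toupper(unname(unlist(fa))))
}

#' Read a protein multiple alignment (aligned FASTA or Clustal)
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return Tibble with columns `id`, `sequence` (gapped, `-` as the gap
#'   character), all rows equal length.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- seqinr::read.alignment(path, format = format, forceToLower = FALSE)
  out <- tibble(id = aln$nam,
                sequence = toupper(gsub("[.]", "-", unlist(aln$seq))))
  check_alignment(out)
}

check_alignment <- function(aln) {
  validate_sequences(aln, allow_gaps = TRUE)
  lens <- nchar(aln$sequence)
  if (length(unique(lens)) != 1L) {
    abort("alignment rows differ in length", class = "rck_validation_error")
  }
  aln
}

alignment_ncol <- function(aln) nchar(aln$sequence[1L])

#' Scan for the Rossmann-fold nucleotide-binding motif
#'
#' Finds all non-overlapping matches of the glycine-rich nucleotide-binding
#' motif `G-x-G-x-x-G` followed by a spacer of 17–18 arbitrary residues and
#' an acidic residue (E or D) — the pattern written GxGxxG\[17-18\]xE/D.
#' Matching is leftmost-first with the shorter spacer preferred when both
#' lengths match at one start.
#'
#' @param seqs Data frame with columns `id` and `sequence` (ungapped), or a
#'   character vector of sequences (names used as ids).
#' @param spacer_range Integer length-2: admissible spacer lengths
#'   (default `c(17, 18)`).
#' @return Tibble with one row per hit: `id`, `start`, `end` (1-based,
#'   inclusive), `spacer_length` and `acidic_residue`.
#' @export
scan_nbs_motif <- function(seqs, spacer_range = c(17L, 18L)) {
  if (is.character(seqs)) {
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- tibble(id = ids, sequence = unname(seqs))
  }
  validate_sequences(seqs)
  spacer_range <- sort(as.integer(spacer_range))
  pattern <- sprintf("G[A-Z]G[A-Z]{2}G[A-Z]{%d,%d}?[ED]",
                     spacer_range[1], spacer_range[2])
  purrr::pmap_dfr(seqs[, c("id", "sequence")], function(id, sequence) {
    sequence <- toupper(sequence)
    m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) return(tibble())
    start <- as.integer(m)
    len <- attr(m, "match.length")
    tibble(id = id, start = start, end = start + len - 1L,
           spacer_length = len - 7L,
           acidic_residue = substring(sequence, start + len - 1L,
                                      start + len - 1L))
  })
}

#' Map an ungapped reference position to its alignment column
#'
#' @param aln Alignment tibble (`id`, gapped `sequence`).
#' @param reference_id Row whose (author) numbering defines positions.
#' @param position 1-based ungapped position in the reference sequence.
#' @return 1-based alignment column holding that reference residue.
#' @seealso [map_alignment_column()] for the inverse mapping.
#' @export
map_reference_position <- function(aln, reference_id, position) {
  aln <- check_alignment(aln)
  row <- aln$sequence[aln$id == reference_id]
  if (length(row) != 1L) {
    abort(paste0("reference row '", reference_id, "' not found (or duplicated)"),
          class = "rck_usage_error")
  }
  chars <- strsplit(row, "")[[1]]
  ungapped <- cumsum(chars != "-")
  if (position < 1L || position > max(ungapped)) {
    abort(sprintf("position %d is beyond the reference length (%d residues)",
                  position, max(ungapped)), class = "rck_usage_error")
  }
  which(ungapped == position & chars != "-")[1L]
}

#' Map an alignment column to the ungapped reference position
#'
#' @inheritParams map_reference_position
#' @param column 1-based alignment column.
#' @return 1-based ungapped position in the reference row, or `NA` when the
#'   reference has a gap in that column.
#' @export
map_alignment_column <- function(aln, reference_id, column) {
  aln <- check_alignment(aln)
  row <- aln$sequence[aln$id == reference_id]
  if (length(row) != 1L) {
    abort(paste0("reference row '", reference_id, "' not found (or duplicated)"),
          class = "rck_usage_error")
  }
  chars <- strsplit(row, "")[[1]]
  if (column < 1L || column > length(chars)) {
    abort(sprintf("column %d out of range [1, %d]", column, length(chars)),
          class = "rck_usage_error")
  }
  if (chars[column] == "-") return(NA_integer_)
  sum(chars[seq_len(column)] != "-")
}

#' Residue conservation at one alignment column
#'
#' Counts every row's residue at the column (gaps counted as gaps, never as
#' matches) and reports the percent of rows carrying a residue from
#' `target_residues`, rounded half away from zero to an integer percent
#' (13 of 15 rows = 86.7 -> 87).
#'
#' @param aln Alignment tibble.
#' @param column 1-based alignment column.
#' @param target_residues Residues counted as conserved (default `"E"`,
#'   matching a glutamate-conservation question; use `c("E", "D")` to widen
#'   to acidic).
#' @return One-row tibble: `column`, `n_rows`, `target` (collapsed set),
#'   `target_count`, `percent_identity` (integer), `gap_count`, and a
#'   `counts` list-column with the full residue frequency table.
#' @export
column_conservation <- function(aln, column, target_residues = "E") {
  aln <- check_alignment(aln)
  nc <- alignment_ncol(aln)
  if (column < 1L || column > nc) {
    abort(sprintf("column %d out of range [1, %d]", column, nc),
          class = "rck_usage_error")
  }
  res <- toupper(substring(aln$sequence, column, column))
  counts <- table(res)
  target_count <- sum(res %in% toupper(target_residues))
  tibble(
    column = as.integer(column),
    n_rows = nrow(aln),
    target = paste(target_residues, collapse = ""),
    target_count = target_count,
    percent_identity = as.integer(round_half_up(100 * target_count / nrow(aln))),
    gap_count = sum(res == "-"),
    counts = list(tibble(residue = names(counts), n = as.integer(counts)))
  )
}

#' Two-residue context motif at an alignment column
#'
#' Tabulates the (column-1, column) residue pairs across rows — e.g. the PE
#' motif formed by a conserved proline preceding the interface glutamate.
#' Rows with a gap at either column are counted under motifs containing
#' `-`; frequencies sum to the number of rows.
#'
#' @inheritParams column_conservation
#' @return Tibble with columns `motif`, `n`, `has_gap`, sorted by
#'   descending `n`.
#' @export
context_motif <- function(aln, column) {
  aln <- check_alignment(aln)
  if (column < 2L) {
    abort("`column` must be at least 2 to have a left neighbour",
          class = "rck_usage_error")
  }
  if (column > alignment_ncol(aln)) {
    abort("`column` out of range", class = "rck_usage_error")
  }
  motifs <- paste0(toupper(substring(aln$sequence, column - 1L, column - 1L)),
                   toupper(substring(aln$sequence, column, column)))
  counts <- table(motifs)
  tibble(motif = names(counts), n = as.integer(counts)) %>%
    mutate(has_gap = grepl("-", .data$motif, fixed = TRUE)) %>%
    arrange(dplyr::desc(.data$n), .data$motif)
}

#' Classify Kef-family sequences by length
#'
#' Kef K+/H+ antiporter sequences split into full-length KefC proteins
#' (at least 580 residues) and the shorter KefC-like group (fewer than 580).
#'
#' @param seqs Data frame with `id`, `sequence`, or character vector.
#' @param threshold Length threshold (default 580).
#' @return Tibble with columns `id`, `length`, `family`.
#' @export
classify_kef_family <- function(seqs, threshold = 580L) {
  if (is.character(seqs)) {
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- tibble(id = ids, sequence = unname(seqs))
  }
  validate_sequences(seqs)
  seqs %>%
    mutate(length = nchar(.data$sequence),
           family = ifelse(.data$length >= threshold, "KefC", "KefC-like")) %>%
    select("id", "length", "family")
}

#' Write an alignment as aligned FASTA
#'
#' @param aln Alignment tibble (`id`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", aln$id), aln$sequence))
  writeLines(lines, path)
  invisible(path)
}
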
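# Simple sequence repeat (microsatellite) detection and aligned-sequence
# mismatch counting. Coordinates are 1-based inclusive throughout, the
# convention used when reporting marker loci.

VALID_BASES <- c("A", "C", "G", "T", "N", "-")

#' Scan a sequence for simple sequence repeats
#'
#' Finds maximal tandem repetitions of 1-6 nt motifs in a nucleotide
#' sequence. A hit is a run of `repeat_count` exact copies of a motif
#' that cannot be extended by a further full or partial copy on either
#' side; the reported `end` covers whole copies only, so
#' `end - start + 1 == nchar(motif) * repeat_count` always holds.
#' Motifs are reported as found in the sequence (e.g. "CT" at its run
#' start, not a rotated or complemented canonical form) unless
#' `canonical = TRUE`, which rotates each motif to its
#' lexicographically smallest form. Runs whose repeated unit is itself
#' periodic (e.g. "ACAC" as a 4-mer) are reported only at their
#' shortest period, and when two runs of different unit length overlap
#' the longer run (more bases) wins. Ambiguous bases (`N`) and
#' alignment gaps (`-`) never participate in a hit.
#'
#' @param seq A single character string over A/C/G/T/N/-, or an object
#'   coercible to one (e.g. a `Biostrings::DNAString`).
#' @param min_unit,max_unit Smallest and largest motif length to
#'   report, within 1-6.
#' @param min_repeats Integer vector of minimum repeat counts indexed
#'   by motif length (positions `min_unit:max_unit` are used). The
#'   default requires 8 copies for mononucleotide runs, 5 for
#'   dinucleotides and 4 for longer motifs, a conventional
#'   microsatellite search setting.
#' @param canonical Rotate motifs to canonical form?
#' @return Data frame with columns `motif`, `repeat_count`, `start`,
#'   `end` (1-based inclusive), ordered by `start`. Zero rows when
#'   nothing qualifies.
#' @examples
#' scan_ssrs("ACACACAC", min_repeats = c(8, 3))
#' @export
scan_ssrs <- function(seq, min_unit = 1L, max_unit = 6L,
                      min_repeats = c(8L, 5L, 4L, 4L, 4L, 4L),
                      canonical = FALSE) {
  s <- toupper(as.character(seq))
  stopifnot(length(s) == 1L)
  stopifnot(min_unit >= 1L, max_unit <= 6L, min_unit <= max_unit)
  if (length(min_repeats) < max_unit) {
    min_repeats <- rep_len(min_repeats, max_unit)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(chars), VALID_BASES)
  if (length(bad)) {
    stop("invalid symbols in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(chars)
  usable <- chars %in% c("A", "C", "G", "T")

  hits <- list()
  for (u in min_unit:max_unit) {
    if (n < 2L * u) next
    # positions where the base u ahead repeats it, both unambiguous
    eq <- chars[seq_len(n - u)] == chars[(u + 1L):n] &
      usable[seq_len(n - u)] & usable[(u + 1L):n]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      run_start <- pos[k]
      span <- r$lengths[k] + u          # bases covered by the full run
      count <- span %/% u
      if (count < min_repeats[u]) next
      motif <- paste(chars[run_start:(run_start + u - 1L)], collapse = "")
      if (motif_period(motif) < u) next  # shorter period reports it
      hits[[length(hits) + 1L]] <- data.frame(
        motif = motif, repeat_count = count, start = run_start,
        end = run_start + u * count - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(), repeat_count = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)

  # overlap suppression: keep the longer run (ties: earlier start, then
  # shorter unit)
  out <- out[order(-(out$end - out$start + 1L), out$start,
                   nchar(out$motif)), , drop = FALSE]
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ov <- keep & !(out$end[i] < out$start | out$start[i] > out$end)
    keep[i] <- !any(ov)
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  if (canonical) {
    out$motif <- vapply(out$motif, canonical_rotation, character(1))
  }
  rownames(out) <- NULL
  out
}

# smallest period of a motif string (e.g. "ACAC" -> 2, "ACG" -> 3)
motif_period <- function(motif) {
  m <- strsplit(motif, "", fixed = TRUE)[[1]]
  u <- length(m)
  for (p in seq_len(u - 1L)) {
    if (u %% p == 0L && all(m == rep_len(m[seq_len(p)], u))) return(p)
  }
  u
}

# lexicographically smallest rotation
canonical_rotation <- function(motif) {
  m <- strsplit(motif, "", fixed = TRUE)[[1]]
  rots <- vapply(seq_along(m), function(i) {
    paste(c(m[i:length(m)], m[seq_len(i - 1L)][i > 1]), collapse = "")
  }, character(1))
  min(rots)
}

#' Scan a set of sequences for SSRs
#'
#' Applies [scan_ssrs()] to each element of a named character vector or
#' `Biostrings::DNAStringSet`, returning one combined table. Each
#' sequence is scanned independently, so results do not depend on the
#' batch composition or order.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @inheritParams scan_ssrs
#' @return Data frame as in [scan_ssrs()] with an extra leading column
#'   `seq_id`.
#' @export
scan_ssrs_set <- function(seqs, min_unit = 1L, max_unit = 6L,
                          min_repeats = c(8L, 5L, 4L, 4L, 4L, 4L),
                          canonical = FALSE) {
  v <- as.character(seqs)
  if (is.null(names(v))) names(v) <- paste0("seq", seq_along(v))
  res <- lapply(names(v), function(id) {
    h <- scan_ssrs(v[[id]], min_unit, max_unit, min_repeats, canonical)
    if (nrow(h)) cbind(seq_id = id, h, stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(seq_id = character(), motif = character(),
                      repeat_count = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-sequence mismatches against a majority-rule consensus
#'
#' For a gapped multiple alignment, builds the column-wise majority
#' consensus over unambiguous bases (A/C/G/T) and counts, for each
#' sequence, the columns at which it differs from that consensus.
#' Gaps and `N` never form or match the consensus, so a sequence
#' carrying a gap where the consensus is a base scores a mismatch —
#' the most conservative reading of a "nucleotide mismatch
#' difference". Columns with no unique majority base (ties, or all
#' gaps) are excluded from counting for every sequence.
#'
#' @param aligned Named character vector or `Biostrings::DNAStringSet`
#'   of >= 2 aligned sequences of equal length (gaps as `-`).
#' @return Named integer vector of mismatch counts, one per sequence,
#'   with attribute `"consensus"` (the consensus string, tie/undefined
#'   columns as `.`) and `"columns_scored"` (number of columns with a
#'   defined consensus).
#' @export
consensus_mismatches <- function(aligned) {
  v <- toupper(as.character(aligned))
  if (length(v) < 2L) stop("need at least 2 aligned sequences",
                           call. = FALSE)
  if (is.null(names(v))) names(v) <- paste0("seq", seq_along(v))
  lens <- nchar(v)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(v, "", fixed = TRUE))
  bad <- setdiff(unique(c(mat)), VALID_BASES)
  if (length(bad)) {
    stop("invalid symbols in alignment: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ncol_aln <- ncol(mat)
  consensus <- character(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- mat[, j]
    tab <- table(factor(col[col %in% c("A", "C", "G", "T")],
                        levels = c("A", "C", "G", "T")))
    mx <- max(tab)
    winners <- names(tab)[tab == mx]
    consensus[j] <- if (mx > 0L && length(winners) == 1L) winners else "."
  }
  scored <- consensus != "."
  counts <- vapply(seq_len(nrow(mat)), function(i) {
    sum(mat[i, scored] != consensus[scored])
  }, integer(1))
  names(counts) <- names(v)
  attr(counts, "consensus") <- paste(consensus, collapse = "")
  attr(counts, "columns_scored") <- sum(scored)
  counts
}

#' Check an amplicon length against its expected size range
#'
#' @param product_length Observed band/product length, bp (> 0).
#' @param expected_min,expected_max Inclusive expected size range, bp.
#' @return Logical: `TRUE` when the product lies within the range.
#' @export
band_size_check <- function(product_length, expected_min, expected_max) {
  stopifnot(is.numeric(product_length), is.numeric(expected_min),
            is.numeric(expected_max))
  if (any(product_length <= 0) || any(expected_min <= 0)) {
    stop("lengths must be positive", call. = FALSE)
  }
  if (any(expected_max < expected_min)) {
    stop("inverted expected range", call. = FALSE)
  }
  product_length >= expected_min & product_length <= expected_max
}

#' Write SSR hits as GFF3
#'
#' Serialises a hit table from [scan_ssrs_set()] to GFF3 with 1-based
#' inclusive coordinates (the native GFF convention).
#'
#' @param hits Data frame with columns `seq_id`, `motif`,
#'   `repeat_count`, `start`, `end`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ssr_gff3 <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  lines <- c("##gff-version 3",
             sprintf("%s\tisofix\tmicrosatellite\t%d\t%d\t.\t+\t.\tmotif=%s;repeats=%d",
                     hits$seq_id, hits$start, hits$end, hits$motif,
                     hits$repeat_count))
  writeLines(lines, path)
  invisible(path)
}
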
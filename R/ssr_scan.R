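#' Default minimum repeat counts per motif class
#'
#' At least six repeats for dinucleotides and five for tri- to
#' hexanucleotides, the standard genome-wide SSR mining thresholds.
#'
#' @return Named integer vector over motif classes.
#' @export
default_min_repeats <- function() {
  c(di = 6L, tri = 5L, tetra = 5L, penta = 5L, hexa = 5L)
}

empty_ssr_frame <- function() {
  data.frame(
    seq_id = character(), start = integer(), end = integer(),
    motif = character(), motif_class = character(),
    repeat_count = integer(), tract_bp = integer(),
    length_class = character(), stringsAsFactors = FALSE
  )
}

#' Detect perfect SSR tracts in a single sequence
#'
#' Scans one nucleotide sequence for maximal, non-extendable perfect
#' microsatellite tracts of period 2-6 (no mismatches, no compound repeats).
#' A tract is emitted once, under the canonical form of its shortest primitive
#' repeat unit, when it reaches the minimum repeat count for its motif class.
#' Ambiguity characters (N or any non-ACGT) terminate tracts and never match.
#' Coordinates are 1-based inclusive.
#'
#' @param sequence Character scalar, or a `Biostrings::DNAString`.
#' @param seq_id Identifier recorded in the `seq_id` column.
#' @param min_repeats Named vector of minimum repeat counts per motif class;
#'   see [default_min_repeats()].
#' @return data.frame with columns seq_id, start, end, motif, motif_class,
#'   repeat_count, tract_bp, length_class, sorted by start.
#' @export
find_perfect_ssrs <- function(sequence, seq_id = "seq",
                              min_repeats = default_min_repeats()) {
  if (methods::is(sequence, "XString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("sequence must be a single character string or DNAString")
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) return(empty_ssr_frame())
  x <- strsplit(sequence, "", fixed = TRUE)[[1]]
  valid <- x %in% c("A", "C", "G", "T")

  rows <- list()
  for (p in 2:6) {
    cls <- motif_class_name(p)
    minrep <- as.integer(min_repeats[[cls]])
    if (n < p * minrep) next
    m <- n - p
    eq <- x[seq_len(m)] == x[(p + 1L):n] & valid[seq_len(m)] & valid[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths + p >= p * minrep)
    for (j in keep) {
      i <- starts[j]
      count <- (r$lengths[j] + p) %/% p
      if (count < minrep) next
      unit <- substr(sequence, i, i + p - 1L)
      if (primitive_period(unit) != p) next # shorter-period tract, or homopolymer
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, start = i, end = i + count * p - 1L,
        motif = canonical_motif(unit), motif_class = cls,
        repeat_count = count, tract_bp = count * p,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_ssr_frame())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  out$length_class <- classify_length(out$tract_bp)
  rownames(out) <- NULL
  out
}

#' Mine SSRs across a multi-record genome
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet`.
#' @param min_repeats See [find_perfect_ssrs()].
#' @return Combined SSR catalog data.frame over all records.
#' @export
ssr_catalog <- function(genome, min_repeats = default_min_repeats()) {
  if (methods::is(genome, "XStringSet")) {
    ids <- names(genome)
    genome <- as.character(genome)
    names(genome) <- ids
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome records must be named")
  }
  out <- lapply(names(genome), function(id) {
    find_perfect_ssrs(genome[[id]], seq_id = id, min_repeats = min_repeats)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify SSR tract length into hypervariable/variable classes
#'
#' Class I (hypervariable) tracts are >= 20 bp; class II (potentially
#' variable) tracts are 12-19 bp; shorter tracts are "below". The two classes
#' partition every tract the miner emits.
#'
#' @param tract_bp Integer vector of tract lengths in bp.
#' @return Character vector: "classI", "classII" or "below".
#' @export
classify_length <- function(tract_bp) {
  ifelse(tract_bp >= 20L, "classI", ifelse(tract_bp >= 12L, "classII", "below"))
}

#' Write an SSR catalog as TSV (1-based inclusive coordinates)
#'
#' @param ssrs SSR catalog data.frame.
#' @param path Output file path.
#' @export
write_ssr_tsv <- function(ssrs, path) {
  write.table(ssrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Format SSR loci as GFF3 feature lines
#'
#' @param ssrs SSR catalog data.frame.
#' @param source Value for the GFF3 source column.
#' @return Character vector of GFF3 lines (type "microsatellite").
#' @export
ssr_gff3_lines <- function(ssrs, source = "ssrqtl") {
  if (nrow(ssrs) == 0L) return(character())
  attrs <- sprintf(
    "ID=ssr%06d;motif=%s;repeat_count=%d;length_class=%s",
    seq_len(nrow(ssrs)), ssrs$motif, ssrs$repeat_count, ssrs$length_class
  )
  paste(ssrs$seq_id, source, "microsatellite", ssrs$start, ssrs$end,
        ".", "+", ".", attrs, sep = "\t")
}
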
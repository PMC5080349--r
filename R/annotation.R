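#' Validate a gene-model segment table
#'
#' Gene models are held as a plain segment table: one row per feature
#' segment with columns `gene_id`, `seq_id`, `strand` ("+"/"-"), `type`
#' (gene, CDS, five_prime_UTR, three_prime_UTR, intron) and 1-based
#' inclusive `start`, `end`. Every gene must have a `gene` row spanning all
#' its segments.
#'
#' @param models Segment data.frame as described above.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_gene_models <- function(models) {
  need <- c("gene_id", "seq_id", "strand", "type", "start", "end")
  miss <- setdiff(need, names(models))
  if (length(miss)) stop("gene model table lacks columns: ", paste(miss, collapse = ", "))
  if (any(models$end < models$start)) stop("gene model segment with end < start")
  for (g in unique(models$gene_id)) {
    rows <- models[models$gene_id == g, , drop = FALSE]
    span <- rows[rows$type == "gene", , drop = FALSE]
    if (nrow(span) != 1L) stop("gene ", g, " must have exactly one 'gene' row")
    segs <- rows[rows$type != "gene", , drop = FALSE]
    if (nrow(segs) && (any(segs$start < span$start) || any(segs$end > span$end))) {
      stop("gene ", g, " has segments outside its gene span")
    }
  }
  invisible(models)
}

# GRanges of one feature type, URR derived strand-aware from gene spans
context_ranges <- function(models, type, urr_len) {
  if (type == "URR") {
    g <- models[models$type == "gene", , drop = FALSE]
    if (nrow(g) == 0L) return(GenomicRanges::GRanges())
    start <- ifelse(g$strand == "+", pmax(1L, g$start - urr_len), g$end + 1L)
    end <- ifelse(g$strand == "+", g$start - 1L, g$end + urr_len)
    keep <- end >= start
    g <- g[keep, , drop = FALSE]
    start <- start[keep]; end <- end[keep]
    if (nrow(g) == 0L) return(GenomicRanges::GRanges())
    return(GenomicRanges::GRanges(g$seq_id, IRanges::IRanges(start, end)))
  }
  types <- switch(type,
    CDS = "CDS",
    UTR = c("five_prime_UTR", "three_prime_UTR"),
    intron = "intron",
    stop("unknown context type ", type)
  )
  m <- models[models$type %in% types, , drop = FALSE]
  if (nrow(m) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(m$seq_id, IRanges::IRanges(m$start, m$end))
}

#' Genic context of genomic intervals
#'
#' Assigns each interval the highest-priority overlapping feature context,
#' with priority CDS > UTR > intron > URR (upstream regulatory region) >
#' intergenic; overlap means at least one shared base. The URR is a window
#' of `urr_len` bp upstream of the transcription start, strand-aware.
#'
#' @param intervals data.frame with seq_id, start, end (1-based inclusive).
#' @param models Gene-model segment table (see [validate_gene_models()]).
#' @param urr_len URR length in bp upstream of the gene start (default 2000).
#' @return Character vector, one context label per interval.
#' @export
feature_context <- function(intervals, models, urr_len = 2000L) {
  validate_gene_models(models)
  n <- nrow(intervals)
  out <- rep("intergenic", n)
  if (n == 0L) return(character())
  q <- GenomicRanges::GRanges(intervals$seq_id,
                              IRanges::IRanges(intervals$start, intervals$end))
  for (type in c("URR", "intron", "UTR", "CDS")) { # ascending priority
    subj <- context_ranges(models, type, urr_len)
    if (length(subj) == 0L) next
    hit <- GenomicRanges::countOverlaps(q, subj) > 0L
    out[hit] <- type
  }
  out
}

#' Reading-frame effect of a coding-region SSR length polymorphism
#'
#' A repeat-length difference inside a CDS shifts the reading frame unless
#' the length change is a multiple of 3. The call depends only on the
#' pairwise tract-length differences modulo 3 across accessions.
#'
#' @param tracts Numeric vector of per-accession tract lengths in bp (NA =
#'   absent accession).
#' @return "frameshift", "in_frame_indel" or "monomorphic".
#' @export
cds_frame_effect <- function(tracts) {
  obs <- unique(tracts[!is.na(tracts)])
  if (length(obs) < 2L) return("monomorphic")
  if (length(unique(obs %% 3L)) == 1L) "in_frame_indel" else "frameshift"
}

#' Default cis-regulatory motif set
#'
#' Two plant cis-regulatory elements with literal consensus sequences:
#' RAV1AAT (CAACA) and CARGCW8GAT (CATAATTATG).
#'
#' @return data.frame with columns name, consensus.
#' @export
default_motifs <- function() {
  data.frame(
    name = c("RAV1AAT", "CARGCW8GAT"),
    consensus = c("CAACA", "CATAATTATG"),
    stringsAsFactors = FALSE
  )
}

# all exact occurrences (start positions) of word in sequence restricted to
# those overlapping position pos
occurrences_over <- function(sequence, word, pos) {
  L <- nchar(word)
  from <- max(1L, pos - L + 1L)
  to <- min(nchar(sequence), pos + L - 1L)
  region <- substr(sequence, from, to)
  hits <- gregexpr(word, region, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer())
  starts <- as.integer(hits) + from - 1L
  starts[starts <= pos & starts + L - 1L >= pos]
}

#' Cis-regulatory motif disruption (or creation) by a SNP
#'
#' Scans for exact occurrences of each motif consensus, on both strands,
#' overlapping a SNP position, and reports occurrences destroyed by the
#' alternate base (effect "disrupted") as well as occurrences that only
#' exist with the alternate base (effect "created").
#'
#' @param pos SNP position (1-based) in `sequence`.
#' @param ref_base,alt_base Reference and alternate bases (single
#'   characters); `ref_base` must match the sequence at `pos`.
#' @param sequence Nucleotide sequence (character scalar).
#' @param motifs data.frame(name, consensus); default [default_motifs()].
#' @return data.frame: name, start, end, strand, ref_word, alt_word, effect.
#' @export
scan_motif_disruption <- function(pos, ref_base, alt_base, sequence,
                                  motifs = default_motifs()) {
  if (methods::is(sequence, "XString")) sequence <- as.character(sequence)
  if (pos < 1L || pos > nchar(sequence)) stop("SNP position outside sequence")
  if (substr(sequence, pos, pos) != ref_base) {
    stop("ref_base '", ref_base, "' does not match sequence at position ", pos)
  }
  if (any(nchar(motifs$consensus) < 4L)) stop("motif consensus must be >= 4 bp")
  alt_seq <- sequence
  substr(alt_seq, pos, pos) <- alt_base
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    for (strand in c("+", "-")) {
      word <- if (strand == "+") motifs$consensus[i] else revcomp_chr(motifs$consensus[i])
      L <- nchar(word)
      ref_hits <- occurrences_over(sequence, word, pos)
      alt_hits <- occurrences_over(alt_seq, word, pos)
      for (s in setdiff(ref_hits, alt_hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = motifs$name[i], start = s, end = s + L - 1L, strand = strand,
          ref_word = substr(sequence, s, s + L - 1L),
          alt_word = substr(alt_seq, s, s + L - 1L),
          effect = "disrupted", stringsAsFactors = FALSE
        )
      }
      for (s in setdiff(alt_hits, ref_hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = motifs$name[i], start = s, end = s + L - 1L, strand = strand,
          ref_word = substr(sequence, s, s + L - 1L),
          alt_word = substr(alt_seq, s, s + L - 1L),
          effect = "created", stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(name = character(), start = integer(), end = integer(),
                      strand = character(), ref_word = character(),
                      alt_word = character(), effect = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$name, out$strand), , drop = FALSE]
}
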
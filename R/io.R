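#' Read a multi-record FASTA genome
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x)) # first token of the header
  out
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a gene-model segment table as GFF3
#'
#' @param models Segment table (see [validate_gene_models()]).
#' @param path Output file.
#' @export
write_gene_models_gff3 <- function(models, path) {
  validate_gene_models(models)
  lines <- c("##gff-version 3", paste(
    models$seq_id, "ssrqtl", models$type, models$start, models$end, ".",
    models$strand, ".",
    ifelse(models$type == "gene", paste0("ID=", models$gene_id),
           paste0("Parent=", models$gene_id)),
    sep = "\t"
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file into the segment-table layout
#'
#' Uses rtracklayer for parsing; gene/CDS/UTR/intron records are kept. When
#' intron rows are absent they are derived per gene as the gaps between
#' exon (or CDS/UTR) segments inside the gene span.
#'
#' @param path GFF3 file.
#' @return Gene-model segment data.frame.
#' @export
read_gene_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in%
    c("gene", "CDS", "five_prime_UTR", "three_prime_UTR", "intron")
  gr <- gr[keep]
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  gene_id <- ifelse(as.character(gr$type) == "gene",
                    as.character(gr$ID), parent)
  models <- data.frame(
    gene_id = gene_id,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!any(models$type == "intron")) {
    introns <- list()
    for (g in unique(models$gene_id)) {
      rows <- models[models$gene_id == g, , drop = FALSE]
      segs <- rows[rows$type != "gene", , drop = FALSE]
      if (nrow(segs) < 2L) next
      segs <- segs[order(segs$start), , drop = FALSE]
      gaps_from <- head(segs$end, -1L) + 1L
      gaps_to <- tail(segs$start, -1L) - 1L
      ok <- gaps_to >= gaps_from
      if (!any(ok)) next
      introns[[g]] <- data.frame(
        gene_id = g, seq_id = rows$seq_id[1], strand = rows$strand[1],
        type = "intron", start = gaps_from[ok], end = gaps_to[ok],
        stringsAsFactors = FALSE
      )
    }
    if (length(introns)) models <- rbind(models, do.call(rbind, introns))
  }
  rownames(models) <- NULL
  validate_gene_models(models)
  models
}

#' Plot a delta-index window profile
#'
#' Mean delta per sliding window along the chromosome with the interpolated
#' null bounds and any called QTL intervals.
#'
#' @param profile Window profile from [window_profile()].
#' @param ci Optional [null_ci()] table (bounds drawn at each window's mean
#'   depth).
#' @param intervals Optional intervals from [call_qtl_intervals()].
#' @param level Confidence level for the drawn bounds.
#' @param main Plot title.
#' @export
plot_delta_profile <- function(profile, ci = NULL, intervals = NULL,
                               level = 0.99, main = "delta (SNP/SSR-index)") {
  mid <- (profile$window_start + profile$window_end) / 2 / 1e6
  plot(mid, profile$mean_delta, type = "l", ylim = c(-1, 1),
       xlab = "position (Mb)", ylab = expression(Delta ~ "(SNP/SSR-index)"),
       main = main)
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(ci)) {
    ok <- !is.na(profile$mean_depth)
    b <- ci_bounds_at_depth(ci, profile$mean_depth[ok], level)
    graphics::lines(mid[ok], b$upper, lty = 2, col = "firebrick")
    graphics::lines(mid[ok], b$lower, lty = 2, col = "firebrick")
  }
  if (!is.null(intervals) && nrow(intervals)) {
    graphics::rect(intervals$start / 1e6, -1, intervals$end / 1e6, 1,
                   col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  }
  invisible(NULL)
}
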
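# half-up rounding at the printed precision (R's round() is banker's)
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Percentage at the printed precision
#'
#' count/total as a percentage, half-up rounded to one decimal (the printed
#' convention of the report tables); zero totals give 0 instead of an error.
#'
#' @param count Numerator count(s).
#' @param total Denominator total.
#' @return Percentage rounded to 1 decimal.
#' @examples
#' percent_of(3318, 6244)  # 53.1
#' @export
percent_of <- function(count, total) {
  if (length(total) == 1L && total == 0) return(rep(0, length(count)))
  round_half_up(100 * count / total, 1L)
}

pct1 <- percent_of

#' Genetic-map summary arithmetic
#'
#' Per linkage group and overall: marker count, map length (max cM -
#' min cM) and mean inter-marker distance. The mean inter-marker distance
#' divides map length by the marker count (the convention under which a
#' 2060.183 cM map with 3791 markers gives 0.543 cM), rounded to 3
#' decimals.
#'
#' @param map data.frame with columns marker_id, lg, cM (unique marker ids,
#'   non-negative positions).
#' @return list(per_lg, total): per-LG data.frame and overall summary.
#' @export
map_summary <- function(map) {
  need <- c("marker_id", "lg", "cM")
  if (!all(need %in% names(map))) {
    stop("map needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(map$marker_id)) stop("marker ids must be unique")
  if (any(map$cM < 0)) stop("cM positions must be non-negative")
  lgs <- unique(map$lg)
  per <- do.call(rbind, lapply(lgs, function(g) {
    cm <- map$cM[map$lg == g]
    len <- max(cm) - min(cm)
    if (length(cm) == 1L) {
      warning("linkage group ", g, " has a single marker; length 0")
    }
    data.frame(lg = g, n_markers = length(cm), length_cM = len,
               mean_interval_cM = round_half_up(len / length(cm), 3L),
               stringsAsFactors = FALSE)
  }))
  total_len <- sum(per$length_cM)
  total_n <- sum(per$n_markers)
  list(
    per_lg = per,
    total = list(n_markers = total_n, length_cM = total_len,
                 mean_interval_cM = round_half_up(total_len / total_n, 3L))
  )
}

count_pct_table <- function(values, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(values))
  counts <- table(factor(values, levels = levels))
  data.frame(
    group = levels, n = as.integer(counts),
    pct = pct1(as.integer(counts), length(values)),
    stringsAsFactors = FALSE
  )
}

#' Marker summary percentage tables
#'
#' Builds the descriptive tables for a marker set: length-class (class
#' I/II) counts and percentages, motif-class distribution, genic-context
#' distribution, frameshift vs in-frame percentages among CDS markers, and
#' within/between-population polymorphism counts with percentages of the
#' total marker number (and densities per Mb when chromosome lengths are
#' supplied). Percentages are half-up rounded to 1 decimal; an empty
#' marker table yields zero tables without error.
#'
#' @param markers Marker data.frame; recognized columns: length_class,
#'   motif_class, context, frame_effect (CDS markers), categories
#'   (semicolon-joined labels), seq_id.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp)
#'   for densities.
#' @return list of data.frames: length_class, motif_class, context,
#'   frame_effect, categories; plus overall_density when lengths given.
#' @export
summary_report <- function(markers, chrom_lengths = NULL) {
  n <- nrow(markers)
  out <- list()
  if (!is.null(markers$length_class)) {
    out$length_class <- count_pct_table(markers$length_class,
                                        c("classI", "classII"))
  }
  if (!is.null(markers$motif_class)) {
    out$motif_class <- count_pct_table(markers$motif_class,
                                       c("di", "tri", "tetra", "penta", "hexa"))
  }
  if (!is.null(markers$context)) {
    out$context <- count_pct_table(markers$context,
                                   c("CDS", "UTR", "intron", "URR", "intergenic"))
  }
  if (!is.null(markers$frame_effect)) {
    cds <- markers$frame_effect[!is.na(markers$frame_effect)]
    out$frame_effect <- count_pct_table(cds, c("frameshift", "in_frame_indel",
                                               "monomorphic"))
  }
  if (!is.null(markers$categories)) {
    labs <- unlist(strsplit(markers$categories[nzchar(markers$categories)], ";",
                            fixed = TRUE))
    ulabs <- sort(unique(labs))
    counts <- vapply(ulabs, function(l) sum(labs == l), integer(1))
    tab <- data.frame(group = ulabs, n = unname(counts),
                      pct = pct1(unname(counts), n), stringsAsFactors = FALSE)
    if (!is.null(chrom_lengths)) {
      tab$density_per_mb <- unname(counts) / (sum(chrom_lengths) / 1e6)
    }
    out$categories <- tab
  }
  if (!is.null(chrom_lengths) && !is.null(markers$seq_id)) {
    out$overall_density <- marker_density(markers, chrom_lengths)$overall
  }
  out
}

#' Write report tables as TSV files
#'
#' Deterministic, byte-identical output for identical input.
#'
#' @param report List of tables from [summary_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_report_tsv <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report)) {
    if (!is.data.frame(report[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(report[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
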
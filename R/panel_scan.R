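#' Assemble an accession panel
#'
#' A panel bundles the genomes of several accessions that share reference
#' coordinates (reference-guided assemblies), their population labels, and
#' which accession is the reference.
#'
#' @param genomes Named list: accession_id -> named character vector (or
#'   `DNAStringSet`) of chromosome sequences.
#' @param populations Named character vector: accession_id -> population
#'   label (e.g. indica, aus, japonica, wild).
#' @param reference Accession id of the reference genome.
#' @return An object of class `accession_panel`.
#' @export
accession_panel <- function(genomes, populations, reference) {
  if (length(genomes) < 2L) stop("a panel needs at least 2 accessions")
  if (is.null(names(genomes))) stop("genomes must be a named list")
  genomes <- lapply(genomes, function(g) {
    if (methods::is(g, "XStringSet")) {
      ids <- names(g)
      g <- as.character(g)
      names(g) <- ids
    }
    g
  })
  if (!reference %in% names(genomes)) stop("reference accession not in panel")
  missing_pop <- setdiff(names(genomes), names(populations))
  if (length(missing_pop)) {
    stop("missing population labels for: ", paste(missing_pop, collapse = ", "))
  }
  if (any(!nzchar(populations[names(genomes)]))) {
    stop("population labels must be non-empty")
  }
  structure(
    list(genomes = genomes,
         populations = populations[names(genomes)],
         reference = reference),
    class = "accession_panel"
  )
}

#' @export
print.accession_panel <- function(x, ...) {
  cat("accession_panel:", length(x$genomes), "accessions, reference",
      x$reference, "\n")
  print(table(x$populations))
  invisible(x)
}

# Measure the repeat tract in one accession at one reference-anchored locus.
# The upstream flank is located by exact match near the expected position
# (coordinates may be shifted by indels elsewhere), then whole repeat units
# are counted and the downstream flank must follow immediately. Returns the
# tract length in bp, or NA when the flanks are not conserved or the tract
# is interrupted. When several positions carry a valid
# flank-tract-flank structure, the one closest to the expected position is
# used, so growing the flank length can only remove accessions, never add.
measure_tract <- function(acc_seq, flank_up, flank_down, unit,
                          expect_start, flank_len, max_shift = 200L) {
  n <- nchar(acc_seq)
  p <- nchar(unit)
  win_from <- max(1L, expect_start - flank_len - max_shift)
  win_to <- min(n, expect_start + flank_len + max_shift + 6L * 50L)
  window <- substr(acc_seq, win_from, win_to)
  hits <- gregexpr(flank_up, window, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NA_integer_)
  cand <- integer()
  for (h in as.integer(hits)) {
    tract_at <- win_from + h - 1L + flank_len # first base after upstream flank
    k <- 0L
    while (tract_at + (k + 1L) * p - 1L <= n &&
           substr(acc_seq, tract_at + k * p, tract_at + (k + 1L) * p - 1L) == unit) {
      k <- k + 1L
    }
    after <- tract_at + k * p
    if (after + flank_len - 1L > n) next
    if (substr(acc_seq, after, after + flank_len - 1L) == flank_down) {
      cand <- c(cand, k * p)
      names(cand)[length(cand)] <- as.character(tract_at)
    }
  }
  if (length(cand) == 0L) return(NA_integer_)
  dist <- abs(as.integer(names(cand)) - expect_start)
  unname(cand[which.min(dist)])
}

#' Anchor reference SSRs across a panel and screen for length polymorphism
#'
#' For every reference SSR locus, each accession contributes a tract length
#' only when both flanking sequences of length `flank_len` match the
#' reference exactly in that accession (the in-silico analogue of conserved
#' primer sites). Accessions with mutated, missing or ambiguous flanks, or an
#' interrupted repeat tract, are recorded as absent (NA), not zero. A marker
#' is polymorphic when at least two accessions with conserved flanks have
#' unequal tract lengths; polymorphic markers carry within/between-population
#' category labels.
#'
#' @param panel An [accession_panel()].
#' @param reference_ssrs SSR catalog on the reference genome, as returned by
#'   [find_perfect_ssrs()] or [ssr_catalog()].
#' @param flank_len Flank conservation length in bp (default 20).
#' @param max_shift Maximum coordinate shift (bp) tolerated when re-locating
#'   a locus in an accession assembly.
#' @return data.frame: one row per reference SSR with locus columns, flank
#'   sequences, one `tract.<accession>` column per accession (bp, NA =
#'   absent), `is_polymorphic`, and semicolon-joined `categories`.
#' @export
anchor_and_compare <- function(panel, reference_ssrs, flank_len = 20L,
                               max_shift = 200L) {
  stopifnot(inherits(panel, "accession_panel"))
  if (flank_len < 1L) stop("flank_len must be >= 1")
  ref <- panel$genomes[[panel$reference]]
  accs <- names(panel$genomes)
  ssrs <- reference_ssrs
  n_mark <- nrow(ssrs)
  tracts <- matrix(NA_integer_, nrow = n_mark, ncol = length(accs),
                   dimnames = list(NULL, accs))
  flank_up <- character(n_mark)
  flank_down <- character(n_mark)
  keep <- logical(n_mark)

  for (i in seq_len(n_mark)) {
    sid <- ssrs$seq_id[i]
    if (!sid %in% names(ref)) stop("reference lacks sequence ", sid)
    rseq <- ref[[sid]]
    s <- ssrs$start[i]; e <- ssrs$end[i]
    if (s - flank_len < 1L || e + flank_len > nchar(rseq)) next # no room for flanks
    fu <- substr(rseq, s - flank_len, s - 1L)
    fd <- substr(rseq, e + 1L, e + flank_len)
    if (grepl("[^ACGT]", fu) || grepl("[^ACGT]", fd)) next # ambiguous flank
    unit <- substr(rseq, s, s + nchar(ssrs$motif[i]) - 1L)
    keep[i] <- TRUE
    flank_up[i] <- fu
    flank_down[i] <- fd
    tracts[i, panel$reference] <- e - s + 1L
    for (a in setdiff(accs, panel$reference)) {
      aseq <- panel$genomes[[a]][[sid]]
      if (is.null(aseq)) next
      tracts[i, a] <- measure_tract(aseq, fu, fd, unit, s, flank_len, max_shift)
    }
  }

  out <- ssrs[keep, , drop = FALSE]
  tracts <- tracts[keep, , drop = FALSE]
  out$flank_up <- flank_up[keep]
  out$flank_down <- flank_down[keep]
  for (a in accs) out[[paste0("tract.", a)]] <- tracts[, a]
  cats <- character(nrow(out))
  poly <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    lab <- classify_marker_polymorphism(tracts[i, ], panel$populations)
    cats[i] <- paste(lab, collapse = ";")
    poly[i] <- length(lab) > 0L
  }
  out$is_polymorphic <- poly
  out$categories <- cats
  rownames(out) <- NULL
  out
}

#' Within/between-population polymorphism labels for one marker
#'
#' A label `within:<pop>` is assigned when two accessions of the same
#' population differ in tract length; `between:<popA>:<popB>` (unordered,
#' alphabetical) when an accession of popA differs from one of popB. Absent
#' accessions (NA tract) never contribute. A monomorphic marker gets an
#' empty label set.
#'
#' @param tracts Named integer vector: accession -> tract length bp (NA =
#'   absent).
#' @param populations Named character vector: accession -> population.
#' @return Character vector of category labels (possibly empty), sorted.
#' @export
classify_marker_polymorphism <- function(tracts, populations) {
  obs <- tracts[!is.na(tracts)]
  if (length(obs) < 2L) return(character())
  accs <- names(obs)
  pops <- populations[accs]
  labels <- character()
  for (i in seq_len(length(obs) - 1L)) {
    for (j in (i + 1L):length(obs)) {
      if (obs[i] == obs[j]) next
      if (pops[i] == pops[j]) {
        labels <- c(labels, paste0("within:", pops[i]))
      } else {
        pr <- sort(c(pops[i], pops[j]))
        labels <- c(labels, paste0("between:", pr[1], ":", pr[2]))
      }
    }
  }
  sort(unique(labels))
}

#' Marker density per chromosome and overall (markers/Mb)
#'
#' @param markers data.frame with a `seq_id` column (one row per marker).
#' @param chrom_lengths Named numeric vector: seq_id -> length in bp.
#' @return list with `per_chromosome` (data.frame seq_id, n_markers,
#'   length_bp, density) and `overall` (total count / total Mb).
#' @export
marker_density <- function(markers, chrom_lengths) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  bad <- setdiff(unique(markers$seq_id), names(chrom_lengths))
  if (length(bad)) stop("markers on unknown sequences: ", paste(bad, collapse = ", "))
  counts <- table(factor(markers$seq_id, levels = names(chrom_lengths)))
  per <- data.frame(
    seq_id = names(chrom_lengths),
    n_markers = as.integer(counts),
    length_bp = as.numeric(chrom_lengths),
    stringsAsFactors = FALSE
  )
  per$density <- per$n_markers / (per$length_bp / 1e6)
  list(
    per_chromosome = per,
    overall = sum(per$n_markers) / (sum(per$length_bp) / 1e6)
  )
}

#' Export marker intervals as BED lines (0-based half-open)
#'
#' @param markers Marker data.frame with seq_id, start, end (1-based
#'   inclusive) and motif columns.
#' @return Character vector of BED lines.
#' @export
marker_bed_lines <- function(markers) {
  if (nrow(markers) == 0L) return(character())
  paste(markers$seq_id, markers$start - 1L, markers$end,
        paste0(markers$motif, "_x", markers$repeat_count), sep = "\t")
}
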
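#' Phenotype summary: mean, CV and broad-sense heritability
#'
#' Entry means are averaged over replicates; CV = sd/mean over entry means.
#' Broad-sense heritability on an entry-mean basis is estimated from one-way
#' ANOVA variance components: with genotype mean square MSG, error mean
#' square MSE and r replicates, sigma2_g = (MSG - MSE)/r, sigma2_e = MSE and
#' H2 = sigma2_g / (sigma2_g + sigma2_e / r), clamped to [0, 1].
#'
#' @param pheno data.frame with columns `individual` and `value` (one row
#'   per replicate measurement).
#' @return list(mean, cv, H2, sigma2_g, sigma2_e, r, entry_means).
#' @export
phenotype_stats <- function(pheno) {
  if (!all(c("individual", "value") %in% names(pheno))) {
    stop("pheno needs columns 'individual' and 'value'")
  }
  if (any(!is.finite(pheno$value))) stop("trait values must be finite")
  em <- tapply(pheno$value, pheno$individual, mean)
  if (length(em) < 2L) stop("need at least 2 individuals")
  m <- mean(em)
  cv <- if (m == 0) NA_real_ else stats::sd(em) / m
  reps <- table(pheno$individual)
  if (min(reps) < 2L) {
    stop("H2 undefined: need at least 2 replicates per individual")
  }
  r <- mean(reps)
  fit <- stats::aov(value ~ factor(individual), data = pheno)
  tab <- suppressWarnings(stats::anova(fit)) # degenerate zero-error fits warn

  msg <- tab$`Mean Sq`[1L]
  mse <- tab$`Mean Sq`[2L]
  sigma2_g <- max(0, (msg - mse) / r)
  h2 <- sigma2_g / (sigma2_g + mse / r)
  if (!is.finite(h2)) h2 <- 1 # zero error variance: fully heritable
  list(mean = m, cv = cv, H2 = min(1, max(0, h2)),
       sigma2_g = sigma2_g, sigma2_e = mse, r = r, entry_means = em)
}

#' Chi-square test of 1:1 Mendelian segregation for one marker
#'
#' Pearson goodness-of-fit of the two homozygous genotype class counts
#' against the expected 1:1 ratio; markers with p < alpha are flagged for
#' removal from map construction. Heterozygotes are excluded before calling
#' this (codominant markers in a selfed population are tested on the two
#' parental homozygous classes).
#'
#' @param counts Integer vector of length 2 (the two homozygous classes).
#' @param alpha Significance threshold (default 0.05).
#' @return list(chi2, p, keep).
#' @export
segregation_filter <- function(counts, alpha = 0.05) {
  if (length(counts) != 2L) stop("counts must have the two homozygous classes")
  if (sum(counts) == 0) stop("zero total count")
  ht <- stats::chisq.test(counts, p = c(0.5, 0.5))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value),
       keep = unname(ht$p.value) >= alpha)
}

#' Select extreme phenotypic bulks of homozygous individuals
#'
#' Individuals are ranked by trait value; the high bulk takes the k
#' top-ranked individuals homozygous for the high-parent allele at every
#' region marker, the low bulk the k bottom-ranked individuals homozygous
#' for the low-parent allele. Heterozygous or recombinant individuals are
#' skipped and the next-ranked eligible individual is taken. Ties are broken
#' by individual order in `trait`.
#'
#' @param trait Named numeric vector of entry means per individual.
#' @param genotypes individuals x markers character matrix coded with
#'   `high_code`, `low_code` and anything else for heterozygous/missing.
#' @param region_markers Marker columns that must be homozygous (may be
#'   empty: only phenotype ranking applies).
#' @param k Bulk size.
#' @param high_code,low_code Genotype codes of the two parental homozygotes.
#' @return list(hgwb, lgwb): character vectors of k individual ids each.
#' @export
select_bulks <- function(trait, genotypes, region_markers, k = 10L,
                         high_code = "A", low_code = "B") {
  if (k < 1L) stop("k must be >= 1")
  ids <- names(trait)
  if (is.null(ids)) stop("trait must be a named vector")
  if (!all(ids %in% rownames(genotypes))) stop("genotypes lack some individuals")
  if (!all(region_markers %in% colnames(genotypes))) {
    stop("region markers missing from genotype table")
  }
  hom <- function(code) {
    if (length(region_markers) == 0L) return(rep(TRUE, length(ids)))
    apply(genotypes[ids, region_markers, drop = FALSE] == code, 1L, all)
  }
  ord_hi <- ids[order(-trait, seq_along(trait))]
  ord_lo <- ids[order(trait, seq_along(trait))]
  eligible_hi <- ord_hi[hom(high_code)[match(ord_hi, ids)]]
  eligible_lo <- ord_lo[hom(low_code)[match(ord_lo, ids)]]
  if (length(eligible_hi) < k) {
    stop("insufficient eligible high-tail individuals: need ", k,
         ", have ", length(eligible_hi))
  }
  if (length(eligible_lo) < k) {
    stop("insufficient eligible low-tail individuals: need ", k,
         ", have ", length(eligible_lo))
  }
  list(hgwb = eligible_hi[seq_len(k)], lgwb = eligible_lo[seq_len(k)])
}

#' Depth/quality/segregation filter for bulk variant calls
#'
#' A call passes when total read depth (high + low + other allele reads) is
#' at least `min_depth` in both bulks, base quality is at least `min_qual`,
#' and the two parental alleles are distinct. Failures carry the first
#' failing reason (depth, quality, monomorphic).
#'
#' @param calls data.frame with columns seq_id, pos, kind, high_allele,
#'   low_allele, qual, hb_hi, hb_lo, lb_hi, lb_lo and optional hb_other,
#'   lb_other read counts.
#' @param min_depth Minimum per-bulk total depth (default 10).
#' @param min_qual Minimum base quality (default 20).
#' @return `calls` with added `filter_status` ("PASS"/"FAIL") and
#'   `fail_reason` columns.
#' @export
filter_variants <- function(calls, min_depth = 10, min_qual = 20) {
  if (is.null(calls$hb_other)) calls$hb_other <- 0L
  if (is.null(calls$lb_other)) calls$lb_other <- 0L
  hb_depth <- calls$hb_hi + calls$hb_lo + calls$hb_other
  lb_depth <- calls$lb_hi + calls$lb_lo + calls$lb_other
  reason <- rep(NA_character_, nrow(calls))
  reason[is.na(reason) & (hb_depth < min_depth | lb_depth < min_depth)] <- "depth"
  reason[is.na(reason) & calls$qual < min_qual] <- "quality"
  reason[is.na(reason) & calls$high_allele == calls$low_allele] <- "monomorphic"
  calls$filter_status <- ifelse(is.na(reason), "PASS", "FAIL")
  calls$fail_reason <- reason
  calls
}

#' SNP/SSR-index of one bulk at one variant
#'
#' Fraction of usable reads carrying the high-parent allele. Reads matching
#' neither parental allele (e.g. stutter tract lengths at SSR sites) are
#' excluded from both numerator and denominator.
#'
#' @param hi Reads carrying the high-parent allele.
#' @param lo Reads carrying the low-parent allele.
#' @return Index in [0, 1]; NA when no usable reads.
#' @export
bulk_index <- function(hi, lo) {
  usable <- hi + lo
  ifelse(usable > 0, hi / usable, NA_real_)
}

#' Per-variant SNP/SSR-index and delta-index table
#'
#' Computes the high- and low-bulk indices and
#' delta = index(HGWB) - index(LGWB), positive when the high-parent allele
#' is enriched in the high bulk. Only PASS calls are used when a
#' `filter_status` column is present.
#'
#' @param calls Variant calls (see [filter_variants()]).
#' @return data.frame: seq_id, pos, kind, index_hgwb, index_lgwb, delta,
#'   depth (mean usable depth of the two bulks).
#' @export
delta_index <- function(calls) {
  if (!is.null(calls$filter_status)) {
    calls <- calls[calls$filter_status == "PASS", , drop = FALSE]
  }
  ih <- bulk_index(calls$hb_hi, calls$hb_lo)
  il <- bulk_index(calls$lb_hi, calls$lb_lo)
  data.frame(
    seq_id = calls$seq_id, pos = calls$pos, kind = calls$kind,
    index_hgwb = ih, index_lgwb = il, delta = ih - il,
    depth = (calls$hb_hi + calls$hb_lo + calls$lb_hi + calls$lb_lo) / 2,
    stringsAsFactors = FALSE
  )
}

#' Sliding-window profile of delta-index along a chromosome
#'
#' Windows are anchored at position 0 and advance by `step_bp`; membership
#' is half-open: a variant belongs to windows with
#' start <= pos < start + window_bp. Window means are unweighted means over
#' the member variants; windows with fewer than `min_variants` variants are
#' reported with NA means (undefined, not zero).
#'
#' @param points Per-variant index table from [delta_index()] (one
#'   chromosome).
#' @param window_bp Window size in bp (default 1 Mb).
#' @param step_bp Step/increment in bp (default 10 kb).
#' @param min_variants Minimum variants for a defined window mean (default 3).
#' @param chrom_length Optional chromosome length; windows cover up to it
#'   (otherwise up to the last variant).
#' @return data.frame: window_start, window_end (exclusive), n, mean_delta,
#'   mean_index_hgwb, mean_index_lgwb, mean_depth.
#' @export
window_profile <- function(points, window_bp = 1e6, step_bp = 1e4,
                           min_variants = 3L, chrom_length = NULL) {
  if (window_bp < step_bp) stop("window must be at least as large as the step")
  if (length(unique(points$seq_id)) > 1L) {
    stop("window_profile works on one chromosome at a time")
  }
  points <- points[!is.na(points$delta), , drop = FALSE]
  points <- points[order(points$pos), , drop = FALSE]
  last <- if (is.null(chrom_length)) {
    if (nrow(points)) max(points$pos) else 0
  } else chrom_length
  starts <- seq(0, max(0, last - 1), by = step_bp)
  pos <- points$pos
  cd <- cumsum(c(0, points$delta))
  ch <- cumsum(c(0, points$index_hgwb))
  cl <- cumsum(c(0, points$index_lgwb))
  cp <- cumsum(c(0, points$depth))
  lo <- findInterval(starts - 0.5, pos) + 1L
  hi <- findInterval(starts + window_bp - 0.5, pos)
  n <- pmax(0L, hi - lo + 1L)
  msum <- function(cs) ifelse(n > 0, cs[hi + 1L] - cs[lo], NA_real_)
  out <- data.frame(
    window_start = starts, window_end = starts + window_bp, n = n,
    mean_delta = msum(cd) / n, mean_index_hgwb = msum(ch) / n,
    mean_index_lgwb = msum(cl) / n, mean_depth = msum(cp) / n
  )
  und <- out$n < min_variants
  out$mean_delta[und] <- NA_real_
  out$mean_index_hgwb[und] <- NA_real_
  out$mean_index_lgwb[und] <- NA_real_
  out
}

#' Physical span of a QTL interval
#'
#' Span in bp between two flanking coordinates, using the printed-span
#' convention end - start.
#'
#' @param start_bp,end_bp Interval flanking positions, start < end.
#' @return Span in bp.
#' @examples
#' interval_length(6827053, 10790507)  # 3963454
#' @export
interval_length <- function(start_bp, end_bp) {
  if (any(start_bp >= end_bp)) stop("interval start must be below end")
  end_bp - start_bp
}
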
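random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_primitive_unit <- function(period) {
  repeat {
    u <- random_dna(period)
    if (primitive_period(u) == period) return(u)
  }
}

substitute_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1L)
}

#' Configuration for the synthetic accession-panel generator
#'
#' Defaults emulate a small multi-accession rice-like panel: 11 accessions
#' over four population groups (indica, aus, japonica, wild) with one
#' japonica reference, two chromosomes seeded with perfect SSR loci and
#' simple gene models. Repeat-count mutations use a geometric step over
#' units (p = 0.5, sign equiprobable), so single-unit variants dominate as
#' observed for microsatellites.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_ssr_per_chrom Planted SSR loci per chromosome.
#' @param gap_range Range (bp) of random background stretches between loci.
#' @param genes_per_chrom Gene models per chromosome (fixed
#'   UTR-CDS-intron-CDS-UTR template, alternating strand).
#' @param accessions Named character vector accession_id -> population; the
#'   first entry is the reference.
#' @param ssr_mut_prob Per-locus, per-accession probability of a
#'   repeat-count mutation.
#' @param snp_rate Background SNP rate per bp (outside SSR/flank windows).
#' @param flank_mut_prob Per-locus, per-accession probability of a single
#'   substitution inside one 20 bp flank (breaks marker transferability).
#' @param flank_len Flank length (bp) protected from background SNPs and
#'   targeted by flank mutations.
#' @param seed Integer seed; recorded in the output.
#' @return list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_chrom = 2L, n_ssr_per_chrom = 40L,
                             gap_range = c(2000L, 4000L),
                             genes_per_chrom = 8L,
                             accessions = c(
                               REF_NIPPO = "japonica", IND1 = "indica",
                               IND2 = "indica", IND3 = "indica",
                               IND4 = "indica", AUS1 = "aus", AUS2 = "aus",
                               JAP2 = "japonica", WILD1 = "wild",
                               WILD2 = "wild", WILD3 = "wild"
                             ),
                             ssr_mut_prob = 0.4, snp_rate = 0.001,
                             flank_mut_prob = 0.05, flank_len = 20L,
                             seed = 1L) {
  stopifnot(ssr_mut_prob >= 0, ssr_mut_prob <= 1, snp_rate >= 0,
            snp_rate <= 1, flank_mut_prob >= 0, flank_mut_prob <= 1,
            n_chrom >= 1, n_ssr_per_chrom >= 1, length(accessions) >= 2)
  structure(as.list(environment()), class = "panel_sim_config")
}

plan_chromosome <- function(cfg, chrom_id) {
  n <- cfg$n_ssr_per_chrom
  period <- sample(2:6, n, replace = TRUE, prob = c(.35, .30, .15, .10, .10))
  loci <- data.frame(
    locus_id = sprintf("%s_ssr%03d", chrom_id, seq_len(n)),
    period = period,
    unit = vapply(period, random_primitive_unit, character(1)),
    count = ifelse(period == 2L,
                   sample(6:18, n, replace = TRUE),
                   sample(5:12, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  loci$gap <- sample(seq(cfg$gap_range[1], cfg$gap_range[2]), n, replace = TRUE)
  loci
}

# splice reference chromosome: background, one guard base each side of every
# tract so planted tracts are maximal exactly as planned
assemble_reference_chrom <- function(loci) {
  pieces <- character(0)
  pos <- 0L
  starts <- ends <- integer(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    u <- loci$unit[i]; p <- loci$period[i]
    guard_l <- sample(setdiff(c("A", "C", "G", "T"), substr(u, p, p)), 1L)
    guard_r <- sample(setdiff(c("A", "C", "G", "T"), substr(u, 1L, 1L)), 1L)
    tract <- strrep(u, loci$count[i])
    pieces <- c(pieces, random_dna(loci$gap[i]), guard_l, tract, guard_r)
    starts[i] <- pos + loci$gap[i] + 2L
    ends[i] <- starts[i] + loci$count[i] * p - 1L
    pos <- ends[i] + 1L
  }
  pieces <- c(pieces, random_dna(2500L))
  loci$start <- starts
  loci$end <- ends
  list(seq = paste(pieces, collapse = ""), loci = loci)
}

gene_template_rows <- function(gene_id, seq_id, strand, s) {
  seg <- function(type, from, to) {
    data.frame(gene_id = gene_id, seq_id = seq_id, strand = strand,
               type = type, start = s + from, end = s + to,
               stringsAsFactors = FALSE)
  }
  parts <- if (strand == "+") {
    rbind(seg("five_prime_UTR", 0L, 149L), seg("CDS", 150L, 449L),
          seg("intron", 450L, 569L), seg("CDS", 570L, 869L),
          seg("three_prime_UTR", 870L, 1019L))
  } else {
    rbind(seg("three_prime_UTR", 0L, 149L), seg("CDS", 150L, 449L),
          seg("intron", 450L, 569L), seg("CDS", 570L, 869L),
          seg("five_prime_UTR", 870L, 1019L))
  }
  rbind(seg("gene", 0L, 1019L), parts)
}

#' Simulate a multi-accession panel with planted SSR/SNP variation
#'
#' Builds a reference genome with seeded perfect SSR loci (guarded so every
#' planted tract is maximal exactly as planned) and simple gene models, then
#' derives each accession by applying repeat-count mutations, background
#' SNPs (kept away from SSR tracts and their flanks), and occasional flank
#' mutations that break marker transferability. The truth table records
#' every per-accession tract length and whether flanks were left intact, so
#' the polymorphism scan can be validated exactly.
#'
#' @param cfg A [panel_sim_config()].
#' @return list of class `ssr_panel_sim`: `panel` ([accession_panel()]
#'   including the reference), `ssrs` (planted reference catalog in
#'   [find_perfect_ssrs()] column layout), `genes` (gene-model segment
#'   table), `truth` (per locus x accession tract lengths and flank_intact
#'   flags), `config`.
#' @export
simulate_panel <- function(cfg = panel_sim_config()) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  set.seed(cfg$seed)
  accs <- names(cfg$accessions)
  ref_id <- accs[1L]
  chrom_ids <- sprintf("chr%02d", seq_len(cfg$n_chrom))

  ref <- character(0)
  all_loci <- list()
  genes <- list()
  for (cid in chrom_ids) {
    built <- assemble_reference_chrom(plan_chromosome(cfg, cid))
    ref[cid] <- built$seq
    built$loci$seq_id <- cid
    all_loci[[cid]] <- built$loci
    len <- nchar(built$seq)
    for (gidx in seq_len(cfg$genes_per_chrom)) {
      s <- 2200L + floor((len - 4400L) * (gidx - 1L) / cfg$genes_per_chrom)
      genes[[length(genes) + 1L]] <- gene_template_rows(
        sprintf("%s_g%02d", cid, gidx), cid,
        if (gidx %% 2L == 0L) "-" else "+", s
      )
    }
  }
  loci <- do.call(rbind, all_loci)
  rownames(loci) <- NULL
  genes <- do.call(rbind, genes)

  genomes <- list()
  genomes[[ref_id]] <- ref
  truth <- list()
  for (i in seq_len(nrow(loci))) {
    truth[[length(truth) + 1L]] <- data.frame(
      locus_id = loci$locus_id[i], seq_id = loci$seq_id[i],
      ref_start = loci$start[i], ref_end = loci$end[i],
      motif = canonical_motif(loci$unit[i]), period = loci$period[i],
      ref_count = loci$count[i], accession = ref_id,
      acc_count = loci$count[i], acc_tract_bp = loci$count[i] * loci$period[i],
      flank_intact = TRUE, stringsAsFactors = FALSE
    )
  }

  for (a in accs[-1L]) {
    acc_genome <- character(0)
    for (cid in chrom_ids) {
      lc <- loci[loci$seq_id == cid, , drop = FALSE]
      x <- strsplit(ref[[cid]], "", fixed = TRUE)[[1]]
      len <- length(x)
      mask <- unlist(lapply(seq_len(nrow(lc)), function(i) {
        seq(max(1L, lc$start[i] - cfg$flank_len - 1L),
            min(len, lc$end[i] + cfg$flank_len + 1L))
      }))
      allowed <- setdiff(seq_len(len), mask)
      n_snp <- stats::rbinom(1L, length(allowed), cfg$snp_rate)
      if (n_snp > 0L) {
        snp_pos <- sample(allowed, n_snp)
        x[snp_pos] <- vapply(x[snp_pos], substitute_base, character(1))
      }
      flank_ok <- rep(TRUE, nrow(lc))
      new_count <- lc$count
      for (i in seq_len(nrow(lc))) {
        if (stats::runif(1) < cfg$flank_mut_prob) {
          off <- sample.int(cfg$flank_len, 1L)
          at <- if (stats::runif(1) < 0.5) lc$start[i] - off else lc$end[i] + off
          if (at >= 1L && at <= len) {
            x[at] <- substitute_base(x[at])
            flank_ok[i] <- FALSE
          }
        }
        if (stats::runif(1) < cfg$ssr_mut_prob) {
          step <- (stats::rgeom(1L, 0.5) + 1L) * sample(c(-1L, 1L), 1L)
          new_count[i] <- max(1L, lc$count[i] + step)
        }
      }
      base_seq <- paste(x, collapse = "")
      pieces <- character(0)
      prev_end <- 0L
      for (i in seq_len(nrow(lc))) {
        pieces <- c(pieces, substr(base_seq, prev_end + 1L, lc$start[i] - 1L),
                    strrep(lc$unit[i], new_count[i]))
        prev_end <- lc$end[i]
      }
      pieces <- c(pieces, substr(base_seq, prev_end + 1L, len))
      acc_genome[cid] <- paste(pieces, collapse = "")
      for (i in seq_len(nrow(lc))) {
        truth[[length(truth) + 1L]] <- data.frame(
          locus_id = lc$locus_id[i], seq_id = cid,
          ref_start = lc$start[i], ref_end = lc$end[i],
          motif = canonical_motif(lc$unit[i]), period = lc$period[i],
          ref_count = lc$count[i], accession = a,
          acc_count = new_count[i],
          acc_tract_bp = new_count[i] * lc$period[i],
          flank_intact = flank_ok[i], stringsAsFactors = FALSE
        )
      }
    }
    genomes[[a]] <- acc_genome
  }

  ssrs <- data.frame(
    seq_id = loci$seq_id, start = loci$start, end = loci$end,
    motif = vapply(loci$unit, canonical_motif, character(1), USE.NAMES = FALSE),
    motif_class = motif_class_name(loci$period),
    repeat_count = loci$count, tract_bp = loci$count * loci$period,
    stringsAsFactors = FALSE
  )
  ssrs$length_class <- classify_length(ssrs$tract_bp)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(
    list(
      panel = accession_panel(genomes, cfg$accessions, ref_id),
      ssrs = ssrs, genes = genes, truth = truth, config = cfg
    ),
    class = "ssr_panel_sim"
  )
}

#' Configuration for the F4 bulked-segregant simulator
#'
#' Defaults mirror the study conditions of a grain-weight mapping design:
#' 190 F4 individuals from a biparental cross, bulks of 10 homozygous
#' extreme individuals per tail, about 100x read depth, one major additive
#' QTL, and plot-level heritability 0.8.
#'
#' @param n Population size.
#' @param generation Selfing generation (4 = F4; expected heterozygosity
#'   (1/2)^(g-1) = 1/8).
#' @param k Bulk size per tail.
#' @param n_variants Variant sites on the chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param morgans Genetic length of the chromosome in Morgans (Haldane, no
#'   interference).
#' @param qtl data.frame(pos, effect): additive QTL positions (bp) and
#'   effects; effect 0 rows are allowed (null loci).
#' @param h2 Plot-level broad-sense heritability target used to set the
#'   environmental variance from the realized genetic variance.
#' @param reps Replicate phenotype measurements per individual.
#' @param depth_mean Mean Poisson read depth per bulk per variant.
#' @param mu Trait grand mean (e.g. 1000-grain weight, g).
#' @param sigma_e0 Environmental SD used when genetic variance is zero
#'   (null simulations).
#' @param ssr_every Every `ssr_every`-th variant is emitted as an SSR site,
#'   the rest as SNPs.
#' @param bulk_region_halfwidth Markers within this distance of a non-zero
#'   QTL must be homozygous in bulk members.
#' @param seq_id Chromosome name.
#' @param seed Integer seed.
#' @return list of class `cross_sim_config`.
#' @export
cross_sim_config <- function(n = 190L, generation = 4L, k = 10L,
                             n_variants = 400L, chrom_length = 1e7,
                             morgans = 1.2,
                             qtl = data.frame(pos = 5e6, effect = 1),
                             h2 = 0.8, reps = 2L, depth_mean = 100,
                             mu = 17.5, sigma_e0 = 1, ssr_every = 10L,
                             bulk_region_halfwidth = 5e5, seq_id = "chr05",
                             seed = 1L) {
  stopifnot(n >= 2 * k, generation >= 2, h2 > 0, h2 <= 1,
            all(is.finite(qtl$effect)))
  structure(as.list(environment()), class = "cross_sim_config")
}

# one gamete from a haplotype pair: Poisson(morgans) crossovers at uniform
# genetic positions (Haldane model, no interference)
meiosis_gamete <- function(h1, h2, loc_morgan, morgans) {
  n_xo <- stats::rpois(1L, morgans)
  phase0 <- sample.int(2L, 1L) - 1L
  if (n_xo == 0L) {
    return(if (phase0 == 0L) h1 else h2)
  }
  xo <- sort(stats::runif(n_xo, 0, morgans))
  phase <- (phase0 + findInterval(loc_morgan, xo)) %% 2L
  ifelse(phase == 0L, h1, h2)
}

simulate_f4_once <- function(cfg) {
  m_pos <- sort(sample.int(cfg$chrom_length, cfg$n_variants))
  loci_pos <- sort(unique(c(m_pos, cfg$qtl$pos)))
  m <- length(loci_pos)
  loc_morgan <- loci_pos / cfg$chrom_length * cfg$morgans
  ids <- sprintf("I%03d", seq_len(cfg$n))
  H1 <- matrix(0L, cfg$n, m)
  H2 <- matrix(0L, cfg$n, m)
  for (i in seq_len(cfg$n)) {
    h1 <- rep(0L, m) # low parent origin
    h2 <- rep(1L, m) # high parent origin
    for (gen in seq_len(cfg$generation - 1L)) {
      n1 <- meiosis_gamete(h1, h2, loc_morgan, cfg$morgans)
      n2 <- meiosis_gamete(h1, h2, loc_morgan, cfg$morgans)
      h1 <- n1; h2 <- n2
    }
    H1[i, ] <- h1; H2[i, ] <- h2
  }
  rownames(H1) <- rownames(H2) <- ids
  list(loci_pos = loci_pos, H1 = H1, H2 = H2, ids = ids)
}

#' Simulate an F4 population with planted QTLs and bulk allele-depth tables
#'
#' Starts from a fully heterozygous F1 and selfs with Poisson (Haldane)
#' crossovers for g-1 generations, one lineage per individual (single-seed
#' descent). Phenotype y = mu + sum(a_i x_i) + e with x in {-1, 0, 1} and
#' environmental variance set from the target heritability. Extreme bulks
#' are chosen with [select_bulks()] (homozygosity enforced at markers near
#' non-zero QTLs), and per-variant bulk read depths are Poisson with
#' binomial high-allele counts at the true bulk allele frequency. If bulk
#' selection is infeasible the population is regenerated with a shifted
#' seed, up to 5 attempts.
#'
#' @param cfg A [cross_sim_config()].
#' @return list of class `f4_bulk_sim`: `loci` (pos, id, kind, cM, is_qtl),
#'   `pheno` (individual, rep, value), `entry_means`, `genotypes` (n x m
#'   "A"/"H"/"B"), `dosage` (n x m high-allele dosage 0/1/2), `bulks`,
#'   `calls` (variant table for [filter_variants()]), `truth` (QTL spec and
#'   realized variances), `config`.
#' @export
simulate_f4_bulks <- function(cfg = cross_sim_config()) {
  stopifnot(inherits(cfg, "cross_sim_config"))
  qtl <- cfg$qtl[cfg$qtl$effect != 0, , drop = FALSE]
  for (attempt in 0:4) {
    set.seed(cfg$seed + 1000L * attempt)
    pop <- simulate_f4_once(cfg)
    m <- length(pop$loci_pos)
    dosage <- pop$H1 + pop$H2
    marker_ids <- sprintf("M%04d", seq_len(m))
    colnames(dosage) <- marker_ids

    geno_val <- cbind(if (nrow(qtl)) dosage[, match(qtl$pos, pop$loci_pos),
                                            drop = FALSE] - 1L)
    G <- cfg$mu + if (nrow(qtl)) as.numeric(geno_val %*% qtl$effect) else 0
    s2g <- if (nrow(qtl)) stats::var(G) else 0
    sigma_e <- if (s2g > 0) sqrt(s2g * (1 - cfg$h2) / cfg$h2) else cfg$sigma_e0
    pheno <- do.call(rbind, lapply(seq_len(cfg$reps), function(r) {
      data.frame(individual = pop$ids, rep = r,
                 value = G + stats::rnorm(cfg$n, 0, sigma_e),
                 stringsAsFactors = FALSE)
    }))
    em <- tapply(pheno$value, pheno$individual, mean)[pop$ids]

    genotypes <- matrix(c("B", "H", "A")[dosage + 1L], nrow = cfg$n,
                        dimnames = list(pop$ids, marker_ids))
    region <- marker_ids[vapply(pop$loci_pos, function(p) {
      nrow(qtl) > 0 && any(abs(p - qtl$pos) <= cfg$bulk_region_halfwidth)
    }, logical(1))]
    bulks <- tryCatch(
      select_bulks(em, genotypes, region, k = cfg$k),
      error = function(e) e
    )
    if (!inherits(bulks, "error")) break
    if (attempt == 4L) stop("bulk selection infeasible after 5 attempts: ",
                            conditionMessage(bulks))
  }

  freq_in <- function(members) {
    colMeans(rbind(pop$H1[members, , drop = FALSE],
                   pop$H2[members, , drop = FALSE]))
  }
  p_h <- freq_in(bulks$hgwb)
  p_l <- freq_in(bulks$lgwb)
  hb_depth <- stats::rpois(m, cfg$depth_mean)
  lb_depth <- stats::rpois(m, cfg$depth_mean)
  hb_hi <- stats::rbinom(m, hb_depth, p_h)
  lb_hi <- stats::rbinom(m, lb_depth, p_l)
  kind <- ifelse(seq_len(m) %% cfg$ssr_every == 0L, "SSR", "SNP")
  calls <- data.frame(
    seq_id = cfg$seq_id, pos = pop$loci_pos, kind = kind,
    high_allele = ifelse(kind == "SSR", "tract_hi", "A"),
    low_allele = ifelse(kind == "SSR", "tract_lo", "G"),
    qual = 30, hb_hi = hb_hi, hb_lo = hb_depth - hb_hi,
    lb_hi = lb_hi, lb_lo = lb_depth - lb_hi,
    stringsAsFactors = FALSE
  )
  loci <- data.frame(
    id = marker_ids, pos = pop$loci_pos,
    cM = pop$loci_pos / cfg$chrom_length * cfg$morgans * 100,
    kind = kind, is_qtl = pop$loci_pos %in% qtl$pos,
    stringsAsFactors = FALSE
  )
  structure(
    list(loci = loci, pheno = pheno, entry_means = em,
         genotypes = genotypes, dosage = dosage, bulks = bulks,
         calls = calls,
         truth = list(qtl = cfg$qtl, sigma2_g = s2g, sigma_e = sigma_e),
         config = cfg),
    class = "f4_bulk_sim"
  )
}
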
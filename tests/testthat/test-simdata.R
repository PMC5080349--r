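small_panel_cfg <- function(seed = 5L, ...) {
  panel_sim_config(n_chrom = 1L, n_ssr_per_chrom = 12L, genes_per_chrom = 3L,
                   seed = seed, ...)
}

small_cross_cfg <- function(seed = 5L, effect = 1, ...) {
  cross_sim_config(n = 60L, k = 5L, n_variants = 80L, chrom_length = 2e6,
                   morgans = 0.5, qtl = data.frame(pos = 1e6, effect = effect),
                   bulk_region_halfwidth = 2e5, seed = seed, ...)
}

test_that("panel generation is deterministic under a fixed seed", {
  a <- simulate_panel(small_panel_cfg(seed = 9L))
  b <- simulate_panel(small_panel_cfg(seed = 9L))
  expect_identical(a$panel$genomes, b$panel$genomes)
  expect_identical(a$truth, b$truth)
  c <- simulate_panel(small_panel_cfg(seed = 10L))
  expect_false(identical(a$panel$genomes, c$panel$genomes))
})

test_that("zero mutation rates give accessions identical to the reference", {
  sim <- simulate_panel(small_panel_cfg(ssr_mut_prob = 0, snp_rate = 0,
                                        flank_mut_prob = 0))
  ref <- sim$panel$genomes[[sim$panel$reference]]
  for (a in names(sim$panel$genomes)) {
    expect_identical(sim$panel$genomes[[a]], ref)
  }
  mk <- anchor_and_compare(sim$panel, sim$ssrs)
  expect_false(any(mk$is_polymorphic))
})

test_that("planted reference tracts are exactly maximal and re-discoverable", {
  sim <- simulate_panel(small_panel_cfg(seed = 31L))
  found <- ssr_catalog(sim$panel$genomes[[sim$panel$reference]])
  key <- paste(found$seq_id, found$start, found$end, found$motif)
  planted <- paste(sim$ssrs$seq_id, sim$ssrs$start, sim$ssrs$end,
                   sim$ssrs$motif)
  expect_true(all(planted %in% key))
})

test_that("panel scan recovers the planted truth at intact flanks", {
  sim <- simulate_panel(small_panel_cfg(seed = 11L))
  mk <- anchor_and_compare(sim$panel, sim$ssrs)
  mk_key <- paste(mk$seq_id, mk$start)
  tr <- sim$truth
  for (r in which(tr$accession != sim$panel$reference)) {
    i <- match(paste(tr$seq_id[r], tr$ref_start[r]), mk_key)
    got <- mk[i, paste0("tract.", tr$accession[r])]
    if (tr$flank_intact[r]) {
      expect_equal(got, tr$acc_tract_bp[r])
    } else {
      expect_true(is.na(got))
    }
  }
})

test_that("gene models from the generator validate and cover all contexts", {
  sim <- simulate_panel(small_panel_cfg())
  expect_silent(validate_gene_models(sim$genes))
  probes <- data.frame(
    seq_id = sim$genes$seq_id[1],
    start = c(sim$genes$start[sim$genes$type == "CDS"][1],
              sim$genes$start[sim$genes$type == "intron"][1],
              sim$genes$start[sim$genes$type == "five_prime_UTR"][1])
  )
  probes$end <- probes$start + 5
  expect_identical(feature_context(probes, sim$genes),
                   c("CDS", "intron", "UTR"))
})

test_that("panel FASTA/GFF3 outputs round-trip through standard readers", {
  sim <- simulate_panel(small_panel_cfg())
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(sim$panel$genomes[[1]], fa)
  back <- read_genome_fasta(fa)
  expect_identical(back, sim$panel$genomes[[1]])
  gff <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(sim$genes, gff)
  skip_if_not_installed("rtracklayer")
  models <- read_gene_models_gff3(gff)
  expect_setequal(unique(models$gene_id), unique(sim$genes$gene_id))
  expect_equal(sum(models$type == "CDS"), sum(sim$genes$type == "CDS"))
})

test_that("F4 simulation is deterministic and Mendelian-sane", {
  a <- simulate_f4_bulks(small_cross_cfg(seed = 2L))
  b <- simulate_f4_bulks(small_cross_cfg(seed = 2L))
  expect_identical(a$calls, b$calls)
  expect_identical(a$pheno, b$pheno)
  # no selection in the full population: allele frequency near 0.5
  expect_lt(abs(mean(a$dosage) / 2 - 0.5), 0.08)
})

test_that("F4 heterozygosity approaches the selfing-series expectation 1/8", {
  sim <- simulate_f4_bulks(cross_sim_config(
    n = 250L, k = 5L, n_variants = 60L, chrom_length = 2e6, morgans = 0.5,
    qtl = data.frame(pos = 1e6, effect = 0), seed = 12L
  ))
  expect_lt(abs(mean(sim$dosage == 1L) - 1 / 8), 0.035)
})

test_that("a strong planted QTL drives the windowed delta peak to its position", {
  sim <- simulate_f4_bulks(small_cross_cfg(seed = 3L))
  ip <- delta_index(filter_variants(sim$calls))
  prof <- window_profile(ip, window_bp = 4e5, step_bp = 2e4)
  peak <- prof[which.max(prof$mean_delta), ]
  qtl_pos <- sim$truth$qtl$pos[1]
  expect_true(qtl_pos >= peak$window_start - 4e5 &&
                qtl_pos <= peak$window_end + 4e5)
  # bulks are truly extreme and homozygous: delta near 1 at the QTL
  at_qtl <- ip[which.min(abs(ip$pos - qtl_pos)), ]
  expect_gt(at_qtl$delta, 0.8)
})

test_that("observed bulk indices track the true bulk allele frequencies", {
  for (seed in c(4L, 6L)) {
    for (eff in c(1, 0)) {
      sim <- simulate_f4_bulks(small_cross_cfg(seed = seed, effect = eff))
      ip <- delta_index(filter_variants(sim$calls))
      p_h <- colMeans(sim$dosage[sim$bulks$hgwb, , drop = FALSE]) / 2
      p_l <- colMeans(sim$dosage[sim$bulks$lgwb, , drop = FALSE]) / 2
      truth_delta <- (p_h - p_l)[match(
        sim$loci$id[match(ip$pos, sim$loci$pos)], colnames(sim$dosage))]
      # only read-depth sampling noise separates observed from true delta
      expect_lt(mean(abs(ip$delta - truth_delta)), 0.06)
    }
  }
})

test_that("null-cross mean delta is centered across independent runs", {
  means <- vapply(1:6, function(s) {
    sim <- simulate_f4_bulks(small_cross_cfg(seed = 100L + s, effect = 0))
    mean(delta_index(filter_variants(sim$calls))$delta)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.3) # single-run drift reflects linkage blocks
  expect_true(any(means > 0) && any(means < 0))
})
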
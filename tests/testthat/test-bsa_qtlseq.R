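test_that("phenotype stats: CV and entry-mean heritability", {
  # identical replicates within individual: no error variance, H2 = 1
  ph <- data.frame(individual = rep(letters[1:5], each = 2),
                   value = rep(c(10, 12, 14, 16, 18), each = 2))
  st <- phenotype_stats(ph)
  expect_equal(st$H2, 1)
  expect_equal(st$mean, 14)
  expect_equal(st$cv, sd(c(10, 12, 14, 16, 18)) / 14)

  # constant trait: CV = 0
  flat <- data.frame(individual = rep(letters[1:4], each = 2), value = 5)
  expect_equal(phenotype_stats(flat)$cv, 0)

  expect_error(
    phenotype_stats(data.frame(individual = letters[1:4], value = 1:4)),
    "2 replicates"
  )
})

test_that("H2 recovers sigma2_g/(sigma2_g + sigma2_e/r) in simulation", {
  set.seed(404)
  n <- 400L
  g <- rnorm(n, 0, 1)          # sigma2_g = 1
  ph <- data.frame(
    individual = rep(sprintf("i%03d", 1:n), each = 2),
    value = rep(g, each = 2) + rnorm(2 * n, 0, 1) # sigma2_e = 1, r = 2
  )
  st <- phenotype_stats(ph)
  expect_equal(st$H2, 2 / 3, tolerance = 0.08)
})

test_that("1:1 segregation chi-square matches hand arithmetic", {
  s <- segregation_filter(c(50, 50))
  expect_equal(s$chi2, 0)
  expect_true(s$keep)
  s <- segregation_filter(c(80, 20))
  expect_equal(s$chi2, 36)     # (80-50)^2/50 + (20-50)^2/50
  expect_false(s$keep)
  s <- segregation_filter(c(60, 40))
  expect_equal(s$chi2, 4)
  expect_equal(s$p, pchisq(4, 1, lower.tail = FALSE)) # ~0.0455
  expect_false(s$keep)
  expect_error(segregation_filter(c(0, 0)), "zero total")
})

test_that("bulk selection takes homozygous extremes, skipping recombinants", {
  ids <- sprintf("i%02d", 1:12)
  trait <- setNames(c(30, 28, 26, 24, 22, 20, 18, 16, 14, 12, 10, 8), ids)
  geno <- matrix("A", 12, 2, dimnames = list(ids, c("m1", "m2")))
  geno[7:12, ] <- "B"
  geno["i02", "m1"] <- "H" # top-2 individual is heterozygous: skipped
  b <- select_bulks(trait, geno, c("m1", "m2"), k = 3)
  expect_equal(b$hgwb, c("i01", "i03", "i04"))
  expect_equal(b$lgwb, c("i12", "i11", "i10"))
  expect_error(select_bulks(trait, geno, c("m1", "m2"), k = 7),
               "insufficient eligible")
})

test_that("bulk selection matches brute-force enumeration on a small population", {
  set.seed(55)
  for (i in 1:10) {
    n <- 20L
    ids <- sprintf("x%02d", 1:n)
    trait <- setNames(rnorm(n), ids)
    geno <- matrix(sample(c("A", "B", "H"), n * 3, TRUE), n, 3,
                   dimnames = list(ids, paste0("m", 1:3)))
    hi_ok <- ids[apply(geno == "A", 1, all)]
    lo_ok <- ids[apply(geno == "B", 1, all)]
    k <- 2L
    if (length(hi_ok) < k || length(lo_ok) < k) next
    b <- select_bulks(trait, geno, paste0("m", 1:3), k = k)
    expect_setequal(b$hgwb, hi_ok[order(-trait[hi_ok])][1:k])
    expect_setequal(b$lgwb, lo_ok[order(trait[lo_ok])][1:k])
  }
})

test_that("variant filters flag depth, quality and monomorphic failures", {
  calls <- data.frame(
    seq_id = "c5", pos = 1:4 * 100, kind = "SNP",
    high_allele = c("A", "A", "A", "G"), low_allele = c("G", "G", "G", "G"),
    qual = c(30, 30, 19, 30),
    hb_hi = c(18, 5, 20, 20), hb_lo = c(2, 3, 5, 5),
    lb_hi = c(1, 10, 2, 2), lb_lo = c(19, 10, 20, 20)
  )
  f <- filter_variants(calls)
  expect_equal(f$filter_status, c("PASS", "FAIL", "FAIL", "FAIL"))
  expect_equal(f$fail_reason, c(NA, "depth", "quality", "monomorphic"))
  # boundary: depth exactly 10 and quality exactly 20 pass
  edge <- filter_variants(data.frame(
    seq_id = "c5", pos = 1, kind = "SNP", high_allele = "A",
    low_allele = "G", qual = 20, hb_hi = 7, hb_lo = 3, lb_hi = 5, lb_lo = 5
  ))
  expect_equal(edge$filter_status, "PASS")
})

test_that("bulk index is the high-parent read fraction with 'other' excluded", {
  expect_equal(bulk_index(18, 2), 0.9)
  expect_equal(bulk_index(0, 15), 0)
  expect_equal(bulk_index(15, 0), 1)
  expect_equal(bulk_index(12, 6), 12 / 18) # stutter reads not counted
  expect_true(is.na(bulk_index(0, 0)))
})

test_that("delta index subtracts low-bulk from high-bulk index", {
  calls <- data.frame(
    seq_id = "c5", pos = c(100, 200, 300), kind = "SNP",
    high_allele = "A", low_allele = "G", qual = 30,
    hb_hi = c(18, 10, 20), hb_lo = c(2, 10, 0),
    lb_hi = c(2, 10, 0), lb_lo = c(18, 10, 20)
  )
  ip <- delta_index(calls)
  expect_equal(ip$delta, c(0.8, 0, 1))
  expect_true(all(ip$index_hgwb >= 0 & ip$index_hgwb <= 1))
  expect_true(all(abs(ip$delta) <= 1))
})

test_that("window means equal a brute-force recomputation", {
  set.seed(61)
  pts <- data.frame(
    seq_id = "c5", pos = sort(sample.int(50000, 50)), kind = "SNP",
    index_hgwb = runif(50), index_lgwb = runif(50), depth = 100
  )
  pts$delta <- pts$index_hgwb - pts$index_lgwb
  for (min_v in c(1L, 3L)) {
    prof <- window_profile(pts, window_bp = 5000, step_bp = 1000,
                           min_variants = min_v)
    want <- oracle_window_means(pts, 5000, 1000, min_v)
    expect_equal(prof$mean_delta, want)
  }
  one <- pts[1, ]
  prof1 <- window_profile(one, 5000, 1000, min_variants = 1L)
  expect_equal(prof1$mean_delta[!is.na(prof1$mean_delta)][1], one$delta)
  # sparse window is undefined, not zero
  prof3 <- window_profile(pts, 5000, 1000, min_variants = 51L)
  expect_true(all(is.na(prof3$mean_delta)))
  expect_error(window_profile(pts, 1000, 5000), "at least as large")
})

test_that("null simulation is symmetric with nested, depth-monotone bounds", {
  ci <- null_ci(k = 10, g = 4, depths = c(20, 200), levels = c(0.95, 0.99),
                R = 20000, seed = 31)
  for (d in c(20, 200)) {
    b95 <- ci[ci$depth == d & ci$level == 0.95, ]
    b99 <- ci[ci$depth == d & ci$level == 0.99, ]
    expect_lt(b99$lower, b95$lower)
    expect_gt(b99$upper, b95$upper)
    expect_lt(abs(b95$upper + b95$lower), 0.03) # symmetric about 0
  }
  w20 <- with(ci[ci$depth == 20 & ci$level == 0.99, ], upper - lower)
  w200 <- with(ci[ci$depth == 200 & ci$level == 0.99, ], upper - lower)
  expect_gt(w20, w200) # more reads, tighter null band
  ci_k <- null_ci(k = 40, g = 4, depths = 100, levels = 0.99, R = 20000,
                  seed = 32)
  ci_k5 <- null_ci(k = 5, g = 4, depths = 100, levels = 0.99, R = 20000,
                   seed = 33)
  expect_gt(with(ci_k5, upper - lower), with(ci_k, upper - lower))
  set.seed(34)
  expect_lt(abs(mean(simulate_null_deltas(10, 4, 100, 20000))), 0.005)
})

test_that("null bounds agree with an independent loop-based simulation", {
  ci <- null_ci(k = 20, g = 2, depths = 100, levels = 0.95, R = 20000,
                seed = 71)
  set.seed(172) # different seed stream for the oracle
  ora <- quantile(oracle_null_deltas(20, 2, 100, 20000), c(0.025, 0.975))
  expect_lt(abs(ci$lower - ora[[1]]), 0.02)
  expect_lt(abs(ci$upper - ora[[2]]), 0.02)
})

test_that("CI interpolation is piecewise linear with clamped extremes", {
  ci <- structure(
    data.frame(depth = c(10, 20), level = 0.99, lower = c(-0.8, -0.6),
               upper = c(0.8, 0.6)),
    class = c("null_ci_table", "data.frame")
  )
  b <- ci_bounds_at_depth(ci, c(5, 15, 100), 0.99)
  expect_equal(b$upper, c(0.8, 0.7, 0.6))
  expect_equal(b$lower, c(-0.8, -0.7, -0.6))
  expect_error(ci_bounds_at_depth(ci, 10, 0.95), "not present")
})

test_that("QTL calling merges overlapping runs and honors gaps", {
  ci <- structure(
    data.frame(depth = 100, level = 0.99, lower = -0.3, upper = 0.3),
    class = c("null_ci_table", "data.frame")
  )
  prof <- data.frame(
    window_start = seq(0, 9000, 1000), window_end = seq(3000, 12000, 1000),
    n = 5, mean_delta = c(0.5, 0.6, 0.5, 0, 0, 0, 0, 0, 0.5, 0.4),
    mean_index_hgwb = 0.5, mean_index_lgwb = 0.1, mean_depth = 100
  )
  pts <- data.frame(pos = seq(100, 11900, 200))
  iv <- call_qtl_intervals(prof, ci, pts, seq_id = "c5")
  expect_equal(nrow(iv), 2L) # windows 1-3 overlap; 9-10 form a second run
  expect_equal(iv$direction, c("high", "high"))
  expect_equal(iv$span_bp, iv$end - iv$start)
  # an undefined window between significant ones breaks the run
  prof2 <- prof
  prof2$mean_delta <- c(0.5, NA, 0.5, rep(0, 7))
  prof2$n[2] <- 1
  iv2 <- call_qtl_intervals(prof2, ci, pts, seq_id = "c5")
  expect_equal(nrow(iv2), 2L)
  # flat zero profile: nothing
  prof$mean_delta[] <- 0
  expect_equal(nrow(call_qtl_intervals(prof, ci, pts)), 0L)
  expect_equal(nrow(call_qtl_intervals(prof[0, ], ci, pts)), 0L)
})

test_that("interval spans use the printed end-minus-start convention", {
  expect_equal(interval_length(6827053, 10790507), 3963454)
  expect_equal(interval_length(8958147, 10792507), 1834360)
  expect_equal(interval_length(5, 6), 1)
  expect_error(interval_length(10, 10), "below end")
})
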
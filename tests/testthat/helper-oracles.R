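# Independent brute-force oracles used by the property tests. These stay
# deliberately naive (regex scans, explicit loops) and separate from the
# package's implementations.

oracle_primitive <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L &&
        paste(rep(substr(unit, 1, p), n / p), collapse = "") == unit) {
      return(p)
    }
  }
  n
}

oracle_canonical <- function(unit) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(unit, "")[[1]]), collapse = ""))
  forms <- character(0)
  for (u in c(unit, rc)) {
    k <- nchar(u)
    for (i in seq_len(k)) {
      forms <- c(forms, paste0(substr(u, i, k), substr(u, 1, i - 1)))
    }
  }
  min(forms)
}

# regex-based maximal perfect tandem-repeat scan, one motif class at a time.
# A zero-width lookahead finds greedy whole-unit matches at every start
# (adjacent tracts may overlap by up to period-1 bases), then an explicit
# maximality filter keeps only tracts whose perfect run cannot extend left.
oracle_find_ssrs <- function(sequence, seq_id = "seq",
                             min_repeats = c(di = 6L, tri = 5L, tetra = 5L,
                                             penta = 5L, hexa = 5L)) {
  cls <- c("di", "tri", "tetra", "penta", "hexa")
  rows <- list()
  for (p in 2:6) {
    minrep <- min_repeats[[cls[p - 1L]]]
    pat <- sprintf("(?=(([ACGT]{%d})\\2{%d,}))", p, minrep - 1L)
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    cs <- attr(m, "capture.start")[, 1L]
    cl <- attr(m, "capture.length")[, 1L]
    for (idx in seq_along(cs)) {
      s <- cs[idx]
      count <- cl[idx] %/% p
      unit <- substr(sequence, s, s + p - 1L)
      if (oracle_primitive(unit) != p) next
      # explicit maximal-match check: drop starts whose run extends left
      if (s > 1L && substr(sequence, s - 1L, s - 1L) ==
            substr(sequence, s - 1L + p, s - 1L + p)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, start = s, end = s + count * p - 1L,
        motif = oracle_canonical(unit),
        motif_class = cls[p - 1L], repeat_count = count, tract_bp = count * p,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      motif_class = character(), repeat_count = integer(),
                      tract_bp = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random test sequence enriched with planted repeat structures: boundary
# counts, homopolymers, N stretches, adjacent tracts
random_ssr_test_seq <- function(len = 2000L) {
  bases <- c("A", "C", "G", "T")
  pieces <- character(0)
  total <- 0L
  while (total < len) {
    kind <- sample(c("bg", "ssr", "homo", "n"), 1L,
                   prob = c(0.45, 0.4, 0.1, 0.05))
    piece <- if (kind == "bg") {
      paste(sample(bases, sample(30:120, 1L), replace = TRUE), collapse = "")
    } else if (kind == "ssr") {
      p <- sample(2:6, 1L)
      u <- paste(sample(bases, p, replace = TRUE), collapse = "")
      strrep(u, sample(3:12, 1L))
    } else if (kind == "homo") {
      strrep(sample(bases, 1L), sample(8:20, 1L))
    } else {
      strrep("N", sample(2:10, 1L))
    }
    pieces <- c(pieces, piece)
    total <- total + nchar(piece)
  }
  substr(paste(pieces, collapse = ""), 1L, len)
}

# brute-force per-window recomputation for window_profile
oracle_window_means <- function(points, window_bp, step_bp, min_variants) {
  last <- max(points$pos)
  starts <- seq(0, max(0, last - 1), by = step_bp)
  vapply(starts, function(s) {
    sel <- points$pos >= s & points$pos < s + window_bp
    if (sum(sel) < min_variants) return(NA_real_)
    mean(points$delta[sel])
  }, numeric(1))
}

# second, loop-based implementation of the null delta simulation
oracle_null_deltas <- function(k, g, depth, R) {
  h <- 0.5^(g - 1)
  out <- numeric(R)
  for (r in seq_len(R)) {
    idx <- numeric(2)
    for (b in 1:2) {
      geno <- sample(c(0, 1, 2), k, replace = TRUE,
                     prob = c((1 - h) / 2, h, (1 - h) / 2))
      p <- sum(geno) / (2 * k)
      idx[b] <- rbinom(1, depth, p) / depth
    }
    out[r] <- idx[1] - idx[2]
  }
  out
}

# pairwise enumeration oracle for polymorphism category labels
oracle_categories <- function(tracts, populations) {
  obs <- tracts[!is.na(tracts)]
  if (length(obs) < 2) return(character())
  prs <- t(utils::combn(names(obs), 2))
  labs <- character(0)
  for (r in seq_len(nrow(prs))) {
    a <- prs[r, 1]; b <- prs[r, 2]
    if (obs[[a]] == obs[[b]]) next
    pa <- populations[[a]]; pb <- populations[[b]]
    labs <- c(labs, if (pa == pb) paste0("within:", pa) else
      paste0("between:", min(pa, pb), ":", max(pa, pb)))
  }
  sort(unique(labs))
}

# small deterministic gene-model fixture covering all five contexts
fixture_gene_models <- function() {
  rbind(
    data.frame(gene_id = "g1", seq_id = "chr1", strand = "+", type = "gene",
               start = 3001, end = 4020, stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", seq_id = "chr1", strand = "+",
               type = c("five_prime_UTR", "CDS", "intron", "CDS",
                        "three_prime_UTR"),
               start = c(3001, 3151, 3451, 3571, 3871),
               end = c(3150, 3450, 3570, 3870, 4020),
               stringsAsFactors = FALSE)
  )
}
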
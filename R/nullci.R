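#' Simulate null delta-index values for one read depth
#'
#' Generative model under the null hypothesis of no QTL: each bulk samples k
#' individuals from an F_g selfed biparental population, where a locus is
#' heterozygous with probability h = (1/2)^(g-1) and each homozygote has
#' probability (1-h)/2. The bulk high-allele frequency is
#' p = (2 n_hom_high + n_het) / (2k); the observed index is
#' Binomial(depth, p)/depth reads, and delta is the difference of the two
#' independent bulk indices.
#'
#' @param k Bulk size (individuals per bulk).
#' @param g Selfing generation (g = 4 for an F4; F1 is g = 1).
#' @param depth Read depth per bulk at the variant.
#' @param R Number of replicate draws.
#' @return Numeric vector of R simulated delta values.
#' @export
simulate_null_deltas <- function(k, g, depth, R) {
  if (k < 1L) stop("bulk size k must be >= 1")
  if (g < 2L) stop("generation g must be >= 2")
  if (depth < 1L) stop("depth must be >= 1")
  h <- 0.5^(g - 1)
  one_bulk <- function() {
    n_het <- stats::rbinom(R, k, h)
    n_hh <- stats::rbinom(R, k - n_het, 0.5)
    p <- (2 * n_hh + n_het) / (2 * k)
    stats::rbinom(R, depth, p) / depth
  }
  one_bulk() - one_bulk()
}

#' Monte-Carlo null confidence intervals for the delta-index
#'
#' Two-sided empirical quantile bounds of the null delta-index distribution
#' as a function of read depth, under no QTL (see
#' [simulate_null_deltas()] for the generative model). Used to judge the
#' significance of observed delta values at their local read depth.
#'
#' @param k Bulk size.
#' @param g Selfing generation (default 4, an F4 population).
#' @param depths Read-depth grid to simulate.
#' @param levels Confidence levels (default 0.95 and 0.99).
#' @param R Replicates per depth (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return data.frame of class `null_ci_table`: depth, level, lower, upper;
#'   simulation parameters in attributes.
#' @export
null_ci <- function(k, g = 4L, depths = c(20, 40, 60, 80, 100, 150, 200),
                    levels = c(0.95, 0.99), R = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (d in sort(depths)) {
    delta <- simulate_null_deltas(k, g, d, R)
    for (lv in levels) {
      qs <- stats::quantile(delta, probs = c((1 - lv) / 2, (1 + lv) / 2),
                            names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        depth = d, level = lv, lower = qs[1], upper = qs[2]
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "k") <- k
  attr(out, "g") <- g
  attr(out, "R") <- R
  attr(out, "seed") <- seed
  class(out) <- c("null_ci_table", class(out))
  out
}

#' Interpolate null CI bounds at a given depth
#'
#' Piecewise-linear interpolation across the simulated depth grid; depths
#' beyond the grid clamp to the nearest simulated entry.
#'
#' @param ci A [null_ci()] table.
#' @param depth Read depth(s) at which to evaluate the bounds.
#' @param level Confidence level present in the table.
#' @return data.frame(depth, lower, upper).
#' @export
ci_bounds_at_depth <- function(ci, depth, level = 0.99) {
  tab <- ci[abs(ci$level - level) < 1e-9, , drop = FALSE]
  if (nrow(tab) == 0L) stop("level ", level, " not present in CI table")
  if (nrow(tab) == 1L) {
    return(data.frame(depth = depth, lower = tab$lower, upper = tab$upper))
  }
  lo <- stats::approx(tab$depth, tab$lower, xout = depth, rule = 2)$y
  up <- stats::approx(tab$depth, tab$upper, xout = depth, rule = 2)$y
  data.frame(depth = depth, lower = lo, upper = up)
}

#' Call QTL intervals from a window profile against null bounds
#'
#' A window is significant when its mean delta falls outside the null
#' bounds interpolated to the window's mean depth. Maximal runs of
#' spatially overlapping significant windows are merged into one interval;
#' undefined windows (too few variants) lying between significant windows
#' break runs. Interval ends are the outermost PASS variant positions
#' inside the run span; span_bp uses the printed-span convention
#' end - start. Direction follows the sign of the peak window delta
#' ("high" = high-parent allele increases the trait).
#'
#' @param profile Window profile from [window_profile()].
#' @param ci Null CI table from [null_ci()].
#' @param points Per-variant index table (PASS variants) used to trim
#'   interval ends to observed variants.
#' @param level Confidence level (default 0.99).
#' @param seq_id Chromosome id recorded in the output.
#' @return data.frame: seq_id, start, end, span_bp, peak_start, peak_delta,
#'   direction, level, n_windows. Zero rows when nothing is significant.
#' @export
call_qtl_intervals <- function(profile, ci, points, level = 0.99,
                               seq_id = "chr") {
  empty <- data.frame(
    seq_id = character(), start = numeric(), end = numeric(),
    span_bp = numeric(), peak_start = numeric(), peak_delta = numeric(),
    direction = character(), level = numeric(), n_windows = integer(),
    stringsAsFactors = FALSE
  )
  if (nrow(profile) == 0L) return(empty)
  defined <- !is.na(profile$mean_delta)
  sig <- rep(FALSE, nrow(profile))
  if (any(defined)) {
    b <- ci_bounds_at_depth(ci, profile$mean_depth[defined], level)
    sig[defined] <- profile$mean_delta[defined] > b$upper |
      profile$mean_delta[defined] < b$lower
  }
  idx <- which(sig)
  if (length(idx) == 0L) return(empty)

  # group overlapping significant windows; undefined windows in between break
  runs <- list()
  cur <- idx[1L]
  if (length(idx) > 1L) {
    for (i in idx[-1L]) {
      prev <- cur[length(cur)]
      overlaps <- profile$window_start[i] < profile$window_end[prev]
      gap_undef <- (i - prev > 1L) && any(!defined[(prev + 1L):(i - 1L)])
      if (overlaps && !gap_undef) {
        cur <- c(cur, i)
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- i
      }
    }
  }
  runs[[length(runs) + 1L]] <- cur

  pos <- sort(points$pos)
  rows <- lapply(runs, function(rn) {
    span_from <- min(profile$window_start[rn])
    span_to <- max(profile$window_end[rn])
    inside <- pos[pos >= span_from & pos < span_to]
    if (length(inside) < 2L) return(NULL)
    # delta saturates at |1| over a linkage plateau around a strong QTL;
    # take the middle of the tied-maximum stretch as the peak estimate
    vals <- abs(profile$mean_delta[rn])
    tied <- rn[vals >= max(vals) - 1e-9]
    peak <- tied[ceiling(length(tied) / 2)]
    data.frame(
      seq_id = seq_id, start = min(inside), end = max(inside),
      span_bp = max(inside) - min(inside),
      peak_start = profile$window_start[peak],
      peak_delta = profile$mean_delta[peak],
      direction = if (profile$mean_delta[peak] > 0) "high" else "low",
      level = level, n_windows = length(rn), stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
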
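#' Polymorphism information content (PIC)
#'
#' Botstein three-term formulation:
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2, the convention of
#' standard marker-genotyping software. Optionally the simpler expected
#' heterozygosity form 1 - sum(p_i^2).
#'
#' @param p Allele frequencies (non-negative, summing to 1 within 1e-9).
#' @param method "botstein" (default) or "het".
#' @return PIC value in [0, 1).
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
#' @export
pic <- function(p, method = c("botstein", "het")) {
  method <- match.arg(method)
  if (any(p < 0)) stop("allele frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  s2 <- sum(p^2)
  if (method == "het") return(1 - s2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Nei-Li distance between two marker profiles
#'
#' Treats each (marker, allele) as a band/fragment. With single allele calls
#' per marker, similarity S = 2 n_xy / (n_x + n_y) where n_xy is the number
#' of markers with identical alleles and n_x, n_y count fragments in each
#' profile; distance = 1 - S. Markers missing (NA) in either profile are
#' excluded from all three counts.
#'
#' @param a,b Allele-call vectors over the same marker set (position-aligned;
#'   values are tract lengths in bp or allele symbols; NA = missing).
#' @return Distance in [0, 1].
#' @export
nei_li_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must cover the same marker set")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no comparable fragments between the two profiles")
  n_x <- sum(ok)
  n_y <- sum(ok)
  n_xy <- sum(a[ok] == b[ok])
  1 - 2 * n_xy / (n_x + n_y)
}

#' Pairwise Nei-Li distance matrix from a genotype table
#'
#' @param genotypes markers x accessions matrix (NA = missing call); pairwise
#'   deletion per marker.
#' @return A `dist` object over accessions.
#' @export
nei_li_dist <- function(genotypes) {
  if (is.data.frame(genotypes)) genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) < 2L) stop("need at least 2 accessions")
  accs <- colnames(genotypes)
  n <- ncol(genotypes)
  d <- matrix(0, n, n, dimnames = list(accs, accs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- nei_li_distance(genotypes[, i], genotypes[, j])
    }
  }
  stats::as.dist(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via ape), returned unrooted.
#' Negative branch lengths, which NJ can produce on non-additive input, are
#' clamped to zero with the negative length transferred to the sister edge
#' so path lengths through the parent node are preserved.
#'
#' @param d Symmetric distance matrix (or `dist`) over >= 3 taxa, zero
#'   diagonal, non-negative entries.
#' @param clamp_negative Clamp negative branch lengths (default TRUE).
#' @return An `ape::phylo` tree with branch lengths.
#' @export
build_nj_tree <- function(d, clamp_negative = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix or dist")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is asymmetric")
  if (any(d < -1e-12)) stop("distances must be non-negative")
  tree <- ape::nj(stats::as.dist(d))
  if (clamp_negative && any(tree$edge.length < 0)) {
    for (e in which(tree$edge.length < 0)) {
      parent <- tree$edge[e, 1L]
      sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
      if (length(sisters)) {
        s <- sisters[1L]
        tree$edge.length[s] <- tree$edge.length[s] + tree$edge.length[e]
      }
      tree$edge.length[e] <- 0
    }
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

#' Write a tree in Newick format
#'
#' @param tree `ape::phylo` object.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
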
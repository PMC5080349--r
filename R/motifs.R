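#' Motif-class name for a repeat unit length
#'
#' @param period Integer repeat-unit length (2-6).
#' @return One of "di", "tri", "tetra", "penta", "hexa".
#' @export
motif_class_name <- function(period) {
  nm <- c(`2` = "di", `3` = "tri", `4` = "tetra", `5` = "penta", `6` = "hexa")
  out <- nm[as.character(period)]
  if (anyNA(out)) stop("repeat-unit length must be 2-6 bases")
  unname(out)
}

# smallest p such that unit is a whole-number repetition of its first p bases
primitive_period <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    if (paste(rep(substr(unit, 1L, p), n %/% p), collapse = "") == unit) {
      return(p)
    }
  }
  n
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Canonical form of an SSR repeat motif
#'
#' Two tracts of the same microsatellite can be written with any cyclic
#' rotation of the unit and on either strand (e.g. "TG", "GT", "CA", "AC" all
#' describe one dinucleotide repeat). The canonical form is the
#' lexicographically smallest string among all cyclic rotations of the unit
#' and of its reverse complement, so the same tract is reported identically
#' regardless of phase or strand.
#'
#' @param unit Repeat unit, 2-6 uppercase ACGT bases, primitive (not itself a
#'   repetition of a shorter unit; homopolymer-like units are rejected).
#' @return Canonical motif string of the same length as `unit`.
#' @examples
#' canonical_motif("TG")   # "CA"
#' canonical_motif("AAG")  # "AAG"
#' @export
canonical_motif <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit)) {
    stop("unit must be a single character string")
  }
  n <- nchar(unit)
  if (n < 2L || n > 6L) stop("repeat-unit length must be 2-6 bases")
  if (grepl("[^ACGT]", unit)) stop("unit must contain only A, C, G, T")
  if (primitive_period(unit) < 2L) {
    stop("unsupported motif: homopolymer unit '", unit, "'")
  }
  if (primitive_period(unit) < n) {
    stop("unsupported motif: '", unit, "' reduces to a shorter period")
  }
  rots <- function(u) {
    k <- nchar(u)
    vapply(seq_len(k), function(i) {
      paste0(substr(u, i, k), substr(u, 1L, i - 1L))
    }, character(1))
  }
  min(c(rots(unit), rots(revcomp_chr(unit))))
}
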
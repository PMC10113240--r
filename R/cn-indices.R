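#' Allele-specific ploidy (asP)
#'
#' The segment-length-weighted mean of total allele-specific copy number,
#' `sum((cnA + cnB) * w) / sum(w)` with `w` the segment length in bases. It
#' is proportional to the average DNA content per cell: 2 for a purely
#' diploid genome, 3 for a uniformly triploid one.
#'
#' @param profile A [segment_profile()].
#' @return The asP value (scalar).
#' @export
compute_asP <- function(profile) {
  stopifnot(inherits(profile, "segment_profile"))
  seg <- profile$segments
  if (nrow(seg) == 0) stop("cannot compute asP on an empty profile")
  w <- seg$end - seg$start
  sum((seg$cnA + seg$cnB) * w) / sum(w)
}

#' Genomic burden (GB)
#'
#' The length-weighted fraction of the genome whose allele-specific copy
#' state differs from the wild-type `(cnA, cnB) = (1, 1)`. By construction,
#' uniformly triploid or tetraploid genomes have GB = 1, and a fully diploid
#' genome has GB = 0.
#'
#' @param profile A [segment_profile()].
#' @return A fraction in `[0, 1]`.
#' @export
compute_gb <- function(profile) {
  stopifnot(inherits(profile, "segment_profile"))
  seg <- profile$segments
  if (nrow(seg) == 0) stop("cannot compute genomic burden on an empty profile")
  w <- seg$end - seg$start
  aberrant <- seg$cnA != 1 | seg$cnB != 1
  sum(w[aberrant]) / sum(w)
}
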
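# DM frequency from metabolizer-group or allele frequencies.

#' Construct a three-group metabolizer distribution
#'
#' Frequencies of the extensive-metabolizer (EM), heterozygote-extensive/
#' intermediate (hetEM/IM) and poor-metabolizer (PM) groups; they must be
#' non-negative and sum to 1. Pass counts and set `counts = TRUE` to
#' normalize, e.g. the genotyped cohort counts (609, 637, 79).
#'
#' @param f_em,f_het_im,f_pm Group frequencies (or counts).
#' @param counts If `TRUE`, inputs are counts and are normalized by
#'   their total.
#' @return An object of class `metabolizer_distribution`.
#' @export
#' @examples
#' metabolizer_distribution(0.460, 0.481, 0.059)
#' metabolizer_distribution(609, 637, 79, counts = TRUE)
metabolizer_distribution <- function(f_em, f_het_im, f_pm, counts = FALSE) {
  v <- c(f_em = f_em, f_het_im = f_het_im, f_pm = f_pm)
  if (anyNA(v) || any(v < 0)) {
    stop("frequencies must be non-negative and non-missing")
  }
  if (counts) v <- v / sum(v)
  if (abs(sum(v) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (got ", format(sum(v)),
         "); pass counts = TRUE to normalize counts")
  }
  structure(as.list(v), class = "metabolizer_distribution")
}

#' @export
print.metabolizer_distribution <- function(x, ...) {
  cat(sprintf("<metabolizer_distribution> EM %.3f, hetEM/IM %.3f, PM %.3f\n",
              x$f_em, x$f_het_im, x$f_pm))
  invisible(x)
}

#' DM frequency from a metabolizer distribution
#'
#' The decreased-metabolizer (DM) group pools hetEM/IM and PM, so
#' `f.DM = f_het_im + f_pm`.
#'
#' @param dist A [metabolizer_distribution()].
#' @return The DM frequency.
#' @export
#' @examples
#' dm_frequency(metabolizer_distribution(0.460, 0.481, 0.059))
dm_frequency <- function(dist) {
  stopifnot(inherits(dist, "metabolizer_distribution"))
  dist$f_het_im + dist$f_pm
}

#' DM frequency implied by Hardy-Weinberg equilibrium
#'
#' A Hardy-Weinberg reconstruction of the DM frequency from the combined
#' frequency `q` of reduced-function alleles: any genotype carrying at
#' least one reduced-function allele is DM, so
#' `f.DM = 1 - (1 - q)^2`. This is a reconstruction of how plausible
#' bounds on f.DM follow from allele-frequency catalogs; the pipeline's
#' default f.DM is always the directly observed 0.54, never this output.
#'
#' @param q Combined reduced-function allele frequency (vectorized),
#'   each in `[0, 1]`.
#' @return The implied DM frequency, monotone increasing in `q`.
#' @export
#' @examples
#' dm_frequency_hwe(c(0.10, 0.30, 0.40))
dm_frequency_hwe <- function(q) {
  q <- as.numeric(q)
  bad <- is.na(q) | q < 0 | q > 1
  if (any(bad)) {
    stop("allele frequency out of [0, 1]: ",
         paste(format(q[bad]), collapse = ", "))
  }
  1 - (1 - q)^2
}
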
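#' Allele-frequency power sums
#'
#' The moments \eqn{a_m = \sum_i p_i^m} for m = 2..6, the building blocks of
#' all non-exclusion formulas.
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @return named numeric \code{c(a2, a3, a4, a5, a6)}.
#' @export
allele_moments <- function(freqs) {
  .check_freqs(freqs)
  stats::setNames(vapply(2:6, function(m) sum(freqs^m), numeric(1)),
                  paste0("a", 2:6))
}

.check_freqs <- function(freqs) {
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 1) ||
      abs(sum(freqs) - 1) > 1e-9)
    stop("degenerate allele frequencies")
  invisible(freqs)
}

#' Per-locus non-exclusion probability of identity
#'
#' The probability that two unrelated individuals drawn from a population in
#' Hardy-Weinberg equilibrium carry the same genotype at the locus:
#' \deqn{Q_I = \sum_g P(g)^2 = 2 a_2^2 - a_4.}
#' Callers are responsible for testing HWE beforehand.
#'
#' @inheritParams allele_moments
#' @return probability in (0, 1].
#' @export
ne_identity <- function(freqs) {
  a <- allele_moments(freqs)
  unname(2 * a["a2"]^2 - a["a4"])
}

#' Per-locus non-exclusion probability for the first parent
#'
#' One minus the single-parent exclusion power: the probability that a random
#' unrelated individual cannot be excluded as the parent of a random offspring
#' when the other parent is unknown,
#' \deqn{1 - E_1, \quad E_1 = 1 - 4a_2 + 2a_2^2 + 4a_3 - 3a_4,}
#' which for a biallelic locus reduces to \eqn{1 - 2 p^2 q^2}.
#'
#' @inheritParams allele_moments
#' @return probability in (0, 1].
#' @export
ne_first_parent <- function(freqs) {
  a <- allele_moments(freqs)
  unname(1 - (1 - 4 * a["a2"] + 2 * a["a2"]^2 + 4 * a["a3"] - 3 * a["a4"]))
}

#' Per-locus non-exclusion probability for the second parent
#'
#' One minus the exclusion power for a candidate parent when the genotype of
#' the true other parent is known,
#' \deqn{E_2 = 1 - 2a_2 + a_3 + 3(a_2 a_3 - a_5) - 2(a_2^2 - a_4).}
#' Provided for completeness alongside the first-parent and parent-pair
#' probabilities.
#'
#' @inheritParams allele_moments
#' @return probability in (0, 1].
#' @export
ne_second_parent <- function(freqs) {
  a <- allele_moments(freqs)
  unname(1 - (1 - 2 * a["a2"] + a["a3"] + 3 * (a["a2"] * a["a3"] - a["a5"]) -
                2 * (a["a2"]^2 - a["a4"])))
}

#' Per-locus non-exclusion probability for a parent pair
#'
#' One minus the exclusion power when a candidate parent pair is jointly
#' compared with an offspring,
#' \deqn{E_3 = 1 + 4a_4 - 4a_5 - 3a_6 - 8a_2^2 + 8 a_2 a_3 + 2 a_3^2.}
#'
#' @inheritParams allele_moments
#' @return probability in (0, 1].
#' @export
ne_parent_pair <- function(freqs) {
  a <- allele_moments(freqs)
  unname(1 - (1 + 4 * a["a4"] - 4 * a["a5"] - 3 * a["a6"] - 8 * a["a2"]^2 +
                8 * a["a2"] * a["a3"] + 2 * a["a3"]^2))
}

#' Combine per-locus non-exclusion probabilities across a panel
#'
#' Loci are assumed independent, so the panel-wide probability is the product.
#'
#' @param per_locus numeric vector of per-locus probabilities in (0, 1].
#' @return the product.
#' @export
combine_ne <- function(per_locus) {
  if (!length(per_locus)) stop("empty probability list")
  if (any(per_locus <= 0 | per_locus > 1)) stop("probabilities must lie in (0, 1]")
  prod(per_locus)
}

#' Panel non-exclusion summary
#'
#' Computes per-locus and combined non-exclusion probabilities for identity,
#' first parent and parent pair from the allele frequencies of the supplied
#' table.  Frequencies should come from individuals sampled without regard to
#' family (family-based sampling biases them).
#'
#' @param table a \code{genotype_table}.
#' @return a list with a per-locus data.frame and the three combined values.
#' @export
exclusion_summary <- function(table) {
  ids <- colnames(table$calls)
  per <- do.call(rbind, lapply(ids, function(m) {
    af <- allele_frequencies(table, m)
    p <- c(af$p_w, af$p_v)
    data.frame(marker_id = m,
               ne_identity = ne_identity(p),
               ne_first_parent = ne_first_parent(p),
               ne_second_parent = ne_second_parent(p),
               ne_parent_pair = ne_parent_pair(p),
               stringsAsFactors = FALSE)
  }))
  list(per_locus = per,
       combined_ne_identity = combine_ne(per$ne_identity),
       combined_ne_first_parent = combine_ne(per$ne_first_parent),
       combined_ne_second_parent = combine_ne(per$ne_second_parent),
       combined_ne_parent_pair = combine_ne(per$ne_parent_pair))
}
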
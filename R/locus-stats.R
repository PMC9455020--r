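#' Per-locus allele frequencies
#'
#' Counts alleles among non-missing calls: the variant-allele frequency is
#' \eqn{p_V = (2 n_{VV} + n_{WV}) / (2 n)} with \eqn{n} the number of typed
#' individuals at the locus (complete-case per locus).
#'
#' @param table a \code{genotype_table}.
#' @param marker_id a marker column name.
#' @return a list with \code{p_w}, \code{p_v} and \code{n_typed}.
#' @export
allele_frequencies <- function(table, marker_id) {
  g <- .marker_col(table, marker_id)
  g <- g[!is.na(g)]
  if (!length(g)) stop("monomorphic-undefined: no typed individuals at ", marker_id)
  p_v <- sum(g) / (2 * length(g))
  list(p_w = 1 - p_v, p_v = p_v, n_typed = length(g))
}

.marker_col <- function(table, marker_id) {
  if (!marker_id %in% colnames(table$calls)) stop("unknown marker: ", marker_id)
  table$calls[, marker_id]
}

#' Observed and expected heterozygosity at a locus
#'
#' \eqn{H_o} is the fraction of heterozygous individuals among those typed.
#' \eqn{H_e} is the gene diversity \eqn{1 - p_W^2 - p_V^2} with, by default,
#' the small-sample correction \eqn{2n/(2n-1)} (the unbiased estimator used by
#' standard parentage software).
#'
#' @inheritParams allele_frequencies
#' @param unbiased apply the \eqn{2n/(2n-1)} correction (default) or return
#'   the plug-in gene diversity.
#' @return a list with \code{ho} and \code{he}.
#' @export
heterozygosities <- function(table, marker_id, unbiased = TRUE) {
  g <- .marker_col(table, marker_id)
  g <- g[!is.na(g)]
  n <- length(g)
  if (n < 2) stop("need at least 2 typed individuals at ", marker_id)
  p <- sum(g) / (2 * n)
  gd <- 1 - p^2 - (1 - p)^2
  list(ho = mean(g == 1L), he = if (unbiased) 2 * n / (2 * n - 1) * gd else gd)
}

#' Polymorphic information content
#'
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}
#'
#' @param freqs numeric vector of allele frequencies summing to 1 (two entries
#'   for a biallelic locus).
#' @return PIC in [0, 1].
#' @export
pic <- function(freqs) {
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("allele frequencies must be non-negative and sum to 1")
  k <- length(freqs)
  cross <- 0
  if (k >= 2)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      cross <- cross + 2 * freqs[i]^2 * freqs[j]^2
  1 - sum(freqs^2) - cross
}

#' Bonferroni adjustment
#'
#' \code{min(1, p * m)} with \code{m = length(p)}, preserving order.  Thin,
#' explicit wrapper so panel reports state the correction used.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Exact and Markov-chain Hardy-Weinberg tests for a biallelic locus
#'
#' The exact test conditions on the observed allele counts and sums the
#' probabilities of all heterozygote counts whose conditional probability does
#' not exceed that of the observed configuration (Haldane/Levene conditional
#' distribution).  The \code{mcmc} method estimates the same tail by a seeded
#' Metropolis chain over heterozygote counts with the classic
#' dememorisation/batch/iteration schedule, and also reports a batch standard
#' error.  A monomorphic locus is degenerate: p = 1 with attribute
#' \code{degenerate}.
#'
#' @inheritParams allele_frequencies
#' @param method \code{"exact_enumeration"} (default) or \code{"mcmc"}.
#' @param dememorization,batches,iterations chain schedule for \code{mcmc}.
#' @param seed integer seed (required for \code{mcmc}).
#' @return the p-value, with attributes \code{degenerate} and (for mcmc)
#'   \code{se}.
#' @export
hwe_test <- function(table, marker_id,
                     method = c("exact_enumeration", "mcmc"),
                     dememorization = 1000, batches = 100, iterations = 1000,
                     seed = NULL) {
  method <- match.arg(method)
  g <- .marker_col(table, marker_id)
  g <- g[!is.na(g)]
  if (length(g) < 2) stop("need at least 2 typed individuals")
  counts <- c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  if (method == "exact_enumeration") hwe_exact(counts[1], counts[2], counts[3])
  else hwe_mcmc(counts[1], counts[2], counts[3], dememorization, batches,
                iterations, seed)
}

#' @rdname hwe_test
#' @param n_ww,n_wv,n_vv genotype counts.
#' @export
hwe_exact <- function(n_ww, n_wv, n_vv) {
  n <- n_ww + n_wv + n_vv
  nv <- 2 * n_vv + n_wv
  if (nv == 0 || nv == 2 * n)
    return(structure(1, degenerate = TRUE))
  pr <- .hwe_conditional(n, nv)
  obs <- pr$p[pr$k == n_wv]
  structure(sum(pr$p[pr$p <= obs * (1 + 1e-12)]), degenerate = FALSE)
}

# conditional distribution of the heterozygote count k given n individuals and
# nv copies of the variant allele (all k with the parity of nv are attainable)
.hwe_conditional <- function(n, nv) {
  kset <- seq.int(nv %% 2, min(nv, 2 * n - nv), by = 2)
  logp <- vapply(kset, function(k) {
    nww <- (2 * n - nv - k) / 2
    nvv <- (nv - k) / 2
    lfactorial(n) - lfactorial(nww) - lfactorial(k) - lfactorial(nvv) +
      k * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  list(k = kset, p = p / sum(p))
}

#' @rdname hwe_test
#' @export
hwe_mcmc <- function(n_ww, n_wv, n_vv, dememorization = 1000, batches = 100,
                     iterations = 1000, seed = NULL) {
  if (is.null(seed)) stop("the Markov-chain test needs a seed")
  n <- n_ww + n_wv + n_vv
  nv <- 2 * n_vv + n_wv
  if (nv == 0 || nv == 2 * n) return(structure(1, degenerate = TRUE, se = 0))
  cond <- .hwe_conditional(n, nv)
  obs_p <- cond$p[cond$k == n_wv]
  kmin <- min(cond$k); kmax <- max(cond$k)
  logw <- stats::setNames(log(cond$p), cond$k)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  k <- n_wv
  step <- function(k) {
    prop <- k + sample(c(-2L, 2L), 1L)
    if (prop < kmin || prop > kmax) return(k)
    if (log(stats::runif(1)) < logw[as.character(prop)] - logw[as.character(k)])
      prop else k
  }
  for (i in seq_len(dememorization)) k <- step(k)
  bm <- numeric(batches)
  for (b in seq_len(batches)) {
    hit <- 0L
    for (i in seq_len(iterations)) {
      k <- step(k)
      if (cond$p[cond$k == k] <= obs_p * (1 + 1e-12)) hit <- hit + 1L
    }
    bm[b] <- hit / iterations
  }
  structure(mean(bm), degenerate = FALSE, se = stats::sd(bm) / sqrt(batches))
}

#' Per-locus and panel-level summary statistics
#'
#' One row per marker: typed count, allele frequencies, observed and unbiased
#' expected heterozygosity, PIC, exact Hardy-Weinberg p-value and its
#' Bonferroni adjustment across the panel, and the per-locus non-exclusion
#' probabilities for identity, first parent and parent pair.  Panel-level
#' \code{mean_ho}, \code{mean_he} and \code{mean_pic} (arithmetic means over
#' loci, the granularity of the published summary tables) are attached as
#' attributes.  Monomorphic loci get zero diversity statistics and a
#' degenerate p of 1 rather than NaN.
#'
#' @param table a \code{genotype_table}.
#' @param unbiased use the small-sample-corrected expected heterozygosity.
#' @return a data.frame of class \code{locus_summary}.
#' @export
locus_summary <- function(table, unbiased = TRUE) {
  ids <- colnames(table$calls)
  rows <- lapply(ids, function(m) {
    af <- allele_frequencies(table, m)
    mono <- af$p_v == 0 || af$p_v == 1
    hh <- if (mono) list(ho = 0, he = 0) else heterozygosities(table, m, unbiased)
    p <- c(af$p_w, af$p_v)
    data.frame(marker_id = m, n_typed = af$n_typed, p_w = af$p_w, p_v = af$p_v,
               ho = hh$ho, he = hh$he, pic = if (mono) 0 else pic(p),
               hwe_p = as.numeric(hwe_exact(sum(table$calls[, m] == 0L, na.rm = TRUE),
                                            sum(table$calls[, m] == 1L, na.rm = TRUE),
                                            sum(table$calls[, m] == 2L, na.rm = TRUE))),
               ne_identity = ne_identity(p), ne_first_parent = ne_first_parent(p),
               ne_parent_pair = ne_parent_pair(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$hwe_p_bonferroni <- bonferroni(out$hwe_p)
  attr(out, "mean_ho") <- mean(out$ho)
  attr(out, "mean_he") <- mean(out$he)
  attr(out, "mean_pic") <- mean(out$pic)
  class(out) <- c("locus_summary", "data.frame")
  out
}

#' Write a per-locus summary TSV
#'
#' @param x a \code{locus_summary}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_locus_summary <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
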
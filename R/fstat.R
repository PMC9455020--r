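#' Weir & Cockerham variance components at one locus
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) components of the Weir & Cockerham (1984) ANOVA
#' for each allele of a biallelic locus, summed over the two alleles.
#' Individuals with a missing call at the locus are dropped (complete case per
#' locus).  With a single group the among-population component is zero and b
#' reduces to the within-population form, which is how the per-population
#' inbreeding coefficient f is obtained.  A locus monomorphic across all
#' groups contributes zero components (flagged via attribute
#' \code{monomorphic}).
#'
#' @param table a \code{genotype_table}.
#' @param marker_id a marker column name.
#' @param grouping factor-like vector over individuals defining populations.
#' @return named numeric \code{c(a, b, c)}.
#' @export
wc_components <- function(table, marker_id, grouping) {
  g <- .marker_col(table, marker_id)
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(table$calls))
    stop("grouping length does not match the table")
  keep <- !is.na(g)
  .wc_components_dosage(g[keep], grouping[keep])
}

# core on a dosage vector; per-allele components summed over the two alleles
# (for a biallelic locus the two allele contributions are identical)
.wc_components_dosage <- function(g, pop) {
  sp <- split(g, pop)
  sp <- sp[lengths(sp) > 0]
  r <- length(sp)
  ni <- lengths(sp)
  if (any(ni < 1) || !length(g)) stop("empty group")
  pi <- vapply(sp, function(x) mean(x) / 2, numeric(1))
  hi <- vapply(sp, function(x) mean(x == 1L), numeric(1))
  if (sum(g) == 0 || sum(g) == 2 * length(g)) # one allele fixed everywhere
    return(structure(c(a = 0, b = 0, c = 0), monomorphic = TRUE))
  nbar <- mean(ni)
  pbar <- sum(ni * pi) / (r * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  if (r > 1) {
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  } else {
    a <- 0
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
  }
  # both alleles of the biallelic locus contribute symmetrically
  structure(2 * c(a = a, b = b, c = hbar / 2), monomorphic = FALSE)
}

#' Multi-locus Weir & Cockerham F-statistics
#'
#' Multi-locus estimates follow the ratio-of-sums convention: variance
#' components are summed over loci before forming the ratio (never a mean of
#' per-locus ratios).  \code{f_st} is \eqn{\theta = \sum a / \sum(a+b+c)}
#' and needs at least two groups; \code{f_is} is \eqn{f = 1 - \sum c /
#' \sum(b+c)}, the within-population inbreeding coefficient.  Estimates may be
#' negative and are reported as computed.
#'
#' @inheritParams wc_components
#' @param statistic \code{"f_is"} or \code{"f_st"}.
#' @return a list of class \code{fstat_result} with \code{statistic},
#'   \code{estimate} and \code{per_locus_components}.
#' @export
multilocus_fstat <- function(table, statistic = c("f_is", "f_st"), grouping) {
  statistic <- match.arg(statistic)
  grouping <- as.character(grouping)
  if (statistic == "f_st" && length(unique(grouping)) < 2)
    stop("f_st needs at least two groups")
  ids <- colnames(table$calls)
  comp <- t(vapply(ids, function(m) wc_components(table, m, grouping),
                   numeric(3)))
  colnames(comp) <- c("a", "b", "c")
  denom <- if (statistic == "f_st") sum(comp) else sum(comp[, "b"] + comp[, "c"])
  if (abs(denom) < .Machine$double.eps * 100)
    stop("undefined-fstat: zero denominator (all loci monomorphic?)")
  est <- if (statistic == "f_st") sum(comp[, "a"]) / denom
         else 1 - sum(comp[, "c"]) / denom
  structure(list(statistic = statistic, estimate = est,
                 per_locus_components = data.frame(locus = ids, comp,
                                                   row.names = NULL),
                 p_value = NULL, n_permutations = 0L, seed = NULL),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(toupper(sub("_", "", x$statistic)), "=", format(x$estimate, digits = 4))
  if (!is.null(x$p_value))
    cat("  (permutation p =", format(x$p_value, digits = 3), ",",
        x$n_permutations, "permutations, seed", x$seed, ")")
  cat("\n")
  invisible(x)
}

#' Permutation test for an F-statistic
#'
#' For \eqn{F_{ST}}, whole individuals are permuted among groups; for
#' \eqn{F_{IS}}, gene copies are permuted among individuals within each group
#' (re-pairing alleles at random, locus by locus), which destroys departures
#' from random mating while preserving allele frequencies.  The two-sided
#' p-value uses absolute values with the add-one correction
#' \eqn{p = (1 + \#\{|T^*| \ge |T|\})/(1 + n_{perm})}, so it is never exactly
#' zero.  Fixing the seed fixes the p-value exactly.
#'
#' @inheritParams multilocus_fstat
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return an \code{fstat_result} with \code{p_value} filled in.
#' @export
fstat_permutation_test <- function(table, statistic = c("f_is", "f_st"),
                                   grouping, n_perm = 999, seed = 1L) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be at least 1")
  grouping <- as.character(grouping)
  obs <- multilocus_fstat(table, statistic, grouping)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  stat_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    tbl <- table
    if (statistic == "f_st") {
      perm_grouping <- sample(grouping)
      stat_perm[i] <- multilocus_fstat(tbl, statistic, perm_grouping)$estimate
    } else {
      tbl$calls <- .shuffle_gene_copies(table$calls, grouping)
      stat_perm[i] <- multilocus_fstat(tbl, statistic, grouping)$estimate
    }
  }
  obs$p_value <- (1 + sum(abs(stat_perm) >= abs(obs$estimate))) / (1 + n_perm)
  obs$n_permutations <- as.integer(n_perm)
  obs$seed <- seed
  obs
}

# randomly re-pair gene copies among individuals within each group, per locus
.shuffle_gene_copies <- function(calls, grouping) {
  out <- calls
  for (gr in unique(grouping)) {
    rows <- which(grouping == gr)
    for (j in seq_len(ncol(calls))) {
      g <- calls[rows, j]
      ok <- which(!is.na(g))
      if (length(ok) < 2) next
      copies <- sample(rep(c(0L, 1L), times = c(
        2 * length(ok) - sum(g[ok]), sum(g[ok]))))
      out[rows[ok], j] <- copies[seq_along(ok)] + copies[length(ok) + seq_along(ok)]
    }
  }
  out
}

#' Pairwise and global FST report
#'
#' Convenience wrapper producing the published-table layout: one row per pair
#' of groups plus a global row, each with the multi-locus \eqn{\theta} and its
#' permutation p-value.
#'
#' @inheritParams fstat_permutation_test
#' @return a data.frame (pop1, pop2, fst, p_value).
#' @export
pairwise_fst <- function(table, grouping, n_perm = 999, seed = 1L) {
  grouping <- as.character(grouping)
  gr <- sort(unique(grouping))
  pairs <- utils::combn(gr, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- grouping %in% pairs[, k]
    r <- fstat_permutation_test(subset_individuals(table, which(sel)), "f_st",
                                grouping[sel], n_perm, seed + k)
    data.frame(pop1 = pairs[1, k], pop2 = pairs[2, k], fst = r$estimate,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  glob <- fstat_permutation_test(table, "f_st", grouping, n_perm, seed)
  rbind(do.call(rbind, rows),
        data.frame(pop1 = "global", pop2 = "global", fst = glob$estimate,
                   p_value = glob$p_value, stringsAsFactors = FALSE))
}
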
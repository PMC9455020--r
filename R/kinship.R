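#' Genotype concordance between two individuals
#'
#' The concordance rate is \eqn{100 \times} (loci with identical genotype
#' state) / (loci typed in both individuals).  A genotype matches only when
#' the full state matches (WW = WW, WV = WV, VV = VV); allele sharing is not
#' counted.  Loci missing in either member are removed from numerator and
#' denominator.
#'
#' @param table a \code{genotype_table}.
#' @param id_a,id_b sample ids.
#' @param pedigree optional \code{pedigree} used to label the pair's kin
#'   class.
#' @return a one-row data.frame (id_a, id_b, kin_class, n_compared_loci,
#'   n_matching_loci, concordance, exact_match).
#' @export
concordance <- function(table, id_a, id_b, pedigree = NULL) {
  ia <- match(id_a, table$samples$sample_id)
  ib <- match(id_b, table$samples$sample_id)
  if (is.na(ia) || is.na(ib))
    stop("unknown sample id: ", paste(c(id_a, id_b)[c(is.na(ia), is.na(ib))],
                                      collapse = ", "))
  ga <- table$calls[ia, ]; gb <- table$calls[ib, ]
  both <- !is.na(ga) & !is.na(gb)
  if (!any(both)) stop("no mutually typed loci for ", id_a, " and ", id_b)
  n_match <- sum(ga[both] == gb[both])
  kin <- if (is.null(pedigree)) "unknown"
         else .kin_class(id_a, id_b, pedigree,
                         fam_a = .family_of(table, ia), fam_b = .family_of(table, ib))
  data.frame(id_a = id_a, id_b = id_b, kin_class = kin,
             n_compared_loci = sum(both), n_matching_loci = n_match,
             concordance = 100 * n_match / sum(both),
             exact_match = n_match == sum(both),
             stringsAsFactors = FALSE)
}

.family_of <- function(table, idx) {
  if ("family_id" %in% names(table$samples)) table$samples$family_id[idx] else NA_character_
}

# kin class of an unordered pair; precedence twin > parent-offspring >
# full sibling > grandparent-grandchild; unrelated pairs are non_kin across
# families and unknown within one family
.kin_class <- function(a, b, ped, fam_a = NA, fam_b = NA) {
  pairmatch <- function(d, x, y) any((d[[1]] == x & d[[2]] == y) |
                                     (d[[1]] == y & d[[2]] == x))
  if (pairmatch(ped$twins, a, b)) return("twin")
  if (pairmatch(ped$parent_offspring, a, b)) return("parent_offspring")
  if (pairmatch(full_sibling_pairs(ped), a, b)) return("full_sibling")
  if (pairmatch(ped$grandparent, a, b)) return("grandparent_grandchild")
  if (!is.na(fam_a) && !is.na(fam_b) && fam_a == fam_b) "unknown" else "non_kin"
}

#' Exhaustive identity matching
#'
#' Scans all unordered pairs of individuals and reports those whose genotypes
#' disagree at no more than \code{max_mismatch} of the mutually typed loci.
#' With the default \code{max_mismatch = 0} this lists perfect matches, the
#' identity-screening step for a marker panel.
#'
#' @param table a \code{genotype_table}.
#' @param max_mismatch maximum number of mismatching loci tolerated.
#' @return a data.frame of matching pairs (possibly empty), with attribute
#'   \code{n_pairs_examined}.
#' @export
find_identical_pairs <- function(table, max_mismatch = 0) {
  n <- nrow(table$calls)
  if (n < 2) stop("need at least 2 individuals")
  ids <- table$samples$sample_id
  out <- list()
  for (i in seq_len(n - 1)) {
    gi <- table$calls[i, ]
    for (j in (i + 1):n) {
      gj <- table$calls[j, ]
      both <- !is.na(gi) & !is.na(gj)
      if (!any(both)) next
      mm <- sum(gi[both] != gj[both])
      if (mm <= max_mismatch)
        out[[length(out) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j], n_compared_loci = sum(both),
          n_mismatching_loci = mm, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(id_a = character(), id_b = character(),
                         n_compared_loci = integer(),
                         n_mismatching_loci = integer(), stringsAsFactors = FALSE)
  attr(res, "n_pairs_examined") <- n * (n - 1) / 2
  res
}

#' Classify all pairs of a table against a pedigree
#'
#' Computes the concordance of every unordered pair and labels it with its kin
#' class: \code{twin}, \code{parent_offspring}, \code{full_sibling} (explicit
#' edges plus pairs sharing a recorded parent), \code{grandparent_grandchild},
#' \code{non_kin} for pairs with no recorded relation belonging to different
#' families, and \code{unknown} for unlabelled same-family pairs (excluded
#' from group comparisons).
#'
#' @param table a \code{genotype_table} with a \code{family_id} metadata
#'   column (pairs are otherwise never classed \code{unknown}).
#' @param pedigree a \code{pedigree}; ids must occur in the table.
#' @return a data.frame of pair comparisons.
#' @export
classify_pairs <- function(table, pedigree) {
  dangling <- setdiff(pedigree_ids(pedigree), table$samples$sample_id)
  if (length(dangling))
    stop("pedigree references unknown sample id(s): ",
         paste(dangling, collapse = ", "))
  ids <- table$samples$sample_id
  n <- length(ids)
  fams <- if ("family_id" %in% names(table$samples)) table$samples$family_id
          else rep(NA_character_, n)
  sibs <- full_sibling_pairs(pedigree)
  ped2 <- pedigree; ped2$full_sibling <- sibs # avoid recomputing per pair
  rows <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1L
    ga <- table$calls[i, ]; gb <- table$calls[j, ]
    both <- !is.na(ga) & !is.na(gb)
    n_match <- sum(ga[both] == gb[both])
    rows[[k]] <- data.frame(
      id_a = ids[i], id_b = ids[j],
      kin_class = .kin_class(ids[i], ids[j], ped2, fams[i], fams[j]),
      n_compared_loci = sum(both), n_matching_loci = n_match,
      concordance = 100 * n_match / sum(both),
      exact_match = n_match == sum(both), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Concordance-rate screening thresholds
#'
#' \code{empirical_quantile} returns the 95th percentile of the non-kin
#' concordances and the 5th percentiles of the parent-offspring and
#' full-sibling concordances, using interpolated order statistics
#' (\code{stats::quantile} \code{type}, default 7 — the linear-interpolation
#' convention of most spreadsheet software).  \code{normal_theory} returns
#' mean \eqn{\pm 1.645 \cdot} sd per class instead.
#'
#' @param comparisons a pair-comparison data.frame from
#'   \code{\link{classify_pairs}}.
#' @param method \code{"empirical_quantile"} or \code{"normal_theory"}.
#' @param quantile_type interpolation type passed to \code{stats::quantile}.
#' @return a list with \code{upper5_nonkin}, \code{lower5_parent_offspring},
#'   \code{lower5_full_sibling}, the method and the convention label, plus the
#'   class sizes used.
#' @export
concordance_thresholds <- function(comparisons,
                                   method = c("empirical_quantile", "normal_theory"),
                                   quantile_type = 7) {
  method <- match.arg(method)
  grab <- function(cls) comparisons$concordance[comparisons$kin_class == cls]
  nk <- grab("non_kin"); po <- grab("parent_offspring"); fs <- grab("full_sibling")
  for (v in list(nk, po, fs)) if (!length(v))
    stop("a required kin class (non_kin, parent_offspring, full_sibling) is empty")
  if (method == "empirical_quantile") {
    list(upper5_nonkin = unname(stats::quantile(nk, 0.95, type = quantile_type)),
         lower5_parent_offspring = unname(stats::quantile(po, 0.05, type = quantile_type)),
         lower5_full_sibling = unname(stats::quantile(fs, 0.05, type = quantile_type)),
         method = method,
         quantile_convention = paste0("interpolated_type", quantile_type),
         n = c(non_kin = length(nk), parent_offspring = length(po),
               full_sibling = length(fs)))
  } else {
    for (v in list(nk, po, fs)) if (length(v) < 2)
      stop("normal_theory needs at least 2 values per class")
    list(upper5_nonkin = mean(nk) + 1.645 * stats::sd(nk),
         lower5_parent_offspring = mean(po) - 1.645 * stats::sd(po),
         lower5_full_sibling = mean(fs) - 1.645 * stats::sd(fs),
         method = method, quantile_convention = "mean_pm_1.645_sd",
         n = c(non_kin = length(nk), parent_offspring = length(po),
               full_sibling = length(fs)))
  }
}

#' Wilcoxon rank-sum test with midranks
#'
#' Reports W as the rank sum of the first group (midranks for ties).  The
#' two-sided p-value uses the normal approximation with the tie-corrected
#' variance; for \eqn{n_1 + n_2 \le 12} and untied data the exact permutation
#' distribution is enumerated instead.
#'
#' @param group1,group2 numeric vectors (e.g. concordance percentages).
#' @param exact_limit total sample size at or below which the exact
#'   enumeration is used (untied data only).
#' @return a list with \code{w_statistic}, \code{n1}, \code{n2},
#'   \code{p_value}, \code{sidedness} and \code{method}.
#' @export
rank_sum_test <- function(group1, group2, exact_limit = 12) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  n1 <- length(group1); n2 <- length(group2); n <- n1 + n2
  r <- rank(c(group1, group2)) # midranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n <= exact_limit) {
    # exact permutation null over all choose(n, n1) placements of group 1,
    # on the midranks, so it remains valid under ties
    sets <- utils::combn(n, n1)
    wnull <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(abs(wnull - mu) >= abs(w - mu) - 1e-9)
    method <- "exact_enumeration"
  } else {
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs(w - mu) / sqrt(sigma2))
    method <- "normal_approximation_tie_corrected"
  }
  list(w_statistic = w, n1 = n1, n2 = n2, p_value = min(1, p),
       sidedness = "two_sided", method = method)
}

#' Histogram table of concordance by kin class
#'
#' Counts pairs per kin class in bins centred on the attainable concordance
#' values (multiples of 100/L for an L-locus panel), the structure of the
#' published concordance histograms.
#'
#' @param comparisons a pair-comparison data.frame.
#' @param n_loci panel size used to place bin centres.
#' @return a contingency table (kin class x concordance bin).
#' @export
concordance_histogram <- function(comparisons, n_loci = 11) {
  centres <- round(100 * (0:n_loci) / n_loci, 1)
  bin <- centres[findInterval(comparisons$concordance,
                              c(-Inf, (centres[-1] + centres[-length(centres)]) / 2)) ]
  table(kin_class = comparisons$kin_class, concordance = bin)
}
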
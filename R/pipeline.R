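#' Run the full analysis chain on the bundled crane tables
#'
#' Reproduces the published analysis end to end and writes one TSV per stage
#' to \code{out_dir}: per-locus summary (diversity, HWE, non-exclusion
#' columns), F-statistics report (global and pairwise FST with permutation
#' p-values, FIS), combined non-exclusion probabilities, perfectly matching
#' identity pairs for the non-kin and 66-sample union sets, kinship
#' concordance report (per-pair classes, thresholds, rank-sum tests,
#' histogram table) and PCA scores with contribution ratios.  A
#' \code{manifest.tsv} records package version, seed, permutation counts and
#' the warning ledger so that deterministic outputs can be reproduced
#' bit-for-bit.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_perm permutations for the F-statistic tests.
#' @param fis_scope convention for the headline FIS of the non-kin set:
#'   \code{"single_population"} (all 39 pooled, the convention of the
#'   published per-region rows) or \code{"regions"} (within-region f across
#'   the three regional subpopulations).
#' @return invisibly, a named list of the written file paths.
#' @export
run_full_reproduction <- function(out_dir, seed = 1L, n_perm = 999,
                                  fis_scope = c("single_population", "regions")) {
  fis_scope <- match.arg(fis_scope)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop("output directory not writable: ", out_dir)
  unlink(probe)

  nonkin <- crane_nonkin_table()
  if (nrow(nonkin$calls) < 2) stop("non-kin table too small for locus statistics")
  kin <- crane_kin_table()
  ped <- crane_pedigree()
  un <- select_dataset("union")
  region <- nonkin$samples$region
  paths <- list()
  wr <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }

  ls_sum <- locus_summary(nonkin)
  wr(ls_sum, "locus_summary.tsv")

  fst_rep <- pairwise_fst(nonkin, region, n_perm = n_perm, seed = seed + 10L)
  fis_grouping <- if (fis_scope == "single_population") rep("all", 39) else region
  fis <- fstat_permutation_test(nonkin, "f_is", fis_grouping,
                                n_perm = n_perm, seed = seed + 20L)
  fst_rep <- rbind(fst_rep,
                   data.frame(pop1 = "FIS", pop2 = fis_scope,
                              fst = fis$estimate, p_value = fis$p_value,
                              stringsAsFactors = FALSE))
  wr(fst_rep, "fstatistics.tsv")

  ex <- exclusion_summary(nonkin)
  ex_rep <- rbind(ex$per_locus,
                  data.frame(marker_id = "combined",
                             ne_identity = ex$combined_ne_identity,
                             ne_first_parent = ex$combined_ne_first_parent,
                             ne_second_parent = ex$combined_ne_second_parent,
                             ne_parent_pair = ex$combined_ne_parent_pair,
                             stringsAsFactors = FALSE))
  wr(ex_rep, "exclusion.tsv")

  idp_nonkin <- find_identical_pairs(nonkin)
  idp_union <- find_identical_pairs(un)
  idp <- rbind(cbind(set = "non_kin", idp_nonkin),
               cbind(set = "union66", idp_union))
  wr(idp, "identity_pairs.tsv")

  pairs <- classify_pairs(kin, ped)
  wr(pairs, "kin_pairs.tsv")
  thr_emp <- concordance_thresholds(pairs)
  thr_nrm <- concordance_thresholds(pairs, "normal_theory")
  thr <- data.frame(
    method = c(thr_emp$method, thr_nrm$method),
    upper5_nonkin = c(thr_emp$upper5_nonkin, thr_nrm$upper5_nonkin),
    lower5_parent_offspring = c(thr_emp$lower5_parent_offspring,
                                thr_nrm$lower5_parent_offspring),
    lower5_full_sibling = c(thr_emp$lower5_full_sibling,
                            thr_nrm$lower5_full_sibling),
    stringsAsFactors = FALSE)
  wr(thr, "kin_thresholds.tsv")
  gr <- function(cls) pairs$concordance[pairs$kin_class == cls]
  rs_po <- rank_sum_test(gr("parent_offspring"), gr("non_kin"))
  rs_fs <- rank_sum_test(gr("full_sibling"), gr("non_kin"))
  wr(data.frame(comparison = c("parent_offspring_vs_non_kin",
                               "full_sibling_vs_non_kin"),
                w = c(rs_po$w_statistic, rs_fs$w_statistic),
                n1 = c(rs_po$n1, rs_fs$n1), n2 = c(rs_po$n2, rs_fs$n2),
                p_value = c(rs_po$p_value, rs_fs$p_value),
                stringsAsFactors = FALSE),
     "kin_rank_sum.tsv")
  hist_tab <- as.data.frame.matrix(concordance_histogram(pairs))
  hist_tab <- cbind(kin_class = rownames(hist_tab), hist_tab)
  wr(hist_tab, "kin_histogram.tsv")

  pca <- pca_genotypes(nonkin)
  scores <- data.frame(sample_id = nonkin$samples$sample_id, region = region,
                       pca$scores[, 1:4], stringsAsFactors = FALSE)
  wr(scores, "pca_scores.tsv")
  wr(data.frame(component = seq_along(pca$contribution_ratios),
                contribution_ratio = pca$contribution_ratios),
     "pca_contributions.tsv")

  manifest <- data.frame(
    key = c("package_version", "seed", "n_perm", "fis_scope",
            "normalized_cells_nonkin", "normalized_cells_kin",
            "n_pairs_nonkin", "n_pairs_union"),
    value = c(as.character(utils::packageVersion("indelpop")), seed, n_perm,
              fis_scope, nrow(nonkin$normalizations), nrow(kin$normalizations),
              attr(idp_nonkin, "n_pairs_examined"),
              attr(idp_union, "n_pairs_examined")),
    stringsAsFactors = FALSE)
  wr(manifest, "manifest.tsv")
  invisible(paths)
}
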
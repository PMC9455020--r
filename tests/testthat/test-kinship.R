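test_that("concordance is the matched-loci percentage, symmetric, missing-aware", {
  kin <- crane_kin_table()
  self <- concordance(kin, "207", "207")
  expect_equal(self$concordance, 100)
  expect_true(self$exact_match)
  # cranes 207 and 352 differ only at Id-10
  ab <- concordance(kin, "207", "352")
  expect_equal(ab$n_matching_loci, 10L)
  expect_equal(ab$concordance, 100 * 10 / 11)
  ba <- concordance(kin, "352", "207")
  expect_equal(ab$concordance, ba$concordance)
  # all loci different
  opp <- make_table(matrix(c(0L, 2L), 2, 11, byrow = FALSE))
  expect_equal(concordance(opp, "1", "2")$concordance, 0)
  # pairwise-complete loci
  m <- matrix(c(1L, NA, 0L, 1L, 1L, 0L), 2, 3)
  expect_equal(concordance(make_table(m), "1", "2")$n_compared_loci, 2L)
  allmiss <- make_table(matrix(c(1L, NA, NA, 1L), 2, 2))
  expect_error(concordance(allmiss, "1", "2"), "mutually typed")
  expect_error(concordance(kin, "207", "nope"), "unknown sample id")
})

test_that("identity scan finds exactly the published matching pairs", {
  nk <- crane_nonkin_table()
  hits <- find_identical_pairs(nk)
  expect_equal(attr(hits, "n_pairs_examined"), 741)
  expect_equal(nrow(hits), 1L)
  expect_setequal(c(hits$id_a, hits$id_b), c("89", "127"))
  un <- select_dataset("union")
  hits66 <- find_identical_pairs(un)
  expect_equal(attr(hits66, "n_pairs_examined"), 2145)
  expect_equal(nrow(hits66), 2L)
  keys <- apply(hits66[, c("id_a", "id_b")], 1,
                function(r) paste(sort(r), collapse = "-"))
  expect_setequal(keys, c("127-89", "331-388"))
  # duplicated rows are reported as matches
  dup <- make_table(matrix(rep(c(0L, 1L, 2L), 2), 2, 3, byrow = TRUE))
  expect_equal(nrow(find_identical_pairs(dup)), 1L)
  # mismatch tolerance widens the net
  expect_gt(nrow(find_identical_pairs(nk, max_mismatch = 1)), 1)
  expect_error(find_identical_pairs(make_table(matrix(0L, 1, 2))), "at least 2")
})

test_that("pairs are classified against the pedigree with precedence rules", {
  kin <- crane_kin_table()
  ped <- crane_pedigree()
  pairs <- classify_pairs(kin, ped)
  expect_equal(nrow(pairs), choose(39, 2))
  tab <- table(pairs$kin_class)
  expect_equal(unname(tab["parent_offspring"]), 25L)
  expect_equal(unname(tab["twin"]), 2L)
  expect_equal(unname(tab["grandparent_grandchild"]), 4L)
  expect_equal(unname(tab["non_kin"]), 652L)
  # twins beat the derived sibling relation (244/245 share both parents)
  tw <- pairs[pairs$id_a %in% c("244", "245") & pairs$id_b %in% c("244", "245"), ]
  expect_equal(tw$kin_class, "twin")
  tw2 <- pairs[pairs$id_a %in% c("315", "316") & pairs$id_b %in% c("315", "316"), ]
  expect_equal(tw2$kin_class, "twin")
  # unlabelled same-family pairs are unknown (e.g. the 123 x 131 couple)
  couple <- pairs[pairs$id_a == "123" & pairs$id_b == "131", ]
  expect_equal(couple$kin_class, "unknown")
  expect_error(classify_pairs(crane_nonkin_table(), ped), "unknown sample id")
  # empty pedigree: every cross-family pair is non_kin
  empty <- classify_pairs(kin, pedigree())
  expect_true(all(empty$kin_class %in% c("non_kin", "unknown")))
})

test_that("thresholds honour the quantile convention and normal theory", {
  eq <- data.frame(kin_class = rep(c("non_kin", "parent_offspring",
                                     "full_sibling"), each = 4),
                   concordance = rep(c(50, 80, 70), each = 4))
  thr <- concordance_thresholds(eq)
  expect_equal(thr$upper5_nonkin, 50)
  expect_equal(thr$lower5_parent_offspring, 80)
  expect_equal(thr$lower5_full_sibling, 70)
  thrn <- concordance_thresholds(eq, "normal_theory")
  expect_equal(thrn$upper5_nonkin, 50) # sd 0: the mean itself
  missing_class <- eq[eq$kin_class != "full_sibling", ]
  expect_error(concordance_thresholds(missing_class), "empty")
  # convention switch reaches stats::quantile
  pairs <- classify_pairs(crane_kin_table(), crane_pedigree())
  po <- pairs$concordance[pairs$kin_class == "parent_offspring"]
  for (ty in c(2, 5, 7)) {
    thr <- concordance_thresholds(pairs, quantile_type = ty)
    expect_equal(thr$lower5_parent_offspring,
                 unname(quantile(po, 0.05, type = ty)))
  }
})

test_that("rank-sum statistic matches wilcox.test and respects its bounds", {
  set.seed(77)
  for (i in 1:12) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    x <- sample(seq(0, 100, by = 100 / 11), n1, TRUE)
    y <- sample(seq(0, 100, by = 100 / 11), n2, TRUE)
    rs <- rank_sum_test(x, y, exact_limit = 0) # force the normal path
    wt <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE))
    expect_equal(rs$w_statistic, unname(wt$statistic) + n1 * (n1 + 1) / 2)
    expect_equal(rs$p_value, wt$p.value, tolerance = 1e-10)
    expect_gte(rs$w_statistic, n1 * (n1 + 1) / 2)
    expect_lte(rs$w_statistic, n1 * n2 + n1 * (n1 + 1) / 2)
  }
})

test_that("rank-sum exact path: separation, identity and the exact oracle", {
  # complete separation: maximal W
  sep <- rank_sum_test(c(7, 8, 9), c(1, 2, 3, 4))
  expect_equal(sep$w_statistic, 3 * 4 + 3 * 4 / 2)
  expect_equal(sep$method, "exact_enumeration")
  # identical tied groups: p = 1
  same <- rank_sum_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)
  # untied exact p equals wilcox.test's exact p
  x <- c(1.2, 3.4, 9.1); y <- c(2.2, 5.5, 7.7, 8.8)
  rs <- rank_sum_test(x, y)
  wt <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(rs$p_value, wt$p.value, tolerance = 1e-10)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("simulated kin classes order as twin >= sibling >= parent-offspring >= non-kin", {
  means <- c(twin = 0, full_sibling = 0, parent_offspring = 0, non_kin = 0)
  reps <- 40
  for (i in seq_len(reps)) {
    sim <- simulate_pedigree(sim_config(
      n_loci = 11, allele_freqs = 0.3, seed = 5000 + i,
      pedigree_spec = list(n_families = 6, n_offspring = 3, n_twin_pairs = 2)))
    pairs <- classify_pairs(sim$table, sim$pedigree)
    for (cl in names(means)) {
      v <- pairs$concordance[pairs$kin_class == cl]
      if (length(v)) means[cl] <- means[cl] + mean(v) / reps
    }
  }
  # twins are independent meioses, so twin and full-sibling concordance share
  # one expectation; allow Monte-Carlo slack on those comparisons
  expect_gte(means["twin"], means["full_sibling"] - 3)
  expect_gte(means["full_sibling"], means["parent_offspring"] - 2)
  expect_gt(means["parent_offspring"], means["non_kin"])
})

test_that("histogram table bins at the attainable concordance values", {
  pairs <- classify_pairs(crane_kin_table(), crane_pedigree())
  h <- concordance_histogram(pairs)
  expect_equal(sum(h), nrow(pairs))
  expect_true(all(colnames(h) %in% as.character(round(100 * 0:11 / 11, 1))))
})
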
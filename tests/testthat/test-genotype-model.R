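test_that("dialect vocabulary parses and typographic variants are normalised", {
  txt <- paste(
    "sample_id\tIdA\tIdB",
    "s1\tW Homo\tWD Hetero",
    "s2\tD Homo\tWD Heter",
    "s3\tWD Hetero\tW Hetero",
    sep = "\n")
  expect_warning(tab <- parse_genotype_table(text = txt), "2 non-canonical")
  expect_equal(unname(tab$calls[, "IdA"]), c(0L, 2L, 1L))
  expect_equal(unname(tab$calls[, "IdB"]), c(1L, 1L, 1L))
  expect_equal(nrow(tab$normalizations), 2L)
  expect_setequal(tab$normalizations$token, c("WD Heter", "W Hetero"))
})

test_that("parse errors name the offending cell and reject duplicates", {
  bad <- "sample_id\tIdA\ns1\tZ Homo\n"
  expect_error(parse_genotype_table(text = bad), "Z Homo.*IdA")
  dup <- "sample_id\tIdA\ns1\tW Homo\ns1\tW Homo\n"
  expect_error(parse_genotype_table(text = dup), "duplicate sample_id")
  mixed <- "sample_id\tIdA\ns1\tWI Hetero\ns2\tWD Hetero\n"
  expect_error(parse_genotype_table(text = mixed), "biallelic")
})

test_that("both bundled tables parse with a stable normalisation ledger", {
  nk <- crane_nonkin_table()
  kin <- crane_kin_table()
  expect_equal(dim(nk), c(39L, 11L))
  expect_equal(dim(kin), c(39L, 11L))
  expect_false(anyNA(nk$calls))
  expect_false(anyNA(kin$calls))
  # four "WD Heter" cells in the non-kin table, two "W Hetero" in the kin table
  expect_equal(nrow(nk$normalizations), 4L)
  expect_equal(nrow(kin$normalizations), 2L)
  expect_true(all(nk$normalizations$marker_id == "Id-10"))
  expect_true(all(kin$normalizations$marker_id == "Id-10"))
  # missing haplotype metadata maps to unknown, never an error
  expect_equal(kin$samples$haplotype[kin$samples$sample_id == "T74/R566"],
               "unknown")
})

test_that("serialise/parse round-trips a genotype table", {
  kin <- crane_kin_table()
  txt <- write_genotype_table(kin)
  back <- parse_genotype_table(text = txt, markers = crane_marker_panel(),
                               quiet = TRUE)
  expect_identical(back$calls, kin$calls)
  expect_identical(back$samples$sample_id, kin$samples$sample_id)

  # typo injection only touches the text layer, and the parser undoes it
  cfg <- sim_config(n_loci = 5, allele_freqs = 0.4, population_sizes = 20,
                    seed = 11)
  sim <- simulate_population(cfg)
  noisy <- write_genotype_table(sim, typo_rate = 0.5, seed = 12)
  expect_match(noisy, "WD Heter\t", fixed = TRUE)
  reparsed <- suppressWarnings(parse_genotype_table(text = noisy))
  expect_identical(reparsed$calls, sim$calls)
})

test_that("dataset selectors return the study sample sets", {
  expect_equal(nrow(select_dataset("non_kin")$calls), 39L)
  expect_equal(nrow(select_dataset("kin")$calls), 39L)
  un <- select_dataset("union")
  expect_equal(nrow(un$calls), 66L)
  expect_false(anyDuplicated(un$samples$sample_id) > 0)
  expect_error(select_dataset("everything"))
  # disjoint union adds sizes
  a <- make_table(matrix(0:1, 2, 3, dimnames = list(c("x1", "x2"), NULL)))
  b <- make_table(matrix(1:2, 2, 3, dimnames = list(c("y1", "y2"), NULL)))
  colnames(b$calls) <- colnames(a$calls)
  expect_equal(nrow(union_tables(a, b)$calls), 4L)
})

test_that("band prediction follows the fragment-length arithmetic", {
  panel <- crane_marker_panel()
  id01 <- panel[panel$marker_id == "Id-01", ] # deletion, 32 bp, product 200
  expect_equal(predict_band_pattern(id01, 0)$fragment_lengths, 200L)
  expect_false(predict_band_pattern(id01, 0)$heteroduplex_possible)
  wv <- predict_band_pattern(id01, 1)
  expect_equal(wv$fragment_lengths, c(168L, 200L))
  expect_true(wv$heteroduplex_possible)
  id03 <- panel[panel$marker_id == "Id-03", ] # insertion, 30 bp, product 160
  expect_equal(predict_band_pattern(id03, 2)$fragment_lengths, 190L)
  # alternative reading: printed product is the insertion-allele product
  expect_equal(predict_band_pattern(id03, 2, "variant")$fragment_lengths, 160L)
  expect_equal(predict_band_pattern(id03, 0, "variant")$fragment_lengths, 130L)
  expect_error(predict_band_pattern(id01, NA), "missing")
})

test_that("band prediction is injective over the three states", {
  panel <- crane_marker_panel()
  for (k in seq_len(nrow(panel))) {
    pats <- lapply(0:2, function(g)
      predict_band_pattern(panel[k, ], g)$fragment_lengths)
    expect_equal(length(unique(pats)), 3L)
  }
})

test_that("pedigree loads, validates and derives sibling pairs", {
  ped <- crane_pedigree()
  expect_equal(nrow(ped$parent_offspring), 25L)
  expect_equal(nrow(ped$twins), 2L)
  expect_equal(nrow(ped$grandparent), 4L)
  sibs <- full_sibling_pairs(ped)
  # C(7,2) for the seven-chick brood + C(3,2) + three two-chick broods
  # (358/359, the twins 244/245, and 124/125)
  expect_equal(nrow(sibs), 21L + 3L + 1L + 1L + 1L)
  expect_error(pedigree(parent_offspring = data.frame(p = c("a", "b"),
                                                      o = c("b", "a"))),
               "ancestor")
})
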
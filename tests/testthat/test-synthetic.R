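test_that("simulation is reproducible and honours degenerate parameters", {
  cfg <- sim_config(n_loci = 7, allele_freqs = 0.3, n_populations = 2,
                    target_fst = 0.1, population_sizes = c(10, 15), seed = 21)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$calls, b$calls)
  # full inbreeding: no heterozygotes
  inbred <- simulate_population(sim_config(n_loci = 20, allele_freqs = 0.4,
                                           inbreeding_f = 1,
                                           population_sizes = 50, seed = 22))
  expect_false(any(inbred$calls == 1L))
  # negative F beyond feasibility errors
  expect_error(simulate_population(sim_config(n_loci = 2, allele_freqs = 0.05,
                                              inbreeding_f = -0.9,
                                              population_sizes = 5, seed = 1)),
               "negative genotype probability")
  expect_error(sim_config(n_loci = 3, allele_freqs = 0.2, population_sizes = 5),
               "seed")
  # missingness injected at the configured rate
  noisy <- simulate_population(sim_config(n_loci = 50, allele_freqs = 0.5,
                                          population_sizes = 100,
                                          missing_rate = 0.1, seed = 23))
  expect_lt(abs(mean(is.na(noisy$calls)) - 0.1), 0.02)
})

test_that("empirical allele frequencies converge to the configured values", {
  freqs <- c(0.1, 0.3, 0.5)
  big <- simulate_population(sim_config(n_loci = 3, allele_freqs = freqs,
                                        population_sizes = 4000, seed = 24))
  for (j in 1:3)
    expect_equal(mean(big$calls[, j]) / 2, freqs[j],
                 tolerance = 3 / sqrt(4000))
})

test_that("zero target FST gives exchangeable populations, positive FST differentiates", {
  flat <- simulate_population(sim_config(n_loci = 40, allele_freqs = 0.4,
                                         n_populations = 2, target_fst = 0,
                                         population_sizes = 200, seed = 25))
  grp <- flat$samples$region
  p1 <- colMeans(flat$calls[grp == "pop1", ]) / 2
  p2 <- colMeans(flat$calls[grp == "pop2", ]) / 2
  expect_equal(mean(p1 - p2), 0, tolerance = 0.02)
  diffed <- simulate_population(sim_config(n_loci = 40, allele_freqs = 0.4,
                                           n_populations = 2, target_fst = 0.2,
                                           population_sizes = 200, seed = 25))
  d2 <- colMeans(diffed$calls[grp == "pop1", ]) / 2 -
    colMeans(diffed$calls[grp == "pop2", ]) / 2
  expect_gt(stats::var(d2), stats::var(p1 - p2))
})

test_that("Mendelian transmission is exact in pedigree simulation", {
  # WW x VV cross: every offspring heterozygous
  sim <- simulate_pedigree(sim_config(n_loci = 30, allele_freqs = 0.5,
                                      seed = 26,
                                      pedigree_spec = list(n_families = 4,
                                                           n_offspring = 5)))
  tab <- sim$table; ped <- sim$pedigree
  po <- ped$parent_offspring
  for (k in seq_len(nrow(po))) {
    gp <- tab$calls[match(po$parent[k], tab$samples$sample_id), ]
    go <- tab$calls[match(po$offspring[k], tab$samples$sample_id), ]
    # a parent and offspring always share an allele: never opposite homozygotes
    expect_false(any(abs(gp - go) == 2L))
  }
  forced <- which(tab$calls[match(po$parent[1], tab$samples$sample_id), ] == 0L &
                    tab$calls[match(po$parent[2], tab$samples$sample_id), ] == 2L)
  if (length(forced)) {
    kid <- tab$calls[match(po$offspring[1], tab$samples$sample_id), forced]
    expect_true(all(kid == 1L))
  }
  # grandparent chains and twins are recorded
  sim2 <- simulate_pedigree(sim_config(n_loci = 5, allele_freqs = 0.5, seed = 27,
                                       pedigree_spec = list(n_families = 2,
                                                            n_offspring = 2,
                                                            n_grandchildren = 2,
                                                            n_twin_pairs = 1)))
  expect_equal(nrow(sim2$pedigree$grandparent), 2 * 2 * 2)
  expect_equal(nrow(sim2$pedigree$twins), 1L)
  expect_error(simulate_pedigree(sim_config(n_loci = 2, allele_freqs = 0.5,
                                            seed = 1,
                                            pedigree_spec = list(n_families = 1,
                                                                 n_offspring = 1,
                                                                 n_parents = 1))),
               "two parents")
})

test_that("sibling concordance exceeds non-kin concordance, matching enumeration", {
  p <- 0.3
  # exact expectation of genotype-state concordance for full sibs via the
  # joint parental-genotype enumeration, and for unrelated pairs
  pg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  gam <- function(g) switch(g, `0` = c(1, 0), `1` = c(0.5, 0.5), `2` = c(0, 1))
  off_dist <- function(gm, gf) {
    m <- gam(as.character(gm)); f <- gam(as.character(gf))
    c(m[1] * f[1], m[1] * f[2] + m[2] * f[1], m[2] * f[2])
  }
  sib_match <- 0
  for (gm in 0:2) for (gf in 0:2) {
    od <- off_dist(gm, gf)
    sib_match <- sib_match + pg[gm + 1] * pg[gf + 1] * sum(od^2)
  }
  nonkin_match <- sum(pg^2)
  expect_gt(sib_match, nonkin_match)

  # simulated siblings at >= 1e4 pairs reproduce the enumerated expectation
  tot <- 0L; n_pairs <- 0L; loci_per <- 25L
  for (i in 1:20) {
    sim <- simulate_pedigree(sim_config(n_loci = loci_per, allele_freqs = p,
                                        seed = 600 + i,
                                        pedigree_spec = list(n_families = 10,
                                                             n_offspring = 3)))
    tab <- sim$table
    sibs <- full_sibling_pairs(sim$pedigree)
    for (k in seq_len(nrow(sibs))) {
      g1 <- tab$calls[match(sibs$id1[k], tab$samples$sample_id), ]
      g2 <- tab$calls[match(sibs$id2[k], tab$samples$sample_id), ]
      tot <- tot + sum(g1 == g2); n_pairs <- n_pairs + loci_per
    }
  }
  expect_gte(n_pairs, 1e4)
  expect_equal(tot / n_pairs, sib_match, tolerance = 4 * sqrt(0.25 / n_pairs) + 0.01)
})
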
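#' Simulation configuration
#'
#' Validated container for the population/pedigree simulator.  Structure
#' between populations follows the Balding-Nichols model: population-specific
#' allele frequencies are drawn from a Beta distribution with mean equal to
#' the base frequency and variance governed by \code{target_fst} (0 gives
#' identical frequencies everywhere).  Within populations genotypes follow
#' the inbreeding law \eqn{P(WV) = 2pq(1 - F)}, with the homozygote
#' probabilities adjusted accordingly.
#'
#' @param n_loci number of biallelic loci.
#' @param allele_freqs base variant-allele frequencies, recycled to
#'   \code{n_loci}; each in (0, 1).
#' @param inbreeding_f within-population inbreeding coefficient F in [-1, 1];
#'   values of F making a genotype probability negative for some frequency
#'   are rejected at simulation time.
#' @param n_populations number of populations.
#' @param target_fst Balding-Nichols differentiation parameter in [0, 1).
#' @param population_sizes individuals per population, recycled to
#'   \code{n_populations}.
#' @param pedigree_spec list with \code{n_families}, \code{n_offspring}
#'   (per family), optional \code{n_grandchildren} (children of the first
#'   offspring and an unrelated mate) and \code{n_twin_pairs} (families whose
#'   first two offspring are twins, i.e. independent meioses of the same
#'   parents).
#' @param missing_rate,typo_rate noise rates in [0, 1); typo noise only
#'   affects the serialised text dialect (see
#'   \code{\link{write_genotype_table}}).
#' @param seed mandatory integer seed.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_loci = 11, allele_freqs = 0.2, inbreeding_f = 0,
                       n_populations = 1, target_fst = 0,
                       population_sizes = 39,
                       pedigree_spec = list(n_families = 12, n_offspring = 2,
                                            n_grandchildren = 0,
                                            n_twin_pairs = 0),
                       missing_rate = 0, typo_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_loci >= 1, all(allele_freqs > 0 & allele_freqs < 1),
            inbreeding_f >= -1, inbreeding_f <= 1,
            n_populations >= 1, target_fst >= 0, target_fst < 1,
            all(population_sizes >= 1),
            missing_rate >= 0, missing_rate < 1,
            typo_rate >= 0, typo_rate < 1)
  structure(list(n_loci = as.integer(n_loci),
                 allele_freqs = rep_len(allele_freqs, n_loci),
                 inbreeding_f = inbreeding_f,
                 n_populations = as.integer(n_populations),
                 target_fst = target_fst,
                 population_sizes = rep_len(as.integer(population_sizes),
                                            n_populations),
                 pedigree_spec = pedigree_spec,
                 missing_rate = missing_rate, typo_rate = typo_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# population-specific frequencies under Balding-Nichols
.bn_freqs <- function(p, fst) {
  if (fst == 0) return(p)
  shape <- (1 - fst) / fst
  stats::rbeta(length(p), p * shape, (1 - p) * shape)
}

# genotype draw with inbreeding: P(VV) = p^2 + Fpq, P(WV) = 2pq(1-F)
.draw_genotypes <- function(n, p, f) {
  pr <- cbind(ww = (1 - p)^2 + f * p * (1 - p),
              wv = 2 * p * (1 - p) * (1 - f),
              vv = p^2 + f * p * (1 - p))
  if (any(pr < -1e-12))
    stop("inbreeding_f = ", f, " gives a negative genotype probability")
  pr[pr < 0] <- 0
  vapply(seq_along(p), function(j) {
    sample.int(3L, n, replace = TRUE, prob = pr[j, ]) - 1L
  }, integer(n))
}

.inject_missing <- function(calls, rate) {
  if (rate > 0) calls[stats::runif(length(calls)) < rate] <- NA_integer_
  calls
}

#' Simulate a (possibly structured) population
#'
#' Draws genotype tables under the configuration: Balding-Nichols
#' population-specific frequencies around the base frequencies, genotypes by
#' the inbreeding law, optional missingness.  Fully reproducible: the same
#' config (including seed) yields a bit-identical table.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{genotype_table} with a \code{region} metadata column
#'   (\code{pop1}, \code{pop2}, ...).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  blocks <- vector("list", config$n_populations)
  for (k in seq_len(config$n_populations)) {
    pk <- .bn_freqs(config$allele_freqs, config$target_fst)
    blocks[[k]] <- .draw_genotypes(config$population_sizes[k], pk,
                                   config$inbreeding_f)
  }
  calls <- do.call(rbind, blocks)
  calls <- .inject_missing(calls, config$missing_rate)
  n <- nrow(calls)
  dimnames(calls) <- list(sprintf("ind%03d", seq_len(n)),
                          sprintf("L%02d", seq_len(config$n_loci)))
  genotype_table(calls,
                 samples = data.frame(
                   sample_id = rownames(calls),
                   region = rep(paste0("pop", seq_len(config$n_populations)),
                                times = config$population_sizes),
                   stringsAsFactors = FALSE))
}

# one Mendelian gamete per locus from a parental dosage vector
.gamete <- function(dosage) {
  ifelse(dosage == 0L, 0L,
         ifelse(dosage == 2L, 1L,
                as.integer(stats::runif(length(dosage)) < 0.5)))
}

.mate <- function(a, b) .gamete(a) + .gamete(b)

#' Simulate families with Mendelian transmission
#'
#' Founder genotypes are drawn as in \code{\link{simulate_population}}
#' (single population); offspring receive one uniformly random allele from
#' each parent, per locus.  Twins are independent meioses of the same parents
#' (dizygotic).  Optional grandchildren are produced by the first offspring
#' of a family and a new unrelated founder, giving grandparent chains.  All
#' generated relations are recorded in the returned pedigree, and each
#' individual carries a \code{family_id}.
#'
#' @param config a \code{\link{sim_config}} whose \code{pedigree_spec} is
#'   used; \code{n_populations} must be 1.
#' @return a list with components \code{table} (a \code{genotype_table}) and
#'   \code{pedigree}.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$pedigree_spec
  if (is.null(spec$n_families) || is.null(spec$n_offspring))
    stop("pedigree_spec needs n_families and n_offspring")
  if ((spec$n_parents %||% 2) < 2 && spec$n_offspring > 0)
    stop("a family template with offspring needs two parents")
  n_gc <- spec$n_grandchildren %||% 0
  n_tw <- spec$n_twin_pairs %||% 0
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  p <- config$allele_freqs
  f <- config$inbreeding_f
  rows <- list(); meta <- list()
  po <- list(); tw <- list(); gp <- list()
  add <- function(id, fam, g) {
    rows[[id]] <<- g
    meta[[id]] <<- data.frame(sample_id = id, family_id = fam,
                              stringsAsFactors = FALSE)
  }
  for (fam in seq_len(spec$n_families)) {
    famid <- sprintf("fam%02d", fam)
    sire <- sprintf("%s_sire", famid); dam <- sprintf("%s_dam", famid)
    add(sire, famid, drop(.draw_genotypes(1, p, f)))
    add(dam, famid, drop(.draw_genotypes(1, p, f)))
    kids <- character(spec$n_offspring)
    for (o in seq_len(spec$n_offspring)) {
      kid <- sprintf("%s_off%d", famid, o)
      kids[o] <- kid
      add(kid, famid, .mate(rows[[sire]], rows[[dam]]))
      po[[length(po) + 1L]] <- c(sire, kid)
      po[[length(po) + 1L]] <- c(dam, kid)
    }
    if (fam <= n_tw && spec$n_offspring >= 2)
      tw[[length(tw) + 1L]] <- c(kids[1], kids[2])
    if (n_gc > 0) {
      if (spec$n_offspring < 1) stop("grandchildren need an offspring generation")
      mate <- sprintf("%s_mate", famid)
      add(mate, famid, drop(.draw_genotypes(1, p, f)))
      for (gck in seq_len(n_gc)) {
        gc_id <- sprintf("%s_gc%d", famid, gck)
        add(gc_id, famid, .mate(rows[[kids[1]]], rows[[mate]]))
        po[[length(po) + 1L]] <- c(kids[1], gc_id)
        po[[length(po) + 1L]] <- c(mate, gc_id)
        gp[[length(gp) + 1L]] <- c(sire, gc_id)
        gp[[length(gp) + 1L]] <- c(dam, gc_id)
      }
    }
  }
  calls <- do.call(rbind, rows)
  colnames(calls) <- sprintf("L%02d", seq_len(config$n_loci))
  calls <- .inject_missing(calls, config$missing_rate)
  tab <- genotype_table(calls, samples = do.call(rbind, c(meta,
                                                          make.row.names = FALSE)))
  ped <- pedigree(
    parent_offspring = if (length(po)) as.data.frame(do.call(rbind, po),
                                                     stringsAsFactors = FALSE),
    twins = if (length(tw)) as.data.frame(do.call(rbind, tw),
                                          stringsAsFactors = FALSE),
    grandparent = if (length(gp)) as.data.frame(do.call(rbind, gp),
                                                stringsAsFactors = FALSE))
  list(table = tab, pedigree = ped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
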
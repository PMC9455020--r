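# Independent oracles used to cross-check the closed-form implementations.
# These are deliberately brute-force and share no code with the package.

# PIC by literal evaluation of the double sum
oracle_pic <- function(p) {
  k <- length(p)
  s <- 1 - sum(p^2)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j)
    s <- s - 2 * p[i]^2 * p[j]^2
  s
}

# Exact conditional HWE distribution by enumerating every placement of the
# variant gene copies onto the 2n ordered allele slots (all placements are
# equally likely given the allele counts), then tabulating heterozygote counts.
oracle_hwe_enum <- function(n_ww, n_wv, n_vv) {
  n <- n_ww + n_wv + n_vv
  nv <- 2 * n_vv + n_wv
  if (nv == 0 || nv == 2 * n) return(1)
  slots <- utils::combn(2 * n, nv)          # which slots carry the V allele
  het_of <- apply(slots, 2, function(vpos) {
    x <- integer(2 * n); x[vpos] <- 1L
    dos <- x[seq(1, 2 * n, 2)] + x[seq(2, 2 * n, 2)]
    sum(dos == 1L)
  })
  tab <- table(het_of) / ncol(slots)        # P(k heterozygotes | allele counts)
  obs <- tab[as.character(n_wv)]
  sum(tab[tab <= obs * (1 + 1e-12)])
}

# Weir & Cockerham components through the ANOVA mean-squares route
# (per allele, both alleles summed), an algebraically different path from the
# closed-form estimator in the package.
oracle_wc_ms <- function(dosage, pop) {
  keep <- !is.na(dosage)
  dosage <- dosage[keep]; pop <- as.character(pop)[keep]
  out <- c(a = 0, b = 0, c = 0)
  for (allele in c("v", "w")) {
    y <- if (allele == "v") dosage / 2 else 1 - dosage / 2  # mean allele indicator
    sp <- split(seq_along(y), pop)
    ni <- lengths(sp); r <- length(sp); N <- sum(ni)
    pi <- vapply(sp, function(ix) mean(y[ix]), numeric(1))
    pbar <- sum(ni * pi) / N
    het <- ifelse(dosage == 1L, 1, 0)
    ssg <- sum(het) * 0.5                       # genes within individuals
    ssi <- 2 * sum(unlist(lapply(seq_along(sp), function(k)
      (y[sp[[k]]] - pi[k])^2)))                 # individuals within pops
    ssp <- 2 * sum(ni * (pi - pbar)^2)          # among pops
    msg <- ssg / N
    msi <- if (N - r > 0) ssi / (N - r) else 0
    c_comp <- msg
    b_comp <- (msi - msg) / 2
    if (r > 1) {
      msp <- ssp / (r - 1)
      nc <- (N - sum(ni^2) / N) / (r - 1)
      a_comp <- (msp - msi) / (2 * nc)
    } else a_comp <- 0
    out <- out + c(a = a_comp, b = b_comp, c = c_comp)
  }
  out
}

# HWE genotype distribution at a biallelic locus: P(WW, WV, VV)
.hwe_geno <- function(p) c(ww = (1 - p)^2, wv = 2 * p * (1 - p), vv = p^2)

# genotype as allele multiset
.alleles_of <- function(g) switch(g, ww = c("w", "w"), wv = c("w", "v"),
                                  vv = c("v", "v"))

# can offspring o be produced by parents a and b?
.trio_compatible <- function(o, a, b) {
  oa <- sort(.alleles_of(o))
  for (x in .alleles_of(a)) for (y in .alleles_of(b))
    if (identical(sort(c(x, y)), oa)) return(TRUE)
  FALSE
}

# does candidate c share at least one allele with offspring o?
.duo_compatible <- function(o, c) length(intersect(.alleles_of(o), .alleles_of(c))) > 0

# Non-exclusion probabilities by exhaustive enumeration over HWE genotypes
oracle_ne_identity <- function(p) sum(.hwe_geno(p)^2)

oracle_ne_first_parent <- function(p) {
  pg <- .hwe_geno(p); s <- 0
  for (o in names(pg)) for (cand in names(pg))
    if (.duo_compatible(o, cand)) s <- s + pg[o] * pg[cand]
  unname(s)
}

oracle_ne_parent_pair <- function(p) {
  pg <- .hwe_geno(p); s <- 0
  for (o in names(pg)) for (c1 in names(pg)) for (c2 in names(pg))
    if (.trio_compatible(o, c1, c2)) s <- s + pg[o] * pg[c1] * pg[c2]
  unname(s)
}

# second parent: true parents (m, f) in HWE, offspring by Mendelian
# transmission, candidate c replaces f; m is known
oracle_ne_second_parent <- function(p) {
  pg <- .hwe_geno(p); s <- 0
  for (m in names(pg)) for (f in names(pg)) {
    # offspring distribution given (m, f)
    off <- c(ww = 0, wv = 0, vv = 0)
    for (x in .alleles_of(m)) for (y in .alleles_of(f)) {
      g <- if (x == y) paste0(x, x) else "wv"
      off[g] <- off[g] + 0.25
    }
    for (o in names(off)) if (off[o] > 0)
      for (cand in names(pg))
        if (.trio_compatible(o, m, cand))
          s <- s + pg[m] * pg[f] * off[o] * pg[cand]
  }
  unname(s)
}

# silhouette of a 1-d embedding under a 2-group labelling
oracle_silhouette <- function(x, grp) {
  d <- abs(outer(x, x, "-"))
  s <- vapply(seq_along(x), function(i) {
    own <- grp == grp[i]; own[i] <- FALSE
    a <- mean(d[i, own]); b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# small builder used across tests
make_table <- function(dosages, region = NULL) {
  m <- as.matrix(dosages)
  samples <- data.frame(sample_id = rownames(m) %||%
                          as.character(seq_len(nrow(m))),
                        stringsAsFactors = FALSE)
  if (!is.null(region)) samples$region <- region
  rownames(m) <- samples$sample_id
  genotype_table(m, samples = samples)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
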
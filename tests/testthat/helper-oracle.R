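# Brute-force allele-counting oracle for the population-genetic metrics,
# written independently of the package implementation: explicit loops over
# individuals, alleles and patches, no vectorised shortcuts.

oracle_ho <- function(geno) {
  nl <- ncol(geno) / 2
  het <- 0
  for (i in seq_len(nrow(geno))) {
    for (l in seq_len(nl)) {
      if (geno[i, 2 * l - 1] != geno[i, 2 * l]) het <- het + 1
    }
  }
  het / (nrow(geno) * nl)
}

oracle_fstats <- function(geno, patch) {
  pats <- c()
  for (p in unique(patch)) if (sum(patch == p) >= 2) pats <- c(pats, p)
  if (length(pats) < 2) return(list(fst = NA_real_, fis = NA_real_))
  nl <- ncol(geno) / 2
  fst_vals <- c(); fis_vals <- c()
  for (l in seq_len(nl)) {
    hs_sum <- 0; ho_sum <- 0
    pool <- list()
    for (p in pats) {
      alleles <- c()
      het <- 0; n_ind <- 0
      for (i in which(patch == p)) {
        a <- geno[i, 2 * l - 1]; b <- geno[i, 2 * l]
        alleles <- c(alleles, a, b)
        n_ind <- n_ind + 1
        if (a != b) het <- het + 1
      }
      sq <- 0
      for (al in unique(alleles)) {
        f <- sum(alleles == al) / length(alleles)
        sq <- sq + f * f
      }
      hs_sum <- hs_sum + (1 - sq)
      ho_sum <- ho_sum + het / n_ind
      pool[[as.character(p)]] <- alleles
    }
    hs <- hs_sum / length(pats)
    ho <- ho_sum / length(pats)
    # pooled frequencies weight patches equally
    all_alleles <- unique(unlist(pool))
    sq <- 0
    for (al in all_alleles) {
      f <- 0
      for (p in pats) {
        ap <- pool[[as.character(p)]]
        f <- f + sum(ap == al) / length(ap)
      }
      f <- f / length(pats)
      sq <- sq + f * f
    }
    ht <- 1 - sq
    if (ht > 0) fst_vals <- c(fst_vals, (ht - hs) / ht)
    if (hs > 0) fis_vals <- c(fis_vals, 1 - ho / hs)
  }
  list(fst = if (length(fst_vals) == 0) NA_real_ else mean(fst_vals),
       fis = if (length(fis_vals) == 0) NA_real_ else mean(fis_vals))
}

# random small population for oracle comparisons: few individuals, few
# distinct alleles so fixation and monomorphism occur
random_small_population <- function(n_ind = NULL, n_loci = 4,
                                    n_alleles = 3) {
  if (is.null(n_ind)) n_ind <- sample(4:12, 1)
  geno <- matrix(sample.int(n_alleles, n_ind * 2 * n_loci, replace = TRUE) +
                 100L, n_ind, 2 * n_loci)
  patch <- sample(1:2, n_ind, replace = TRUE)
  list(geno = geno, patch = patch)
}

# brute-force pedigree descendant counting by repeated scans (no recursion)
oracle_descendants <- function(pedigree, founder, horizon = Inf) {
  desc <- c(founder)
  repeat {
    added <- FALSE
    for (i in seq_len(nrow(pedigree))) {
      row <- pedigree[i, ]
      if (is.na(row$mother)) next
      if (row$birth_year > horizon) next
      if ((row$mother %in% desc || row$father %in% desc) &&
          !(row$id %in% desc)) {
        desc <- c(desc, row$id)
        added <- TRUE
      }
    }
    if (!added) break
  }
  length(desc) - 1
}
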
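#' Neutral microsatellite genetics parameters
#'
#' Individuals carry `n_loci` diploid microsatellite loci (default 12, i.e.
#' 24 alleles, one maternal and one paternal per locus), stored as integer
#' repeat lengths. Mutation follows the stepwise mutation model at rate `mu`
#' per locus per generation, applied to each transmitted allele at
#' inheritance. Founder alleles are drawn uniformly (with replacement) from
#' `founder_allele_min:founder_allele_max`.
#'
#' @param n_loci number of diploid loci.
#' @param mutation_rate per-locus per-generation mutation probability.
#' @param founder_allele_min,founder_allele_max inclusive bounds of founder
#'   allele lengths.
#' @return An object of class `genetics_params`.
#' @export
genetics_params <- function(n_loci = 12L, mutation_rate = 1e-4,
                            founder_allele_min = 120L,
                            founder_allele_max = 220L) {
  stopifnot(n_loci >= 1, mutation_rate >= 0, mutation_rate <= 1,
            founder_allele_min >= 1,
            founder_allele_min <= founder_allele_max)
  structure(list(n_loci = as.integer(n_loci), mutation_rate = mutation_rate,
                 founder_allele_min = as.integer(founder_allele_min),
                 founder_allele_max = as.integer(founder_allele_max)),
            class = "genetics_params")
}

# Genotypes are integer matrices with one row per individual and 2 * n_loci
# columns; locus l occupies columns 2l-1 (maternal slot) and 2l (paternal
# slot). Slot order is preserved for bookkeeping but all metrics are
# invariant to it.

#' Sample founder genotypes
#'
#' Each founder receives `2 * n_loci` alleles drawn independently and
#' uniformly (with replacement) from the founder allele range, emulating
#' founders sampled unrelated from a large, diverse autochthonous
#' population. With the default range of 101 possible lengths the expected
#' per-locus heterozygosity of a founder is `1 - 1/101` (about 0.99).
#'
#' @param params a [genetics_params()].
#' @param n number of founders.
#' @return Integer matrix `n` x `2 * n_loci`.
#' @export
sample_founder_genotype <- function(params, n = 1L) {
  stopifnot(inherits(params, "genetics_params"))
  k <- 2L * params$n_loci
  vals <- params$founder_allele_min:params$founder_allele_max
  matrix(vals[sample.int(length(vals), n * k, replace = TRUE)],
         nrow = n, ncol = k)
}

#' Stepwise mutation of microsatellite alleles
#'
#' Each allele mutates independently with probability `mu`; a mutating
#' allele increases or decreases its length by 1 with equal probability.
#' Because a repeat length of zero is impossible, an allele of length 1
#' that draws the decreasing step keeps its length instead, so a forced
#' mutation at length 1 yields 1 or 2 with equal probability.
#'
#' @param alleles integer vector of allele lengths (all >= 1).
#' @param mu mutation probability per allele.
#' @return Integer vector of (possibly) mutated lengths.
#' @export
mutate_smm <- function(alleles, mu) {
  if (any(alleles < 1)) stop("allele lengths must be >= 1")
  if (mu <= 0) return(as.integer(alleles))
  hit <- runif(length(alleles)) < mu
  if (any(hit)) {
    step <- ifelse(runif(sum(hit)) < 0.5, -1L, 1L)
    out <- alleles[hit] + step
    out[out < 1L] <- 1L
    alleles[hit] <- out
  }
  as.integer(alleles)
}

#' Mendelian inheritance with stepwise mutation
#'
#' For each locus the offspring receives one of the mother's two alleles
#' (probability 1/2 each) into its maternal slot and one of the father's two
#' alleles (probability 1/2 each) into its paternal slot; every transmitted
#' allele is then passed through [mutate_smm()] at the parameter mutation
#' rate.
#'
#' @param mother,father genotype vectors of length `2 * n_loci`.
#' @param params a [genetics_params()].
#' @return Offspring genotype vector of length `2 * n_loci`.
#' @export
inherit <- function(mother, father, params) {
  stopifnot(inherits(params, "genetics_params"))
  nl <- params$n_loci
  if (length(mother) != 2L * nl || length(father) != 2L * nl)
    stop("locus-count mismatch between genotypes and parameters")
  base <- 2L * seq_len(nl) - 1L
  m_pick <- mother[base + (runif(nl) < 0.5)]
  p_pick <- father[base + (runif(nl) < 0.5)]
  off <- integer(2L * nl)
  off[base] <- mutate_smm(m_pick, params$mutation_rate)
  off[base + 1L] <- mutate_smm(p_pick, params$mutation_rate)
  off
}

#' Export genotypes in GENEPOP format
#'
#' Writes a sampled population as GENEPOP text (one `Pop` block per patch,
#' alleles as 3-digit codes) for cross-validation with external
#' population-genetics software.
#'
#' @param genotypes integer matrix, individuals x `2 * n_loci`.
#' @param patch integer or character vector assigning each individual to a
#'   subpopulation.
#' @param path output file path.
#' @param title first (comment) line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(genotypes, patch, path,
                          title = "felidgen sampled population") {
  stopifnot(nrow(genotypes) == length(patch))
  nl <- ncol(genotypes) %/% 2L
  if (any(genotypes > 999L))
    stop("GENEPOP 3-digit coding cannot represent alleles > 999")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("locus%02d", seq_len(nl)), con)
  for (p in unique(patch)) {
    writeLines("Pop", con)
    for (i in which(patch == p)) {
      g <- genotypes[i, ]
      codes <- vapply(seq_len(nl), function(l) {
        sprintf("%03d%03d", g[2L * l - 1L], g[2L * l])
      }, character(1))
      writeLines(paste0("ind_", p, "_", i, " , ", paste(codes, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
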
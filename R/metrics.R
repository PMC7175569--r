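#' Sample residents for genetic analysis
#'
#' Population-genetic outputs are computed on living residents only (only
#' residents take part in reproduction). At most `max_per_patch` residents
#' are taken per breeding patch, uniformly without replacement when a patch
#' holds more. The sampling RNG is seeded independently of the simulation
#' stream so metric subsampling never perturbs trajectories.
#'
#' @param st a `felid_state`.
#' @param max_per_patch maximum residents per patch (default 30).
#' @param seed optional integer seed for the subsampling draw.
#' @return List with `genotypes` (matrix), `patch` (integer labels), `ids`.
#' @export
sample_residents <- function(st, max_per_patch = 30L, seed = NULL) {
  p <- individual_patch(st)
  res <- which(st$status == ST_RESIDENT)
  keep <- with_seed(seed, {
    unlist(lapply(unique(p[res]), function(k) {
      i <- res[p[res] == k]
      if (length(i) > max_per_patch) sample(i, max_per_patch) else i
    }))
  })
  keep <- sort(keep)
  list(genotypes = st$geno[keep, , drop = FALSE],
       patch = p[keep], ids = st$id[keep])
}

#' Observed heterozygosity
#'
#' The fraction of heterozygous (individual, locus) pairs: a diploid locus
#' is heterozygous when its two alleles differ. Averaging over loci within
#' individuals and then over individuals is equivalent, for complete data,
#' to the overall fraction reported here. Values near 1 indicate high
#' genetic diversity, near 0 strong fixation.
#'
#' @param genotypes integer matrix, individuals x `2 * n_loci`.
#' @return Proportion in `[0, 1]`.
#' @export
observed_heterozygosity <- function(genotypes) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  if (nrow(genotypes) == 0) stop("empty sample")
  nl <- ncol(genotypes) %/% 2L
  a1 <- genotypes[, 2L * seq_len(nl) - 1L, drop = FALSE]
  a2 <- genotypes[, 2L * seq_len(nl), drop = FALSE]
  mean(a1 != a2)
}

#' F-statistics (Nei) across breeding patches
#'
#' Per locus, the mean within-patch expected heterozygosity `Hs` (patches
#' weighted equally), the total expected heterozygosity `Ht` from allele
#' frequencies pooled across patches (again weighting patches equally), and
#' the mean within-patch observed heterozygosity `Ho` are computed from
#' allele counts. The fixation index is `FST = (Ht - Hs) / Ht` (Nei's Gst
#' form) averaged over loci with `Ht > 0`, the inbreeding coefficient
#' `FIS = 1 - Ho / Hs` averaged over loci with `Hs > 0`; monomorphic loci
#' are excluded from the respective averages. Expected heterozygosities use
#' the plain `1 - sum(p^2)` form without small-sample correction. With
#' fewer than two patches holding at least two individuals each, both
#' statistics are `NA` (a two-subpopulation structure is required, e.g.
#' after failed colonisation of the arrival patch).
#'
#' @param genotypes integer matrix, individuals x `2 * n_loci`.
#' @param patch vector assigning individuals to patches.
#' @return List with elements `fst` and `fis`.
#' @export
f_statistics <- function(genotypes, patch) {
  stopifnot(nrow(genotypes) == length(patch))
  pats <- unique(patch)
  pats <- pats[vapply(pats, function(k) sum(patch == k), numeric(1)) >= 2]
  if (length(pats) < 2) return(list(fst = NA_real_, fis = NA_real_))
  nl <- ncol(genotypes) %/% 2L
  fst_l <- fis_l <- rep(NA_real_, nl)
  for (l in seq_len(nl)) {
    a1 <- genotypes[, 2L * l - 1L]
    a2 <- genotypes[, 2L * l]
    alleles <- sort(unique(c(a1, a2)))
    freqs <- matrix(0, length(pats), length(alleles))
    hs_p <- ho_p <- numeric(length(pats))
    for (pi in seq_along(pats)) {
      sel <- patch == pats[pi]
      cnt <- table(factor(c(a1[sel], a2[sel]), levels = alleles))
      f <- as.numeric(cnt) / sum(cnt)
      freqs[pi, ] <- f
      hs_p[pi] <- 1 - sum(f^2)
      ho_p[pi] <- mean(a1[sel] != a2[sel])
    }
    hs <- mean(hs_p)
    ho <- mean(ho_p)
    pool <- colMeans(freqs)
    ht <- 1 - sum(pool^2)
    if (ht > 0) fst_l[l] <- (ht - hs) / ht
    if (hs > 0) fis_l[l] <- 1 - ho / hs
  }
  list(fst = if (all(is.na(fst_l))) NA_real_ else mean(fst_l, na.rm = TRUE),
       fis = if (all(is.na(fis_l))) NA_real_ else mean(fis_l, na.rm = TRUE))
}

#' Moving-window population growth factors
#'
#' For a per-patch census series `N_0, ..., N_T` the growth factor over
#' 20-year windows is `lambda_t = N_t / N_(t-20)` for window ends
#' `t = 40, 60, ..., T`. The first window (`t = 20`) is excluded because its
#' reference can be an initially empty patch (infinite lambda); windows with
#' a zero denominator yield `NA`.
#'
#' @param n numeric vector of yearly patch counts, element `i` holding year
#'   `i - 1` (so `n[1]` is year 0); at least 41 years (indices) long.
#' @param interval window length in years (default 20).
#' @return Data frame with columns `t` (window end year) and `lambda`.
#' @export
lambda_series <- function(n, interval = 20L) {
  t_max <- length(n) - 1L
  if (t_max < 2L * interval)
    stop("census must cover at least ", 2L * interval, " years")
  ends <- seq.int(2L * interval, t_max, by = interval)
  lam <- vapply(ends, function(t) {
    denom <- n[t - interval + 1L]
    if (is.na(denom) || denom == 0) NA_real_ else n[t + 1L] / denom
  }, numeric(1))
  data.frame(t = ends, lambda = lam)
}

#' Colonisation success of the arrival patch
#'
#' `TRUE` iff at least one resident holds a territory in the arrival patch;
#' dispersers merely present in the patch do not count.
#'
#' @param st a `felid_state`.
#' @return Logical scalar.
#' @export
colonisation_success <- function(st) {
  p <- individual_patch(st)
  any(st$status == ST_RESIDENT & p == PATCH[["ARRIVAL"]])
}

#' Descendant counts per founder
#'
#' Computes, for every founder (individual without recorded parents), the
#' size of its descendant set — the transitive closure over the
#' mother/father links — among individuals born by `horizon_year`, plus
#' whether the founder took part in reproduction at all.
#'
#' @param pedigree a [pedigree_table()] data frame.
#' @param horizon_year count descendants born in or before this year
#'   (default `Inf`, all).
#' @return Data frame with columns `id`, `n_descendants`,
#'   `has_descendant`.
#' @export
descendants_per_founder <- function(pedigree, horizon_year = Inf) {
  founders <- pedigree$id[is.na(pedigree$mother) & is.na(pedigree$father)]
  kids <- pedigree[!is.na(pedigree$mother) &
                   pedigree$birth_year <= horizon_year, ]
  children <- split(rep(kids$id, 2L), c(kids$mother, kids$father))
  n_desc <- vapply(founders, function(f) {
    seen <- integer(0)
    frontier <- children[[as.character(f)]]
    while (length(frontier) > 0) {
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      frontier <- unlist(children[as.character(frontier)], use.names = FALSE)
    }
    length(seen)
  }, numeric(1))
  data.frame(id = founders, n_descendants = n_desc,
             has_descendant = n_desc > 0)
}
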
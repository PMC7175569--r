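test_that("observed heterozygosity handles the limiting cases", {
  hom <- rbind(rep(c(5L, 5L), 12), rep(c(7L, 7L), 12))
  expect_equal(observed_heterozygosity(hom), 0)
  het <- matrix(rep(c(1L, 2L), 12), nrow = 1)
  expect_equal(observed_heterozygosity(het), 1)
  expect_equal(observed_heterozygosity(rbind(hom[1, ], het[1, ])), 0.5)
  expect_error(observed_heterozygosity(hom[0, , drop = FALSE]), "empty")
})

test_that("F-statistics match hand-computed values", {
  # patch A all (1,1), patch B all (1,2) at every locus:
  # Hs = (0 + 0.5)/2 = 0.25, pooled p1 = 0.75 -> Ht = 0.375, FST = 1/3
  a <- matrix(rep(c(1L, 1L), 12), 3, 24, byrow = TRUE)
  b <- matrix(rep(c(1L, 2L), 12), 3, 24, byrow = TRUE)
  fs <- f_statistics(rbind(a, b), rep(1:2, each = 3))
  expect_equal(fs$fst, 1 / 3)

  # complete differentiation: patches fixed for different alleles
  b2 <- matrix(rep(c(9L, 9L), 12), 3, 24, byrow = TRUE)
  expect_equal(f_statistics(rbind(a, b2), rep(1:2, each = 3))$fst, 1)

  # identical allele frequencies: panmixia limit
  p <- rbind(rep(c(1L, 2L), 12), rep(c(2L, 1L), 12))
  expect_equal(f_statistics(rbind(p, p), rep(1:2, each = 2))$fst, 0)

  # single patch -> NA
  fs1 <- f_statistics(a, rep(1, 3))
  expect_true(is.na(fs1$fst) && is.na(fs1$fis))

  # fully monomorphic data -> NA (no polymorphic locus)
  mono <- matrix(rep(c(4L, 4L), 12), 4, 24, byrow = TRUE)
  expect_true(is.na(f_statistics(mono, rep(1:2, each = 2))$fst))
})

test_that("metrics agree with the brute-force oracle on random populations", {
  set.seed(30)
  for (i in 1:100) {
    pop <- random_small_population()
    expect_equal(observed_heterozygosity(pop$geno), oracle_ho(pop$geno),
                 tolerance = 1e-12)
    fs <- f_statistics(pop$geno, pop$patch)
    or <- oracle_fstats(pop$geno, pop$patch)
    expect_equal(fs$fst, or$fst, tolerance = 1e-12)
    expect_equal(fs$fis, or$fis, tolerance = 1e-12)
  }
})

test_that("F-statistics are invariant to relabelling patches and individuals", {
  set.seed(31)
  pop <- random_small_population(n_ind = 12)
  fs <- f_statistics(pop$geno, pop$patch)
  perm <- sample(nrow(pop$geno))
  fs_perm <- f_statistics(pop$geno[perm, ], pop$patch[perm])
  expect_equal(fs, fs_perm)
  relab <- c(7, 3)[pop$patch]
  expect_equal(f_statistics(pop$geno, relab), fs)
})

test_that("lambda series follows the 20-year window definition", {
  years <- 0:200
  expect_equal(lambda_series(rep(30, 201))$lambda, rep(1, 9))
  expect_equal(lambda_series(2^(years / 20))$lambda, rep(2, 9))
  lam <- lambda_series(rep(30, 201))
  expect_equal(lam$t, seq(40, 200, by = 20))
  # zero denominators yield NA (never-colonised arrival patch)
  expect_true(all(is.na(lambda_series(rep(0, 201))$lambda)))
  expect_error(lambda_series(rep(1, 30)), "census")
})

test_that("colonisation needs resident territories in the arrival patch", {
  g <- assemble_three_patch(landscape_spec(control = "CS2"))
  set.seed(32)
  st <- initialize_founders(4, g)
  expect_false(colonisation_success(st))
  # a disperser standing in the arrival patch does not colonise
  st$row[1] <- 30; st$col[1] <- 160
  expect_false(colonisation_success(st))
  # a settled female there does
  st$sex[2] <- 1L
  st$row[2] <- 30; st$col[2] <- 160
  expect_true(settle_female(st, st$id[2]))
  expect_true(colonisation_success(st))
})

test_that("residents are subsampled to at most 30 per patch", {
  g <- breeding_patch_grid(65, 40) # 2600 cells, room for ~50 territories
  set.seed(33)
  st <- initialize_founders(100, g)
  for (f in st$id[st$sex == 1L]) settle_female(st, f)
  n_res <- sum(st$status == 2L)
  expect_gt(n_res, 30)
  samp <- sample_residents(st, 30, seed = 1)
  expect_equal(nrow(samp$genotypes), 30)
  samp2 <- sample_residents(st, 30, seed = 1)
  expect_identical(samp$ids, samp2$ids)
  # subsampling shifts Ho only by sampling noise
  full_ho <- observed_heterozygosity(st$geno[st$status == 2L, ])
  hos <- sapply(1:100, function(s)
    observed_heterozygosity(sample_residents(st, 30, seed = s)$genotypes))
  expect_lt(abs(mean(hos) - full_ho), 0.01)
})

test_that("descendant counts follow the pedigree transitive closure", {
  ped <- data.frame(
    id = c(1, 2, 3, 10, 11, 12),
    sex = c(1, 2, 1, 1, 2, 1),
    mother = c(NA, NA, NA, 1, 10, 11),
    father = c(NA, NA, NA, 2, 2, 2),
    birth_year = c(-1, -1, -1, 1, 5, 9))
  d <- descendants_per_founder(ped)
  expect_equal(d$n_descendants[d$id == 3], 0) # childless founder
  expect_equal(d$n_descendants[d$id == 1], 3) # chain 1 -> 10 -> 11 -> 12
  expect_equal(d$n_descendants[d$id == 2], 3)
  expect_false(d$has_descendant[d$id == 3])
  # horizon cuts descendants born later
  d5 <- descendants_per_founder(ped, horizon_year = 5)
  expect_equal(d5$n_descendants[d5$id == 1], 2)
})

test_that("descendant counts agree with a brute-force traversal on a run", {
  r <- run_cs3(10, years = 25, seed = 5)
  ped <- r$pedigree
  d <- descendants_per_founder(ped, horizon_year = 20)
  founders <- ped$id[is.na(ped$mother)]
  for (f in founders) {
    expect_equal(d$n_descendants[d$id == f],
                 oracle_descendants(ped, f, horizon = 20))
  }
  # first-generation identity: summed parent slots equal twice the number of
  # offspring with two founder parents plus those with one
  kids <- ped[!is.na(ped$mother), ]
  direct <- sapply(founders, function(f)
    sum(kids$mother == f) + sum(kids$father == f))
  n2 <- sum(kids$mother %in% founders & kids$father %in% founders)
  n1 <- sum(xor(kids$mother %in% founders, kids$father %in% founders))
  expect_equal(sum(direct), 2 * n2 + n1)
})
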
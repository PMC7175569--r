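test_that("founders have even sex ratio, source locations, and reproducible genotypes", {
  g <- assemble_three_patch(landscape_spec(control = "CS3"))
  set.seed(10)
  st <- initialize_founders(10, g)
  expect_equal(sum(st$sex == 1L), 5)
  expect_equal(sum(st$sex == 2L), 5)
  expect_true(all(st$status == 1L))
  expect_true(all(st$age >= 1))
  expect_true(all(g$patch[cbind(st$row, st$col)] == PATCH[["SOURCE"]]))
  expect_true(all(g$classes[cbind(st$row, st$col)] == HABITAT[["BREEDING"]]))
  expect_true(all(is.na(st$mother)))

  set.seed(123); st1 <- initialize_founders(20, g)
  set.seed(123); st2 <- initialize_founders(20, g)
  expect_identical(st1$geno, st2$geno)

  expect_warning(st3 <- initialize_founders(11, g), "floored")
  expect_equal(length(st3$id), 10)
  expect_error(initialize_founders(0, g), "positive")
})

test_that("female settlement claims the target size and respects the minimum", {
  g <- breeding_patch_grid(65, 20) # one 1300-cell patch
  set.seed(11)
  st <- initialize_founders(2, g)
  fid <- st$id[st$sex == 1L][1]
  expect_true(settle_female(st, fid))
  expect_equal(length(territory_cells(st, fid)),
               st$demography$territory_target)
  # with an explicit large target the first female takes min(146, available)
  set.seed(11)
  st2 <- initialize_founders(2, g)
  fid2 <- st2$id[st2$sex == 1L][1]
  expect_true(settle_female(st2, fid2, target = 146))
  expect_equal(length(territory_cells(st2, fid2)), 146)
})

test_that("females cannot settle where less than the minimum area is free", {
  g <- breeding_patch_grid(5, 9) # 45 cells < 46 minimum
  set.seed(12)
  st <- initialize_founders(2, g)
  fid <- st$id[st$sex == 1L][1]
  expect_false(settle_female(st, fid))
  expect_equal(length(st$terr), 0)
})

test_that("sequential female settlement saturates within the tiling bounds", {
  for (target in c(46, 146)) {
    g <- breeding_patch_grid(65, 20)
    d <- demography_params(territory_target = target)
    set.seed(13)
    st <- initialize_founders(80, g, demography = d)
    fems <- st$id[st$sex == 1L]
    for (f in fems) settle_female(st, f)
    n_settled <- length(st$terr)
    expect_gte(n_settled, 8)   # floor(1300 / 146)
    expect_lte(n_settled, 28)  # floor(1300 / 46)
    # same-sex territories are disjoint
    all_cells <- unlist(st$terr)
    expect_equal(anyDuplicated(all_cells), 0)
  }
})

test_that("males claim up to three reachable unclaimed female territories", {
  g <- breeding_patch_grid(65, 20)
  set.seed(14)
  st <- initialize_founders(20, g)
  fems <- st$id[st$sex == 1L]
  for (f in fems) settle_female(st, f)
  n_fem <- length(st$terr)
  expect_gte(n_fem, 5)
  males <- st$id[st$sex == 2L]
  # first male claims at most three although more are unclaimed; place him
  # inside the first female's territory so a claim is reachable
  j <- match(males[1], st$id)
  cell <- st$terr[[1]][1]
  st$row[j] <- (cell - 1) %% 65 + 1
  st$col[j] <- (cell - 1) %/% 65 + 1
  expect_true(settle_male(st, males[1]))
  expect_lte(sum(st$claims == males[1]), 3)
  expect_gte(sum(st$claims == males[1]), 1)
  # each female is overlapped by at most one male
  for (m in males[-1]) settle_male(st, m)
  expect_lte(length(st$claims), n_fem)
  expect_equal(anyDuplicated(names(st$claims)), 0)
  # once every female is claimed, further males cannot settle
  if (length(st$claims) == n_fem) {
    extra <- males[match(FALSE, males %in% st$claims)]
    if (!is.na(extra) && st$status[match(extra, st$id)] == 1L)
      expect_false(settle_male(st, extra))
  }
})

test_that("resident mortality is binomial at the yearly rate", {
  g <- breeding_patch_grid(65, 20)
  deaths <- 0; trials <- 0
  set.seed(15)
  for (i in 1:100) {
    st <- initialize_founders(40, g)
    fems <- st$id[st$sex == 1L]
    for (f in fems) settle_female(st, f)
    n_res <- sum(st$status == 2L)
    st$age <- rep(2L, length(st$id)) # below max_age
    n0 <- length(st$id)
    apply_mortality(st)
    # dispersers are untouched by yearly mortality
    deaths <- deaths + (n0 - length(st$id))
    trials <- trials + n_res
  }
  expect_gte(trials, 1e3)
  expect_lt(abs(deaths / trials - 0.1), 0.02)

  # with zero rates and young ages nobody dies
  st <- initialize_founders(40, g,
          demography = demography_params(p_mortality_resident_yearly = 0))
  n0 <- length(st$id)
  apply_mortality(st)
  expect_equal(length(st$id), n0)
})

test_that("disperser survival over a season matches the daily rate", {
  # large dispersal-only world, no settlement possible
  g <- uniform_grid(50, 50, HABITAT[["DISPERSAL"]])
  cfg_d <- demography_params()
  set.seed(16)
  surv <- replicate(6, {
    n <- 400
    season <- felidgen:::cpp_dispersal_season(
      g$classes, g$patch, matrix(0L, 50, 50), matrix(0L, 50, 50),
      seq_len(n), rep(2L, n), rep(25L, n), rep(25L, n),
      integer(0), integer(0), list(),
      0.03, 0.5, 10L, cumsum(build_step_distribution(45, 11)$probs),
      0.0015, 365L, 46L, 46L, 3L, 438L)
    mean(season$status == 0L)
  })
  expect_lt(abs(mean(surv) - 0.9985^365), 0.02) # ~ 0.578
})

test_that("breeding requires age, residency and an overlapping male", {
  g <- breeding_patch_grid(65, 20)
  set.seed(17)
  st <- initialize_founders(4, g)
  fid <- st$id[st$sex == 1L][1]
  mid <- st$id[st$sex == 2L][1]
  settle_female(st, fid)
  i <- match(fid, st$id)
  st$age[i] <- 2L # exactly 2: not older than 2, ineligible
  j <- match(mid, st$id)
  st$row[j] <- st$row[i]; st$col[j] <- st$col[i]
  stopifnot(settle_male(st, mid))
  out <- reproduce(st)
  expect_equal(out$n_events, 0L)
  # female without an overlapping male does not breed either
  st$age[i] <- 5L
  st$claims <- integer(0)
  st$male_occ[] <- 0L
  out2 <- reproduce(st)
  expect_equal(out2$n_events, 0L)
})

test_that("surviving independents average 1.5 per breeding event", {
  g <- breeding_patch_grid(65, 20)
  set.seed(18)
  st <- initialize_founders(2, g,
          demography = demography_params(p_breed = 1))
  fid <- st$id[st$sex == 1L][1]
  mid <- st$id[st$sex == 2L][1]
  settle_female(st, fid)
  j <- match(mid, st$id)
  st$row[j] <- st$row[match(fid, st$id)]
  st$col[j] <- st$col[match(fid, st$id)]
  stopifnot(settle_male(st, mid))
  st$age[] <- 5L
  total_born <- 0; total_events <- 0
  for (i in 1:10000) {
    out <- reproduce(st)
    total_events <- total_events + out$n_events
    total_born <- total_born + out$n_born
    # discard kittens again to keep the state constant
    remove_individuals(st, which(st$status == 0L))
  }
  expect_equal(total_events, 10000)
  expect_lt(abs(total_born / total_events - 1.5), 0.05)
})

test_that("kittens inherit from their recorded parents", {
  g <- breeding_patch_grid(65, 20)
  set.seed(19)
  st <- initialize_founders(2, g,
          demography = demography_params(p_breed = 1),
          genetics = genetics_params(mutation_rate = 0))
  fid <- st$id[st$sex == 1L][1]
  mid <- st$id[st$sex == 2L][1]
  settle_female(st, fid)
  j0 <- match(mid, st$id)
  st$row[j0] <- st$row[match(fid, st$id)]
  st$col[j0] <- st$col[match(fid, st$id)]
  stopifnot(settle_male(st, mid))
  st$age[] <- 5L
  while (sum(st$status == 0L) == 0) reproduce(st)
  kit <- which(st$status == 0L)[1]
  i <- match(fid, st$id); j <- match(mid, st$id)
  expect_equal(st$mother[kit], fid)
  expect_equal(st$father[kit], mid)
  for (l in seq_len(12)) {
    expect_true(st$geno[kit, 2 * l - 1] %in% st$geno[i, (2 * l - 1):(2 * l)])
    expect_true(st$geno[kit, 2 * l] %in% st$geno[j, (2 * l - 1):(2 * l)])
  }
})

test_that("a felid year preserves the census bookkeeping identity", {
  set.seed(20)
  cfg <- sim_config(landscape_spec(control = "CS3"), ms = "shy",
                    n_founders = 20, years = 40, master_seed = 3)
  r <- run_simulation(cfg, 1)
  cen <- r$census
  ev <- r$events
  tot <- aggregate(cbind(n_residents, n_dispersers) ~ year, cen, sum)
  n_alive <- tot$n_residents + tot$n_dispersers
  for (y in seq_len(nrow(ev))) {
    deaths <- ev$deaths_residents[y] + ev$deaths_dispersers_source[y] +
      ev$deaths_dispersers_connectivity[y] + ev$deaths_dispersers_arrival[y]
    # alive(t+1) = alive(t) - deaths + births - max-age deaths; max-age
    # removals are not itemised so the identity is an upper bound equality
    expect_lte(n_alive[y + 1], n_alive[y] - deaths + ev$births[y])
  }
})

test_that("advancing an empty population records an empty census without error", {
  g <- breeding_patch_grid(65, 20)
  set.seed(21)
  st <- initialize_founders(2, g)
  remove_individuals(st, 1:2)
  expect_silent(advance_year(st, "shy"))
  expect_true(st$extinct)
  cen <- census_table(st)
  expect_true(all(cen$n_residents == 0))
})

test_that("territory invariants hold after simulated years", {
  set.seed(22)
  cfg <- sim_config(landscape_spec(control = "CS3"), ms = "shy",
                    n_founders = 30, years = 30, master_seed = 9)
  r <- run_simulation(cfg, 1)
  st <- r$final_state
  # female territories disjoint and within bounds
  cells <- unlist(st$terr)
  expect_equal(anyDuplicated(cells), 0)
  sizes <- lengths(st$terr)
  expect_true(all(sizes >= st$demography$territory_min))
  expect_true(all(sizes <= st$demography$territory_max))
  # resident <=> non-empty territory
  for (i in seq_along(st$id)) {
    tc <- territory_cells(st, st$id[i])
    if (st$status[i] == 2L) expect_gt(length(tc), 0)
    else expect_equal(length(tc), 0)
  }
  # every claimed female exists and is claimed by exactly one living male
  expect_true(all(names(st$claims) %in% names(st$terr)))
  expect_true(all(st$claims %in% st$id))
  expect_true(all(table(names(st$claims)) == 1))
  # males overlap 1-3 females
  expect_true(all(table(st$claims) <= st$demography$max_females_per_male))
})

test_that("the mortality rate identity and closed-form survival hold", {
  d <- demography_params()
  expect_equal(365 * d$p_mortality_disperser_daily, 0.5475)
  expect_lt(abs(365 * d$p_mortality_disperser_daily - 0.547), 1e-3)
  expect_equal((1 - d$p_mortality_disperser_daily)^365, 0.578,
               tolerance = 1e-3)
})
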
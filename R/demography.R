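#' Demography parameters of the felid-year life cycle
#'
#' Default values follow the calibrated lynx parameterisation: dispersers
#' face a daily mortality probability `p_mortality_disperser_daily` (0.0015,
#' evaluated on each of the `season_days` dispersal days, equivalent to a
#' summed rate of about 0.547 per year), residents a yearly probability
#' `p_mortality_resident_yearly` (0.1). A resident female older than 2 years
#' whose territory is overlapped by a resident male's breeds with
#' probability `p_breed` (0.75); litter sizes of 1, 2 or 3 are drawn with
#' probabilities `litter_probs` (mean 2) and each kitten survives to
#' independence with probability `kitten_survival` (0.75), so a breeding
#' event yields on average 1.5 independent subadults entering the next year
#' as age-1 dispersers.
#'
#' Female territories are contiguous regions of breeding habitat between
#' `territory_min` (46) and `territory_max` (146) cells; settling females
#' claim `territory_target` cells by region growing (default the minimum,
#' 46, which reproduces the emergent carrying capacity of roughly 30
#' residents in a 1300-cell breeding patch). A resident male's territory
#' overlaps up to `max_females_per_male` (3) female territories; each female
#' is overlapped by at most one male.
#'
#' @param p_mortality_disperser_daily daily disperser mortality probability.
#' @param p_mortality_resident_yearly yearly resident mortality probability.
#' @param p_breed breeding probability per eligible female per year.
#' @param female_breeding_age females breed when strictly older than this
#'   (years).
#' @param independence_age age (years) at which subadults become dispersers.
#' @param litter_probs probabilities of litter sizes 1, 2, 3.
#' @param kitten_survival survival probability of each kitten to
#'   independence.
#' @param max_age individuals die when exceeding this age (years).
#' @param territory_min,territory_max,territory_target female territory
#'   bounds and claimed size, in cells (km2).
#' @param max_females_per_male maximum female territories per male.
#' @param male_search_area breeding-habitat cells a settling male searches
#'   closest-first for unclaimed female territories (the extent of a large
#'   male range, default three maximal female territories).
#' @param season_days dispersal days per felid year.
#' @return An object of class `demography_params`.
#' @export
demography_params <- function(p_mortality_disperser_daily = 0.0015,
                              p_mortality_resident_yearly = 0.1,
                              p_breed = 0.75,
                              female_breeding_age = 2L,
                              independence_age = 1L,
                              litter_probs = c(0.25, 0.5, 0.25),
                              kitten_survival = 0.75,
                              max_age = 15L,
                              territory_min = 46L,
                              territory_max = 146L,
                              territory_target = 46L,
                              max_females_per_male = 3L,
                              male_search_area = 438L,
                              season_days = 365L) {
  stopifnot(p_mortality_disperser_daily >= 0,
            p_mortality_disperser_daily <= 1,
            p_mortality_resident_yearly >= 0,
            p_mortality_resident_yearly <= 1,
            p_breed >= 0, p_breed <= 1,
            length(litter_probs) == 3, all(litter_probs >= 0),
            abs(sum(litter_probs) - 1) < 1e-9,
            kitten_survival >= 0, kitten_survival <= 1,
            territory_min >= 1, territory_min <= territory_max,
            territory_target >= territory_min,
            territory_target <= territory_max,
            max_females_per_male >= 1, male_search_area >= 1,
            max_age >= 1, season_days >= 1)
  structure(list(p_mortality_disperser_daily = p_mortality_disperser_daily,
                 p_mortality_resident_yearly = p_mortality_resident_yearly,
                 p_breed = p_breed,
                 female_breeding_age = as.integer(female_breeding_age),
                 independence_age = as.integer(independence_age),
                 litter_probs = litter_probs,
                 kitten_survival = kitten_survival,
                 mean_independents = sum(litter_probs * 1:3) * kitten_survival,
                 max_age = as.integer(max_age),
                 territory_min = as.integer(territory_min),
                 territory_max = as.integer(territory_max),
                 territory_target = as.integer(territory_target),
                 max_females_per_male = as.integer(max_females_per_male),
                 male_search_area = as.integer(male_search_area),
                 season_days = as.integer(season_days)),
            class = "demography_params")
}

# status codes
ST_KITTEN <- 0L; ST_DISPERSER <- 1L; ST_RESIDENT <- 2L
SEX_F <- 1L; SEX_M <- 2L

#' Initialise a population of founders
#'
#' Creates the simulation state for a reintroduction: `n` founders with an
#' exactly even sex ratio, disperser status, ages drawn uniformly from
#' `independence_age` to `independence_age + 2`, starting locations uniform
#' over the breeding cells of the source patch, founder genotypes from
#' [sample_founder_genotype()], and no parents. An odd `n` is floored to the
#' next even number with a warning.
#'
#' @param n number of founders (even, > 0).
#' @param grid a [habitat_grid()].
#' @param genetics a [genetics_params()].
#' @param demography a [demography_params()].
#' @return A mutable simulation state (environment of class `felid_state`)
#'   holding the population vectors, genotypes, territory registry,
#'   census/event accumulators and pedigree.
#' @export
initialize_founders <- function(n, grid, genetics = genetics_params(),
                                demography = demography_params()) {
  stopifnot(inherits(grid, "habitat_grid"))
  if (n <= 0) stop("n must be positive")
  if (n %% 2 != 0) {
    warning("odd founder count ", n, " floored to ", n - 1)
    n <- n - 1
  }
  n <- as.integer(n)
  src_cells <- which(grid$classes == HABITAT[["BREEDING"]] &
                     grid$patch == PATCH[["SOURCE"]])
  if (length(src_cells) == 0) stop("no breeding habitat in the source patch")
  cells <- src_cells[sample.int(length(src_cells), n, replace = TRUE)]
  nr <- nrow(grid$classes)

  st <- new.env(parent = emptyenv())
  class(st) <- "felid_state"
  st$grid <- grid
  st$demography <- demography
  st$genetics <- genetics
  st$id <- seq_len(n)
  st$sex <- rep(c(SEX_F, SEX_M), each = n %/% 2L)
  ia <- demography$independence_age
  st$age <- sample(ia:(ia + 2L), n, replace = TRUE)
  st$status <- rep(ST_DISPERSER, n)
  st$row <- as.integer((cells - 1L) %% nr + 1L)
  st$col <- as.integer((cells - 1L) %/% nr + 1L)
  st$natal <- rep(PATCH[["SOURCE"]], n)
  st$mother <- rep(NA_integer_, n)
  st$father <- rep(NA_integer_, n)
  st$geno <- sample_founder_genotype(genetics, n)
  st$next_id <- n + 1L
  st$fem_occ <- matrix(0L, nrow(grid$classes), ncol(grid$classes))
  st$male_occ <- matrix(0L, nrow(grid$classes), ncol(grid$classes))
  st$terr <- list()        # female id (character) -> cell indices
  st$claims <- integer(0)  # named: female id -> claiming male id
  st$year <- 0L
  st$extinct <- FALSE
  st$census <- list()  # per year: c(year, residents by patch, dispersers by patch)
  st$events <- list()  # per year numeric record, see advance_year
  st$pedigree <- list(cbind(id = st$id, sex = st$sex,
                            mother = NA_integer_, father = NA_integer_,
                            birth_year = -st$age))
  st
}

#' @export
print.felid_state <- function(x, ...) {
  cat(sprintf("<felid_state> year %d: %d alive (%d residents, %d dispersers)%s\n",
              x$year, length(x$id), sum(x$status == ST_RESIDENT),
              sum(x$status == ST_DISPERSER),
              if (x$extinct) " [extinct]" else ""))
  invisible(x)
}

#' Population snapshot as a data frame
#'
#' @param x a `felid_state`.
#' @param ... unused.
#' @return Data frame with one row per living individual.
#' @export
as.data.frame.felid_state <- function(x, ...) {
  data.frame(id = x$id,
             sex = c("F", "M")[x$sex],
             age = x$age,
             status = c("kitten", "disperser", "resident")[x$status + 1L],
             row = x$row, col = x$col,
             natal_patch = names(PATCH)[x$natal],
             mother = x$mother, father = x$father)
}

state_index <- function(st, id) {
  i <- match(id, st$id)
  if (is.na(i)) stop("no living individual with id ", id)
  i
}

#' Attempt female territory settlement
#'
#' If an unoccupied contiguous region (4-connectivity) of breeding habitat
#' of at least `territory_min` cells is reachable from the female's current
#' cell, she claims `territory_target` cells by breadth-first region growing
#' (or the whole region if smaller than the target) and becomes resident;
#' otherwise she remains a disperser.
#'
#' @param st a `felid_state`.
#' @param id id of a female disperser.
#' @param target optional override of the claimed territory size (cells),
#'   capped at `territory_max`.
#' @return `TRUE` if the female settled, else `FALSE`.
#' @export
settle_female <- function(st, id, target = NULL) {
  i <- state_index(st, id)
  stopifnot(st$sex[i] == SEX_F, st$status[i] == ST_DISPERSER)
  d <- st$demography
  if (is.null(target)) target <- d$territory_target
  target <- min(target, d$territory_max)
  cells <- cpp_settle_female(st$grid$classes, st$fem_occ,
                             st$row[i], st$col[i], target, d$territory_min)
  if (length(cells) == 0) return(FALSE)
  st$fem_occ[cells] <- id
  st$terr[[as.character(id)]] <- cells
  st$status[i] <- ST_RESIDENT
  TRUE
}

#' Attempt male territory settlement
#'
#' From his current cell the male searches the surrounding breeding habitat
#' closest-first (breadth-first, up to `male_search_area` cells) and, if he
#' encounters at least one resident female territory without a resident
#' male, becomes resident, claiming up to `max_females_per_male` such
#' territories; his territory is their union. Each female territory is
#' overlapped by at most one male.
#'
#' @param st a `felid_state`.
#' @param id id of a male disperser.
#' @return `TRUE` if the male settled, else `FALSE`.
#' @export
settle_male <- function(st, id) {
  i <- state_index(st, id)
  stopifnot(st$sex[i] == SEX_M, st$status[i] == ST_DISPERSER)
  fem_ids <- as.integer(names(st$terr))
  if (length(fem_ids) == 0) return(FALSE)
  claimed <- vapply(as.character(fem_ids), function(f) {
    if (f %in% names(st$claims)) st$claims[[f]] else 0L
  }, integer(1))
  got <- cpp_settle_male(st$grid$classes, st$fem_occ, fem_ids, claimed,
                         st$row[i], st$col[i],
                         st$demography$max_females_per_male,
                         st$demography$male_search_area)
  if (length(got) == 0) return(FALSE)
  st$claims[as.character(got)] <- id
  for (f in as.character(got)) st$male_occ[st$terr[[f]]] <- id
  st$status[i] <- ST_RESIDENT
  TRUE
}

# Resident males with spare claim capacity absorb unclaimed female
# territories within their search area (their territories expand over
# females that settled nearby), before any new male can settle on them.
expand_male_claims <- function(st) {
  males <- which(st$sex == SEX_M & st$status == ST_RESIDENT)
  if (length(males) == 0) return(invisible(st))
  maxf <- st$demography$max_females_per_male
  for (i in males) {
    cur <- sum(st$claims == st$id[i])
    if (cur >= maxf) next
    fem_ids <- as.integer(names(st$terr))
    claimed <- vapply(as.character(fem_ids), function(f) {
      if (f %in% names(st$claims)) st$claims[[f]] else 0L
    }, integer(1))
    got <- cpp_settle_male(st$grid$classes, st$fem_occ, fem_ids, claimed,
                           st$row[i], st$col[i], maxf - cur,
                           st$demography$male_search_area)
    if (length(got) > 0) {
      st$claims[as.character(got)] <- st$id[i]
      for (f in as.character(got)) st$male_occ[st$terr[[f]]] <- st$id[i]
    }
  }
  invisible(st)
}

#' Territory cells of a resident
#'
#' For a female, her own territory; for a male, the union of the female
#' territories he overlaps.
#'
#' @param st a `felid_state`.
#' @param id individual id.
#' @return Integer vector of cell indices (column-major).
#' @export
territory_cells <- function(st, id) {
  i <- state_index(st, id)
  if (st$status[i] != ST_RESIDENT) return(integer(0))
  if (st$sex[i] == SEX_F) return(st$terr[[as.character(id)]])
  fems <- names(st$claims)[st$claims == id]
  unlist(st$terr[fems], use.names = FALSE)
}

#' Remove individuals from the population
#'
#' Drops the individuals at the given vector indices from the state (death
#' or culling), freeing the territories of dead resident females, releasing
#' male claims on them, and reverting resident males left without any
#' overlapped female to disperser status.
#'
#' @param st a `felid_state`.
#' @param idx integer indices into the population vectors (not ids).
#' @return The state, invisibly.
#' @export
remove_individuals <- function(st, idx) {
  if (length(idx) == 0) return(invisible(st))
  dead_ids <- st$id[idx]
  dead_f <- dead_ids[st$sex[idx] == SEX_F & st$status[idx] == ST_RESIDENT]
  dead_m <- dead_ids[st$sex[idx] == SEX_M & st$status[idx] == ST_RESIDENT]
  for (id in dead_f) {
    key <- as.character(id)
    cells <- st$terr[[key]]
    if (!is.null(cells)) {
      st$fem_occ[cells] <- 0L
      st$male_occ[cells] <- 0L
    }
    st$terr[[key]] <- NULL
    st$claims <- st$claims[names(st$claims) != key]
  }
  if (length(dead_m) > 0) {
    widowed <- names(st$claims)[st$claims %in% dead_m]
    for (f in widowed) st$male_occ[st$terr[[f]]] <- 0L
    st$claims <- st$claims[!(st$claims %in% dead_m)]
  }
  keep <- setdiff(seq_along(st$id), idx)
  for (f in c("id", "sex", "age", "status", "row", "col", "natal",
              "mother", "father"))
    st[[f]] <- st[[f]][keep]
  st$geno <- st$geno[keep, , drop = FALSE]
  # males left without any overlapped female revert to dispersers
  males <- which(st$sex == SEX_M & st$status == ST_RESIDENT)
  if (length(males) > 0) {
    still <- st$id[males] %in% st$claims
    st$status[males[!still]] <- ST_DISPERSER
  }
  invisible(st)
}

#' Apply yearly mortality to residents
#'
#' Each resident dies with probability `p_mortality_resident_yearly`; any
#' individual whose age exceeds `max_age` dies as well. Territories and
#' male claims of the dead are freed, and males left without an overlapped
#' female revert to disperser status. Daily disperser mortality is applied
#' inside the dispersal season (see [advance_year()]).
#'
#' @param st a `felid_state`.
#' @return Number of deaths, invisibly.
#' @export
apply_mortality <- function(st) {
  d <- st$demography
  n <- length(st$id)
  if (n == 0) return(invisible(0L))
  die <- (st$status == ST_RESIDENT &
          runif(n) < d$p_mortality_resident_yearly) |
         st$age > d$max_age
  remove_individuals(st, which(die))
  invisible(sum(die))
}

#' Reproduction of resident pairs
#'
#' Every resident female older than `female_breeding_age` whose territory is
#' overlapped by a resident male breeds with probability `p_breed` with that
#' male. Litter size is drawn from `litter_probs`, each kitten survives to
#' independence with probability `kitten_survival`, and each surviving
#' kitten receives its genotype by [inherit()] (Mendelian inheritance plus
#' stepwise mutation), a uniformly random sex, and a location drawn from the
#' mother's territory. Kittens are recorded in the pedigree and enter the
#' next felid year as age-1 dispersers.
#'
#' @param st a `felid_state`.
#' @return List with `n_events` (breeding events that occurred) and
#'   `n_born` (surviving independents created).
#' @export
reproduce <- function(st) {
  d <- st$demography
  fems <- which(st$sex == SEX_F & st$status == ST_RESIDENT &
                st$age > d$female_breeding_age)
  fems <- fems[as.character(st$id[fems]) %in% names(st$claims)]
  if (length(fems) == 0) return(list(n_events = 0L, n_born = 0L))
  breed <- runif(length(fems)) < d$p_breed
  fems <- fems[breed]
  n_events <- length(fems)
  if (n_events == 0) return(list(n_events = 0L, n_born = 0L))
  nr <- nrow(st$grid$classes)
  k_mother <- integer(0); k_father <- integer(0); k_cell <- integer(0)
  k_geno <- list()
  for (i in fems) {
    fid <- st$id[i]
    mid <- st$claims[[as.character(fid)]]
    j <- match(mid, st$id)
    if (is.na(j) || st$status[j] != ST_RESIDENT)
      stop("internal invariant failure: claiming male missing or not resident")
    litter <- sample.int(3L, 1L, prob = d$litter_probs)
    surv <- rbinom(1L, litter, d$kitten_survival)
    if (surv == 0) next
    terr <- st$terr[[as.character(fid)]]
    for (k in seq_len(surv)) {
      k_mother <- c(k_mother, fid)
      k_father <- c(k_father, mid)
      k_cell <- c(k_cell, terr[sample.int(length(terr), 1L)])
      k_geno[[length(k_geno) + 1L]] <-
        inherit(st$geno[i, ], st$geno[j, ], st$genetics)
    }
  }
  n_born <- length(k_mother)
  if (n_born > 0) {
    ids <- seq.int(st$next_id, length.out = n_born)
    st$next_id <- st$next_id + n_born
    sexes <- ifelse(runif(n_born) < 0.5, SEX_F, SEX_M)
    st$id <- c(st$id, ids)
    st$sex <- c(st$sex, sexes)
    st$age <- c(st$age, rep(0L, n_born))
    st$status <- c(st$status, rep(ST_KITTEN, n_born))
    st$row <- c(st$row, as.integer((k_cell - 1L) %% nr + 1L))
    st$col <- c(st$col, as.integer((k_cell - 1L) %/% nr + 1L))
    st$natal <- c(st$natal, st$grid$patch[k_cell])
    st$mother <- c(st$mother, k_mother)
    st$father <- c(st$father, k_father)
    st$geno <- rbind(st$geno, do.call(rbind, k_geno))
    st$pedigree[[length(st$pedigree) + 1L]] <-
      cbind(id = ids, sex = sexes, mother = k_mother, father = k_father,
            birth_year = st$year)
  }
  list(n_events = n_events, n_born = n_born)
}

# patch assignment for the census: residents by territory, everyone else by
# current location
individual_patch <- function(st) {
  p <- st$grid$patch[cbind(st$row, st$col)]
  res <- which(st$status == ST_RESIDENT)
  for (i in res) {
    cells <- territory_cells(st, st$id[i])
    if (length(cells) > 0) p[i] <- st$grid$patch[cells[1]]
  }
  p
}

record_census <- function(st) {
  p <- individual_patch(st)
  res <- st$status == ST_RESIDENT
  disp <- st$status == ST_DISPERSER
  st$census[[length(st$census) + 1L]] <-
    c(st$year,
      sum(res & p == 1L), sum(res & p == 2L), sum(res & p == 3L),
      sum(disp & p == 1L), sum(disp & p == 2L), sum(disp & p == 3L))
  if (length(st$id) == 0) st$extinct <- TRUE
  invisible(st)
}

#' Advance the simulation by one felid year
#'
#' Executes, in order: the annual census; the dispersal season, in which
#' every non-resident of at least independence age moves daily, is exposed
#' to daily mortality, and attempts settlement at its end-of-day location;
#' yearly resident mortality (plus maximum-age deaths); reproduction with
#' inheritance and mutation; and the age/status update that turns this
#' year's surviving kittens into age-1 dispersers. The census at the start
#' of a year with no living individuals marks the run extinct and the year
#' becomes a no-op.
#'
#' @param st a `felid_state`.
#' @param ms a [movement_syndrome()] or preset name.
#' @return The state, invisibly.
#' @export
advance_year <- function(st, ms = movement_syndrome("shy")) {
  ms <- ms_of(ms)
  d <- st$demography
  record_census(st)
  if (st$extinct) {
    st$year <- st$year + 1L
    return(invisible(st))
  }

  expand_male_claims(st)
  disp <- which(st$status == ST_DISPERSER & st$age >= d$independence_age)
  deaths_disp <- c(SOURCE = 0, CONNECTIVITY = 0, ARRIVAL = 0)
  migrants <- 0L
  n_settled <- 0L
  if (length(disp) > 0) {
    fem_ids <- as.integer(names(st$terr))
    claimed <- if (length(fem_ids) > 0) {
      vapply(as.character(fem_ids), function(f) {
        if (f %in% names(st$claims)) st$claims[[f]] else 0L
      }, integer(1))
    } else integer(0)
    dist <- build_step_distribution(ms$s_max, ms$exponent_x)
    season <- cpp_dispersal_season(
      st$grid$classes, st$grid$patch, st$fem_occ, st$male_occ,
      st$id[disp], st$sex[disp], st$row[disp], st$col[disp],
      fem_ids, claimed,
      if (length(fem_ids) > 0) unname(st$terr[as.character(fem_ids)])
      else list(),
      ms$p_matrix, ms$p_corr, ms$max_matrix_run,
      cumsum(dist$probs),
      d$p_mortality_disperser_daily, d$season_days,
      d$territory_target, d$territory_min, d$max_females_per_male,
      d$male_search_area)

    st$row[disp] <- season$row
    st$col[disp] <- season$col
    st$fem_occ <- season$fem_occ
    st$male_occ <- season$male_occ
    if (length(season$settled_female_id) > 0) {
      for (k in seq_along(season$settled_female_id)) {
        fid <- season$settled_female_id[k]
        st$terr[[as.character(fid)]] <- season$settled_female_cells[[k]]
      }
    }
    if (length(season$assigned_female) > 0)
      st$claims[as.character(season$assigned_female)] <- season$assigned_male
    if (length(season$settled_male_id) > 0) {
      for (k in seq_along(season$settled_male_id)) {
        got <- season$settled_male_females[[k]]
        st$claims[as.character(got)] <- season$settled_male_id[k]
      }
    }
    settled <- disp[season$status == 2L]
    st$status[settled] <- ST_RESIDENT
    n_settled <- length(settled)
    if (length(settled) > 0) {
      newp <- individual_patch(st)[settled]
      migrants <- sum(newp != st$natal[settled])
    }
    dead <- season$status == 1L
    if (any(dead)) {
      dp <- season$death_patch[dead]
      deaths_disp <- vapply(PATCH, function(k) sum(dp == k), numeric(1))
    }
    remove_individuals(st, disp[dead])
  }

  deaths_res <- apply_mortality(st)
  rep_out <- reproduce(st)

  st$age <- st$age + 1L
  st$status[st$status == ST_KITTEN] <- ST_DISPERSER
  remove_individuals(st, which(st$age > d$max_age))

  st$events[[length(st$events) + 1L]] <-
    c(st$year, rep_out$n_born, rep_out$n_events, deaths_res,
      deaths_disp[["SOURCE"]], deaths_disp[["CONNECTIVITY"]],
      deaths_disp[["ARRIVAL"]], n_settled, migrants)
  st$year <- st$year + 1L
  invisible(st)
}

#' Annual census table
#'
#' @param st a `felid_state`.
#' @return Data frame with columns `year`, `patch`, `n_residents`,
#'   `n_dispersers`, one row per patch per censused year.
#' @export
census_table <- function(st) {
  if (length(st$census) == 0)
    return(data.frame(year = integer(0), patch = character(0),
                      n_residents = numeric(0), n_dispersers = numeric(0)))
  m <- do.call(rbind, st$census)
  data.frame(year = rep(m[, 1], each = 3),
             patch = rep(names(PATCH), nrow(m)),
             n_residents = as.vector(t(m[, 2:4])),
             n_dispersers = as.vector(t(m[, 5:7])))
}

events_table <- function(st) {
  m <- do.call(rbind, st$events)
  if (is.null(m))
    m <- matrix(numeric(0), 0, 9)
  colnames(m) <- c("year", "births", "breeding_events", "deaths_residents",
                   "deaths_dispersers_source",
                   "deaths_dispersers_connectivity",
                   "deaths_dispersers_arrival", "settlers", "migrants")
  as.data.frame(m)
}

#' Pedigree table
#'
#' @param st a `felid_state`.
#' @return Data frame with columns `id`, `sex`, `mother`, `father`,
#'   `birth_year` covering every individual ever created (founders have `NA`
#'   parents and negative birth years reflecting their release age).
#' @export
pedigree_table <- function(st) {
  as.data.frame(do.call(rbind, st$pedigree))
}
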
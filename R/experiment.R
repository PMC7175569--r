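#' Simulation configuration
#'
#' Bundles everything one run needs: the landscape specification, the
#' movement syndrome, the founder population size, the number of simulated
#' felid years (default 200, roughly 40 generations), replication, and a
#' master seed from which all per-replicate, per-purpose RNG streams
#' (landscape, founders, simulation, metric subsampling) are derived
#' deterministically, so that any subset of a sweep reproduces identically.
#'
#' @param landscape a [landscape_spec()].
#' @param ms a [movement_syndrome()] or preset name.
#' @param n_founders founder population size (even).
#' @param years simulated years (>= 1).
#' @param n_replicates replicates per configuration in [run_sweep()].
#' @param master_seed integer master seed.
#' @param demography a [demography_params()].
#' @param genetics a [genetics_params()].
#' @param max_sampled_per_patch residents sampled per patch for the genetic
#'   metrics (default 30).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(landscape = landscape_spec(control = "CS3"),
                       ms = "shy", n_founders = 50L, years = 200L,
                       n_replicates = 1L, master_seed = 1L,
                       demography = demography_params(),
                       genetics = genetics_params(),
                       max_sampled_per_patch = 30L) {
  stopifnot(inherits(landscape, "landscape_spec"), years >= 1,
            n_founders > 0, n_replicates >= 1)
  structure(list(landscape = landscape, ms = ms_of(ms),
                 n_founders = as.integer(n_founders),
                 years = as.integer(years),
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 demography = demography, genetics = genetics,
                 max_sampled_per_patch = as.integer(max_sampled_per_patch)),
            class = "sim_config")
}

landscape_id <- function(spec) {
  if (!is.null(spec$control)) {
    match(spec$control, c("CS1", "CS2", "CS3")) * 1000L
  } else {
    as.integer(round(spec$dispersal_fraction * 100)) * 10L +
      spec$fragmentation
  }
}

replicate_seeds <- function(config, replicate) {
  base <- mix_seed(config$master_seed, landscape_id(config$landscape),
                   replicate)
  list(landscape = mix_seed(base, 1), founders = mix_seed(base, 2),
       simulation = mix_seed(base, 3), metrics = mix_seed(base, 4))
}

#' Run one demogenetic simulation
#'
#' Initialises founders in the source patch of the configured landscape,
#' advances the felid-year cycle for `years` years (or until extinction),
#' and computes the year-`years` demogenetic outputs on at most 30 sampled
#' residents per patch: observed heterozygosity, FST and FIS (NA without a
#' two-patch structure), per-patch growth-factor series, colonisation
#' success and extinction. Outputs of extinct runs are `NA`. Identical
#' `(config, replicate)` pairs give bit-identical results.
#'
#' @param config a [sim_config()].
#' @param replicate replicate index (used in seed derivation).
#' @return An object of class `felid_run`: list with `metrics` (one-row
#'   data frame), `lambda` (per-patch series), `census`, `events`,
#'   `pedigree`, `final_state`, `config`, `replicate`, `seeds`.
#' @export
run_simulation <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- replicate_seeds(config, replicate)
  spec <- config$landscape
  grid <- with_seed(seeds$landscape, {
    s2 <- spec
    s2$seed <- seeds$landscape
    assemble_three_patch(s2)
  })
  set.seed(seeds$founders)
  st <- initialize_founders(config$n_founders, grid,
                            genetics = config$genetics,
                            demography = config$demography)
  set.seed(seeds$simulation)
  for (y in seq_len(config$years)) {
    advance_year(st, config$ms)
    if (st$extinct) break
  }
  if (!st$extinct) record_census(st) # final-year state

  cen <- census_table(st)
  lam <- NULL
  metrics <- data.frame(ho = NA_real_, fst = NA_real_, fis = NA_real_,
                        colonised = NA, extinct = st$extinct,
                        n_sampled_source = NA_integer_,
                        n_sampled_arrival = NA_integer_,
                        n_residents_final = NA_integer_)
  if (!st$extinct && st$year >= config$years) {
    samp <- sample_residents(st, config$max_sampled_per_patch,
                             seed = seeds$metrics)
    colonised <- colonisation_success(st)
    metrics$colonised <- colonised
    metrics$n_sampled_source <- sum(samp$patch == PATCH[["SOURCE"]])
    metrics$n_sampled_arrival <- sum(samp$patch == PATCH[["ARRIVAL"]])
    metrics$n_residents_final <- sum(st$status == ST_RESIDENT)
    if (nrow(samp$genotypes) > 0)
      metrics$ho <- observed_heterozygosity(samp$genotypes)
    fs <- f_statistics(samp$genotypes, samp$patch)
    metrics$fst <- fs$fst
    metrics$fis <- fs$fis
    if (config$years >= 40) {
      lam <- do.call(rbind, lapply(c("SOURCE", "ARRIVAL"), function(pn) {
        nser <- cen$n_residents[cen$patch == pn] +
                cen$n_dispersers[cen$patch == pn]
        out <- lambda_series(nser)
        if (pn == "ARRIVAL" && !colonised) out$lambda <- NA_real_
        cbind(patch = pn, out)
      }))
    }
  }
  structure(list(metrics = metrics, lambda = lam, census = cen,
                 events = events_table(st),
                 pedigree = pedigree_table(st), final_state = st,
                 config = config, replicate = as.integer(replicate),
                 seeds = seeds),
            class = "felid_run")
}

#' @export
print.felid_run <- function(x, ...) {
  cat(sprintf("<felid_run> replicate %d, %d years%s\n", x$replicate,
              x$config$years, if (x$metrics$extinct) " [extinct]" else ""))
  print(x$metrics)
  invisible(x)
}

#' Run a sweep of simulation configurations
#'
#' Executes every configuration for its configured number of replicates and
#' returns one row per run. Rows carry the configuration parameters, so the
#' table is self-describing; results are independent of execution order
#' because every run's RNG streams derive from
#' `(master_seed, landscape, replicate)` alone. Failures of individual runs
#' are caught, flagged in the `failed` column and the sweep continues.
#'
#' @param configs list of [sim_config()] objects.
#' @param keep_runs keep the full `felid_run` objects as an attribute
#'   (`"runs"`) of the result (memory-heavy for large sweeps).
#' @return Data frame, one row per run.
#' @export
run_sweep <- function(configs, keep_runs = FALSE) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  rows <- list()
  runs <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (rep in seq_len(cfg$n_replicates)) {
      res <- tryCatch(run_simulation(cfg, rep), error = identity)
      failed <- inherits(res, "error")
      if (failed) warning("run failed: ", conditionMessage(res))
      spec <- cfg$landscape
      row <- data.frame(
        config = ci,
        control = if (is.null(spec$control)) NA_character_ else spec$control,
        dispersal_fraction = if (is.null(spec$control))
          spec$dispersal_fraction else NA_real_,
        fragmentation = if (is.null(spec$control))
          spec$fragmentation else NA_integer_,
        syndrome = cfg$ms$label,
        n_founders = cfg$n_founders,
        replicate = rep,
        failed = failed)
      if (failed) {
        row <- cbind(row, data.frame(ho = NA_real_, fst = NA_real_,
                                     fis = NA_real_, colonised = NA,
                                     extinct = NA,
                                     n_residents_final = NA_integer_))
      } else {
        row <- cbind(row, res$metrics[, c("ho", "fst", "fis", "colonised",
                                          "extinct", "n_residents_final")])
        if (keep_runs) runs[[length(runs) + 1L]] <- res
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_runs) attr(out, "runs") <- runs
  out
}

#' Aggregate sweep results per parameter set
#'
#' Means of the genetic metrics plus extinction and colonisation fractions,
#' grouped by landscape, syndrome and founder size.
#'
#' @param results a [run_sweep()] table.
#' @return Data frame with one row per parameter set.
#' @export
aggregate_sweep <- function(results) {
  key <- paste(results$control, results$dispersal_fraction,
               results$fragmentation, results$syndrome, results$n_founders)
  parts <- lapply(split(results, key), function(g) {
    data.frame(control = g$control[1],
               dispersal_fraction = g$dispersal_fraction[1],
               fragmentation = g$fragmentation[1],
               syndrome = g$syndrome[1],
               n_founders = g$n_founders[1],
               n_runs = nrow(g),
               mean_ho = mean(g$ho, na.rm = TRUE),
               mean_fst = mean(g$fst, na.rm = TRUE),
               mean_fis = mean(g$fis, na.rm = TRUE),
               extinction_fraction = mean(g$extinct, na.rm = TRUE),
               colonisation_fraction = mean(g$colonised, na.rm = TRUE))
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$syndrome, out$n_founders, out$control,
                   out$dispersal_fraction, out$fragmentation,
                   na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
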
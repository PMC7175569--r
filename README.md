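# felidgen

Spatially explicit, individual-based demogenetic simulation for solitary
felids, parameterised for Eurasian lynx (*Lynx lynx*).

Reintroduced felid populations are small and often isolated, so their fate
is decided not only by demography but by how fast genetic diversity erodes —
and movement behaviour ("shy stayers" vs "bold movers") shapes both.
felidgen couples a territory-based demographic model on a habitat raster
with neutral microsatellite genetics, so that reintroduction scenarios can
be compared by their long-run genetic outcomes. It is aimed at population
ecologists and conservation-genetics modellers studying founder-size,
landscape and movement-syndrome effects.

The model in brief:

* **Landscape** — a 65 × 169 grid of 1 km² cells: two 1300 km² breeding
  patches ("source", "arrival") separated by a 129 × 65 "connectivity"
  patch whose mixture of dispersal habitat and avoided matrix is generated
  by midpoint displacement with a controlled habitat fraction and
  fragmentation degree. Control scenarios fill the connectivity patch with
  pure matrix (CS1), pure dispersal habitat (CS2) or barrier (CS3 — a
  closed source patch).
* **Dispersal** — a daily habitat-dependent correlated walk. Step counts
  per day follow P(s) = φ(1 − (s−1)/(s_max−1))^x; habitat preference is
  applied before directional persistence P_c; matrix cells are entered
  with probability P_matrix and forays are capped at P_maxmat consecutive
  matrix cells. The shy/intermediate/bold syndromes are
  (P_matrix, P_c, P_maxmat) = (0.03, 0.5, 10), (0.06, 0.5, 20),
  (0.12, 0.5, 40).
* **Demography** — the felid year: census, dispersal with daily mortality
  (P_MD = 0.0015/day), settlement (female territories 46–146 km² of
  breeding habitat; males overlap 1–3 female territories), resident
  mortality (P_MR = 0.1/yr), reproduction (P_B = 0.75 for resident females
  older than 2; litter × kitten-survival calibrated to 1.5 independent
  subadults per breeding event).
* **Genetics** — 12 diploid microsatellite loci (24 alleles), founder
  alleles uniform on 120–220, Mendelian inheritance, stepwise mutation at
  10⁻⁴/locus/generation with a reflecting length-1 boundary.
* **Outputs** — observed heterozygosity Ho, Nei's FST = (Ht − Hs)/Ht and
  FIS = 1 − Ho/Hs on ≤30 sampled residents per patch, 20-year growth
  factors λ, colonisation success, extinction, census and pedigree tables,
  GENEPOP export.

## A worked example

A closed source patch (CS3) with 50 shy founders, simulated for 200 years
(~40 generations):

```r
library(felidgen)

cfg <- sim_config(landscape_spec(control = "CS3"), ms = "shy",
                  n_founders = 50, years = 200, master_seed = 42)
r <- run_simulation(cfg, replicate = 1)
r$metrics
#>          ho fst fis colonised extinct n_sampled_source n_sampled_arrival
#> 1 0.5545977  NA  NA     FALSE   FALSE               29                 0
#>   n_residents_final
#> 1                29

src <- subset(r$census, patch == "SOURCE")
mean(tail(src$n_residents, 50))
#> [1] 29.56
```

Reading: after 200 years of drift in a closed patch this replicate retains
Ho ≈ 0.55 of its initial ≈ 0.99 founder heterozygosity (replicate means sit
near 0.5); FST/FIS are `NA`
because a closed patch has no two-subpopulation structure; the 1300 km²
patch supports ≈ 30 residents (≈ 20 territorial females plus the males
overlapping them) — the emergent carrying capacity that the territory
rules are calibrated to. With bolder movement or fewer founders, diversity
at 200 years drops; with a traversable connectivity patch, explorers that
die in the matrix drain the gene pool unless the founder stock compensates.

Sweeps over landscapes × syndromes × founder sizes:

```r
cfgs <- lapply(c("shy", "bold"), function(ms)
  sim_config(landscape_spec(0.3, 2), ms = ms, n_founders = 50,
             n_replicates = 10, master_seed = 1))
res <- run_sweep(cfgs)
aggregate_sweep(res)
```

A thin command-line front end is installed with the package
(`exec/felidgen`): `felidgen landscape`, `felidgen run`, `felidgen sweep`.

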
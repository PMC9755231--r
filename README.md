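# tplext

Mean–variance scaling analysis of host-associated microbiomes via Taylor's
power law and its community-level extensions.

## The problem and who this is for

Taylor's power law relates the variance *V* of population abundance to its
mean *M* as

&nbsp;&nbsp;&nbsp;&nbsp;*V = a·M^b*,&nbsp;&nbsp;&nbsp;&nbsp;ln *V* = ln *a* + *b*·ln *M*

where the exponent *b* measures spatial aggregation: *b* < 1 indicates a
uniform (regular) abundance distribution, *b* = 1 random placement, and
*b* > 1 aggregation. Extended to whole communities, the law comes in two
forms relevant to microbiome surveys:

- **Type-I (community level)** — one (*M*, *V*) point per sampling unit
  (e.g. one host individual), with mean and variance taken across all OTUs
  in that unit. The fitted slope *b₁* measures community spatial
  heterogeneity.
- **Type-III (mixed-species population level)** — one point per OTU, with
  mean and variance taken across sampling units. The slope *b₃* measures
  the heterogeneity of each taxon's pooled ("mixed-species") population.

`tplext` is for microbial ecologists who have an OTU table and per-sample
host metadata and want to (i) fit both extensions overall, per host species,
and per dominant phylum; (ii) classify heterogeneity from the point estimate
or the confidence interval; (iii) test whether *b* is invariant to host body
size using geometric skin-area models (a cone-plus-cylinder 3D model and a
triangle-plus-rectangle 2D silhouette built from head length, head width and
body length); and (iv) run the supporting community statistics (Shannon
diversity, Kruskal–Wallis, Bray–Curtis, ANOSIM). A moment-controlled
synthetic community generator makes the whole pipeline testable without any
external data.

## Worked example

Simulate a four-species host survey whose per-OTU abundances follow
*V = M^1.8* within each species, then analyze it:

```r
library(tplext)

comm <- ple_community_spec(n_samples = 10, n_otus = 300, target_b = 1.8,
                           family = "power_law_gamma",
                           level_target = "type_III", seed = 1)
species <- lapply(1:4, function(s)
  ple_species_spec(sprintf("Frog_%d", s), n_individuals = 15,
                   trait_mean = c(a = 10 + 2 * s, b = 8 + s, h = 35 + 6 * s),
                   trait_sd = c(a = 1, b = 1, h = 3),
                   community = comm))
tabs <- simulate_study(ple_study_spec(species, n_sites = 5, seed = 42))
study <- join_tables(tabs$counts, tabs$metadata)
study
#> ple_study: 750 OTUs x 60 samples, 4 host species, 5 sites

fit <- fit_ple(type3_mean_variance(study))
fit
#> PLE fit (type_III) [all]: b = 1.6697 (95% CI 1.6323..1.7071), ln a = 1.6297
#>   n = 750 points (0 dropped), r^2 = 0.9113, p = 0
classify_heterogeneity(fit, basis = "ci_test")
#> heterogeneity: aggregated (basis: ci_test)

anosim(bray_curtis(study), study$metadata$host_species,
       n_permutations = 999, seed = 42)
#> ANOSIM: R = 1.0000, p = 0.001 (sampled, 999 permutations)

areas <- species_mean_area(skin_areas(study$metadata))
fits <- grouped_fits(study, level = "type_III", group_by = "host_species")
b_vs_area(fits, areas, area_kind = "A3")
#> b vs A3 (type_III, 4 species): slope = -1.62e-05, p = 0.383, r^2 = 0.381
```

Reading the output: the pooled Type-III slope (1.67, CI entirely above 1)
classifies the mixed-species populations as aggregated — note it sits below
the within-species generating exponent 1.8 because pooling hosts with
different composition adds between-host mean spread. ANOSIM separates the
four hosts perfectly (R = 1; p at its permutation floor), and the trend of
*b* against the 3D skin area is flat (slope ≈ 0, p = 0.38), i.e. *b* is
scale-invariant here, as it was generated to be.

`run_pipeline()` wires all stages together from a config list and writes
every table (fits, diversity, areas, trends) as TSV with a provenance log;
see `?run_pipeline`.

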
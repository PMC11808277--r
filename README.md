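# fpdassembly

Inference of community assembly processes — habitat filtering, limiting
similarity, neutrality — from presence/absence assemblages, by weighing
trait-based against phylogenetic interspecific distances.

## The problem and the method

For the species present at a site, the mean pairwise distance (MPD)
compared against randomized communities yields a standardized effect size

    SES = (MPD_obs − mean(MPD_null)) / sd(MPD_null)

with SES < 0 indicating clustering (co-occurring species more similar
than chance; the habitat-filtering signature) and SES > 0 over-dispersion
(limiting similarity). Whether "similar" is measured on traits or on the
phylogeny matters: measured traits may miss the assembly-relevant niche
axes, and phylogeny proxies them only when they are conserved. The
package therefore works on the weighted functional–phylogenetic distance

    FPDist(a) = (a · PDist'^p + (1 − a) · FDist'^p)^(1/p),  a ∈ [0, 1], p = 2

(primes: each matrix rescaled to [0, 1] by its maximum), where FDist is
the Gower distance over mixed-type traits re-embedded by PCoA and PDist
the patristic distance. The weight `a` is selected empirically: SES.MFPD
is regressed on environmental covariates plus a competition-intensity
covariate COMP (functional–phylogenetic evenness, FPDve, from the minimum
spanning tree of each site in ordination space), and `a*` is the grid
value maximizing the model's adjusted R². Driver importance is decomposed
with LMG relative importance, spatial autocorrelation is checked with
Moran's I on inverse great-circle distances, and per-site MFPD-versus-a
curves against null envelopes classify each site's assembly regime.

A synthetic-data module (birth–death trees, traits with tunable Pagel-λ
phylogenetic signal, communities assembled by known processes, covariates
coupled to process strength) makes the whole pipeline testable offline
with known ground truth.

## Worked example

```r
library(fpdassembly)

study <- generate_study(n_sites = 30, pool_size = 100, seed = 42,
                        process_mix = c(filtering = 1),
                        covariate_coupling = "filtering",
                        trait_lambda = 0, driver = "measured")

fd <- functional_distances(study$traits)   # Gower -> PCoA -> Euclidean
pd <- patristic_distances(study$phy)

scan <- scan_a(study$comm, fd, pd, study$env,
               null_spec("frequency", n_iterations = 199, seed = 7),
               a_grid = seq(0, 1, by = 0.05))
scan
#> a-scan over 21 weights
#>   a* = 0.2  max adjusted R2 = 0.4837
```

Assembly here was simulated as filtering on a measured, phylogenetically
signal-free trait, and the scan duly lands near `a* = 0`: the measured
traits, not the phylogeny, carry the niche axes, and the covariate model
explains a substantial share of the SES variation at that weight. Site
SES values at the selected weight and the per-site evenness (COMP) are in
`scan$ses` and `scan$comp`; the per-`a` fitted models in `scan$fits`.

```r
d <- fpdist(fd, pd, fpdist_spec(a = scan$a_star))
head(ses_mfpd(study$comm, d, null_spec(n_iterations = 999, seed = 11)), 3)
#>     site richness observed_mfpd null_mean     null_sd        ses rank_quantile p_value flag
#> 1 site01       53     0.5277273 0.5371160 0.009653034 -0.9726166        0.1545   0.309   ok
#> 2 site02       50     0.5306911 0.5381453 0.009387741 -0.7940382        0.2005   0.401   ok
#> 3 site03       25     0.5327679 0.5376267 0.009443580 -0.5145168        0.2925   0.585   ok
```

Negative SES marks functional–phylogenetic clustering; `flag` records sites where SES is undefined (richness < 2 or
degenerate null). Envelope curves and regime labels come from
`envelope()` + `classify_regime()`, and the file-based runners
(`run_ses`, `run_scan_a`, `run_fit`, `run_envelope`, `run_simulate`)
execute the same stages from CSV/Newick inputs to CSV/JSON outputs with a
reproducibility manifest.

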
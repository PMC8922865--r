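# kneecut

Cutoff point identification in ranked descriptive omics profiles.

## The problem

Descriptive high-throughput studies quantify thousands of continuous
variables — gene expression, protein abundance, chemical-sensitivity
scores — in a single sample, with no treatment groups or phenotypes to
compare against. The usual dichotomization machinery (fold change + FDR,
Otsu-style bimodal thresholds, UMI droplet filters) does not apply, yet a
practitioner still wants the small set of variables that dominates the
system: the genes that carry the tissue's physiology, the proteins that
define the organ.

The ranked value distribution of such data is almost always **biphasic**: a
long first phase of values growing slowly with rank, then a short second
phase growing rapidly. The bend between the phases is a natural, parameter
free cutoff. kneecut finds it geometrically:

1. Sort all `N` values ascending; plot value `V` against rank `R`
   (curve *A*).
2. Draw the chord *B* through the first and last ranked points,
   `y = m_B x + b_B` with `m_B = (V_max − V_min)/(N − 1)`.
3. For every rank, compute the perpendicular distance from the curve point
   to the chord,

   `D(R) = |V − m_B R − b_B| / sqrt(1 + m_B²)`.

4. The cutoff is the rank maximizing `D`. Records ranked **strictly above**
   the cutoff form the shortlist of dominant variables; the cutoff record
   itself is excluded. Exact ties for the maximum resolve to the largest
   rank (the most stringent shortlist).

The package also ships a truncation-robustness sweep (stepwise removal of
the lowest-value records, emulating low-abundance detection dropout, with
the cutoff recomputed from scratch at each step), a seeded generator of
biphasic profiles with a known knee, a low-tail control-list builder for
negative-control enrichment runs, a stringency offset for stricter or
looser shortlists relative to the reproducible reference cutoff, TSV/CSV
readers and writers, diagnostic plots, and a command-line interface.

## Worked example

```r
library(kneecut)

# a synthetic profile: 2000 records, true knee at rank 1900, noisy
tab  <- generateBiphasic(n = 2000, kneeRank = 1900, s1 = 0.01, s2 = 1,
                         noiseSd = 2, seed = 42)
prof <- rankProfile(tab)
prof
#> RankedProfile with 2000 records
#>   value range: [0, 119.337]
#>   zero-valued records: 79

cut <- findCutoff(prof)
cut
#> CutoffResult on 2000 records
#>   cutoff rank: 1888 (g1599, value 21.3752)
#>   max perpendicular distance: 91.1134
#>   shortlist size (ranks > cutoff): 112

head(extractShortlist(prof, cut), 3)
#>      id rank    value     distance
#> 1 g2000 2000 119.3370 5.568956e-15
#> 2 g1999 1999 118.6023 6.737876e-01
#> 3 g1997 1998 116.5089 2.703850e+00

truncationSweep(prof, increment = 200)
#> StabilityTable: 10 steps, increment 200
#>   full-data shortlist size: 112
#>   shortlist stable up to 30.0% of records removed
```

With additive noise of twice the low-phase scale the recovered cutoff
(rank 1888) sits 12 ranks — 0.6 % of the data — below the true knee, and
the 112-record shortlist is unchanged after removing up to 30 % of the
lowest-value records. `plotRankedProfile(prof, cut)` draws the ranked
curve, the chord, and a red vertical line at the cutoff.

From a shell the same run is:

```sh
Rscript inst/scripts/kneecut.R find --input values.tsv \
    --out-shortlist shortlist.tsv --out-summary summary.json
```

with subcommands `find`, `robustness` and `simulate`; errors exit non-zero
(2 input, 3 degenerate flat profile, 4 size) without partial outputs.

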
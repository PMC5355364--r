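# exomatch

Design and score dietary amino-acid ratios from an organism's genome.

Dietary protein quality is a 20-dimensional balancing problem: growth and
reproduction are capped by whichever essential amino acid (EAA) the food
supplies in shortest measure relative to the consumer's needs. **Exome
matching** estimates those needs directly from the genome: translate every
protein-coding gene in silico, compute each protein's proportional
amino-acid usage, and average across proteins. With the exome profile
`p` and a diet's molar profile `d`, the predicted output-limiting score
of the diet is

    r = min_i  d_i / p_i        (minimum over essential amino acids)

where the conditionally essential amino acids Y and C draw mole-for-mole
on their precursors F and M when undersupplied (the pair constraint
pools to `(d_P + d_D)/(p_P + p_D)`). The argmin is the limiting amino
acid; `r2/r1` predicts the proportional output change between two diets
at equal total amino-acid mass; and supplementing the limiting amino
acid raises predicted output linearly until the next constraint binds at
a computable breakpoint fold.

The package is for nutritional and life-history researchers who work
with chemically defined (holidic) diets and want to (1) derive a
requirement profile from any proteome FASTA, (2) identify and quantify
dietary amino-acid limitations, (3) design maximally mismatched control
ratios under an equidistance constraint, and (4) test whether a gene
set's amino-acid usage is unusually close to the exome average.

## Worked example

```r
library(exomatch)

# a reproducible stand-in proteome (use your organism's FASTA instead)
sp  <- make_synthetic_proteome(500, n_short = 25, n_long = 10, seed = 7,
                               path = "proteome.fasta")
exo <- exome_profile("proteome.fasta")
#> Exome-average amino-acid profile (mean_of_proportions)
#> Proteins: 465 retained of 500 (25 short, 10 long; bounds [100, 2000])

# a diet identical to the requirement except arginine cut in half
amt <- setNames(as.numeric(exo$profile), aa_codes())
amt["R"] <- amt["R"] * 0.5
diet <- recipe_to_profile(diet_recipe("lowR", amt, unit = "molar_proportion"))

limiting_report(diet, exo)
#> Limiting amino-acid report for diet 'lowR'
#> r = 0.5139, limiting: R
#> Runner-up: F (1.028)

breakpoint(diet, exo, aa = "R")
#> Supplementation breakpoint for R: x* = 2
#> Next limiting amino acid: F (r_next = 1.028, baseline r = 0.5139)

response_curve(diet, exo, aa = "R", fold_grid = c(1, 1.5, 2, 2.5, 3))
#>   fold relative_output
#> 1  1.0             1.0
#> 2  1.5             1.5
#> 3  2.0             2.0
#> 4  2.5             2.0
#> 5  3.0             2.0
```

Reading the numbers: halving arginine relative to requirement makes it
limiting with score `r = 0.514` — the renormalised diet supports 51% of
matched-diet output. Adding arginine back raises predicted output
proportionally (1.5x supply gives 1.5x output) until, at 2x addition, the
next constraint binds and the curve plateaus.

Control-diet design reflects a mismatched ratio through the requirement
profile, preserving its distance while maximising distance from the
original mismatch:

```r
des <- design_mismatch(exo$profile, diet)
c(des$dist_CA, des$dist_BA, des$dist_CB)
#> [1] 0.02704249 0.02704249 0.05408498   # equidistant, twice as far from B
```

Gene-set machinery: `rank_by_similarity()` ranks genes by distance of
their amino-acid usage to the exome average, and `set_mean_rank_test()`
tests one-sidedly whether a set's mean rank is smaller than chance, by
exact-moment normal approximation or seeded permutation.

`run_pipeline()` drives everything from one JSON config, and
`inst/cli/exomatch.R` exposes each step as a shell subcommand
(`profile`, `limiting`, `breakpoint`, `foldchange`, `design-mismatch`,
`rank`, `enrich`, `synth`, `run`).

Note on published diet tables: the package never fabricates a published
recipe. `packaged_recipes()` is an explicit registry that ships empty;
transcribe a published formulation into a TSV and load it with
`read_diet_tsv()` to analyse it.

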
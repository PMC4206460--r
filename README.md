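# phosphoswap

Kinase-dependent phosphopeptidome discovery from forward/reverse
(label-swap) stable-isotope quantitative phosphoproteomics.

## The problem

To chart the substrate repertoire of a single protein kinase, a
proteome-derived tryptic peptide library is dephosphorylated, incubated with
or without the recombinant kinase (the motivating enzyme is polo-like
kinase 2, an acidophilic Ser/Thr kinase), dimethyl-labeled (light CH₂O /
medium CD₂O), enriched for phosphopeptides and quantified by LC-MS/MS. The
label assignment is swapped between a *forward* and a *reverse* experiment,
each with three technical replicates. Kinase-generated phosphopeptides are
essentially absent from the control channel, so their treated/control ratio
*r* is very large (capped at 100 by the search software), while residual
background phosphorylation and unphosphorylated contaminants sit at *r* ≈ 1.

`phosphoswap` implements the downstream computation:

- PSM-table quantification: strict q < 0.05 filtering, per-replicate ratio
  orientation (forward: light/medium; reverse: reciprocal) and capping,
  replicate averaging, class 1 (both experiments) / class 2 (one experiment)
  classification;
- significance threshold anchored on the contaminant non-phosphopeptides
  (fixed ratio 2, or empirically 2^max contaminant log₂ ratio);
- mapping selected phosphopeptides to unique protein phosphosites, with
  missed-cleavage collapsing, accession grouping and union-find
  protein-group counting;
- two-sample logo statistics — per position p ∈ {−7…+7}\{0} and residue r,
  a two-sided Welch t-test on the indicator vectors **1**[window(p) = r] of
  foreground sites vs random S/T-centered proteome windows;
- consensus matching in compact notation (e.g. the strict CK2 consensus
  `s/t[DE]x[DE]`);
- cross-reference against a curated phosphosite annotation table (a
  40-record table of PLK2-generated sites catalogued in PhosphositePlus
  ships with the package), separating *annotated* from *orphan* sites;
- a first-class synthetic experiment generator whose additive log-odds
  kinase model is calibrated exactly to planted motif frequencies, with
  per-site ground truth for precision/recall evaluation.

## Worked example

Simulate a complete forward/reverse experiment and analyze it end to end:

```r
library(phosphoswap)

cfg <- simulation_config(seed = 42L)              # 200 proteins, 3 replicates
bundle <- run_simulation(cfg, out_dir = "demo")   # FASTA + PSM TSV + truth
res <- run_pipeline(pipeline_config(
  psm_paths = bundle$paths[["psms"]],
  fasta_path = bundle$paths[["fasta"]],
  truth_path = bundle$paths[["truth"]],
  seed = 43L, out_dir = "demo/out"))

res$threshold
#> Threshold report (fixed mode)
#>   ratio threshold: 2 (log2 1)
#>   max non-phosphopeptide log2 ratio: 0.7223 (n = 295)
#>   phosphopeptides above/below threshold: 225 / 543
```

The contaminant log₂ ratios never exceed 1, so ratio 2 cleanly separates
kinase-dependent phosphopeptides from background. Mapping the 225 selected
phosphopeptides collapses them to unique sites:

```r
c(res$summary$n_sites, res$summary$n_protein_groups)
#> [1] 86 72
```

The recovered specificity matches the planted acidophilic, N-terminally
determined motif (75% E at −3, 62.5% L at −2, 59% D at −1, up to binomial
sampling error at n = 86 sites), and the logo flags exactly those
determinants as the strongest over-representations:

```r
w <- motif_windows(res$sites)
round(100 * c(E3 = residue_frequency(w, -3, "E"),
              L2 = residue_frequency(w, -2, "L"),
              D1 = residue_frequency(w, -1, "D")), 1)
#>   E3   L2   D1
#> 72.1 55.8 64.0

head(res$summary$over_represented, 3)
#>   position residue fg_freq bg_freq        p
#> 1       -3       E   0.721  0.0692 1.14e-22
#> 2       -1       D   0.640  0.0451 7.69e-19
#> 3       -2       L   0.558  0.0970 4.24e-13

unlist(res$evaluation[c("precision", "recall")])
#> precision    recall
#>         1         1
```

Every selected site is a true kinase substrate and every substrate emitted
into the tables was recovered. `demo/out/` holds the site table, logo table,
threshold/xref reports and a JSON run summary stamped with the config hash.

A thin command-line front end with `simulate` and `run` subcommands is
installed at `inst/scripts/phosphoswap.R`.

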
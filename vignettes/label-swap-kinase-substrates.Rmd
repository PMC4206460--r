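---
title: "Identifying a kinase-dependent phosphopeptidome from label-swap quantitative phosphoproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying a kinase-dependent phosphopeptidome from label-swap quantitative phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoswap)
```

## The experimental design this package analyzes

A proteome-derived tryptic peptide library is exhaustively dephosphorylated
and then incubated with or without a single recombinant kinase (the
motivating application is polo-like kinase 2, PLK2, an acidophilic Ser/Thr
kinase implicated in alpha-synuclein S129 phosphorylation). Treated and
control samples are labeled with light (CH~2~O, +28.0313 Da) and medium
(CD~2~O, +32.0564 Da) dimethyl reagents and quantified by LC-MS/MS after
TiO~2~ phosphopeptide enrichment. The design is label-swapped: in the
*forward* experiment the kinase-treated sample takes the light label, in the
*reverse* experiment the medium label, which controls for labeling bias.
Each experiment has three technical replicates.

Peptides phosphorylated by the kinase are essentially absent from the
control, so their treated/control ratio is very large (the search software
caps it at 100). Residual phosphorylation left by incomplete
dephosphorylation appears equally in both channels (ratio near 1), as do the
unphosphorylated contaminant peptides that survive enrichment. The analysis
problem is to separate these populations, map the surviving phosphopeptides
to unique protein phosphosites, and characterize the kinase's sequence
specificity.

## Pipeline stages

1. **Quantification** (`quantify_peptides()`): PSM rows with q-value
   $\ge$ 0.05 are discarded (the comparison is strict, matching the
   confidence convention of the upstream search). Each raw light/medium
   ratio is oriented to treated/control — identity in the forward
   experiment, reciprocal in the reverse — and capped at 100 per replicate
   *before* averaging; the cap is a property of each reported quantification,
   so applying it per replicate mirrors what the search software emits.
   (Capping after averaging, and a geometric mean, are available as options.)
   Replicates are averaged per experiment, and peptides quantified in both
   experiments are *class 1*, in one experiment *class 2*.
2. **Threshold selection** (`calibrate_threshold()`, `select_dependent()`):
   contaminant non-phosphopeptides have true ratio 1, so their observed
   log~2~ ratio distribution measures pure quantification noise. The default
   is the conventional fixed threshold of ratio 2 (log~2~ ratio 1, which the
   contaminant distribution is observed not to exceed); `empirical` mode
   derives the threshold programmatically as $2^{\max(\text{contaminant
   log}_2)}$. Selection is strict (`>`). For class 1 peptides the default
   rule requires **both** experiment means above the threshold — the
   conservative reading; `any` is exposed for sensitivity analysis because
   the handling of peptides above the threshold in only one experiment is
   genuinely underdetermined.
3. **Site mapping** (`collapse_sites()`): selected peptides are exactly
   matched into the FASTA database; peptide-local phospho positions become
   protein coordinates (1-based, with the phosphosite at window offset 0).
   Peptides differing only in missed cleavages collapse onto the same
   (accession group, position) record; records sharing any
   accession:position locus are merged transitively. Peptides matching
   several proteins keep all loci as one ';'-joined accession group; when
   the $\pm$7 windows of the group members disagree the site is flagged
   ambiguous and excluded from motif statistics by default. Protein groups
   are counted after union-find merging of groups sharing any accession, so
   a protein appearing in several grouped rows counts once.
4. **Two-sample logo** (`compute_logo()`): for every position $-7..+7$
   (center excluded) and every residue, the foreground site windows are
   compared with random S/T-centered proteome windows
   (`extract_st_background()`, default 10,000 with replacement) by a
   two-sided Welch t-test on the 0/1 indicator vectors "residue $r$ at
   position $p$". Gap positions leave both numerator and denominator (the
   windows extend only *up to* 7 residues at protein termini). Pairs with
   $p < \alpha$ (default 0.05, no multiple-testing correction — the
   classical two-sample-logo behavior; Bonferroni available) are flagged
   over- or under-represented by the sign of $t$.
5. **Consensus matching** (`match_motif()`): patterns are written in the
   field's compact notation, e.g. the strict CK2 consensus `s/t[DE]x[DE]`;
   matching is strict, and a gap at a constrained offset fails.
6. **Annotation cross-reference** (`crossref()`): sites are looked up in a
   curated phosphosite table (the package ships a 40-record table of
   PLK2-generated phosphosites catalogued in PhosphositePlus, with upstream
   kinases where known). An annotated site with no known kinase is
   *orphan*. Residue letters must agree at a matching coordinate;
   isoform-coordinate reconciliation is out of scope and such sites count
   as unannotated, with a warning.

## The synthetic experiment generator

Because no public raw data accompany this design, the package includes a
first-class generator (`simulate_experiment()`) producing PSM tables with
the statistical structure the analysis assumes, plus per-site ground truth.

**Kinase preference model.** Substrate probability of an S/T site is an
additive log-odds (logistic) model over its $\pm$7 window:
$P(\text{substrate}) = \mathrm{logit}^{-1}(b + \sum_p w_{p,\,\text{window}[p]})$,
gaps contributing zero. The default model is calibrated
(`calibrate_kinase_model()`) so that, among substrates drawn from an
i.i.d.-residue proteome, glutamate at $-3$ occurs at 75%, leucine at $-2$ at
62.5% and aspartate at $-1$ at 59% — the acidophilic, N-terminally
determined specificity profile reported for PLK2. Calibration is exact: with
one determinant per position the three indicators are independent
Bernoullis, the selected-set marginals follow by enumerating the $2^3$
combinations, and the weights are solved numerically.

Two non-obvious numerical points. First, these strong marginals are only
attainable at low baselines: at higher $b$ the logistic saturates and the
marginal system has no solution (the calibrator then fails loudly rather
than returning an approximate model). Second, the system can have several
exact roots with very different overall substrate rates; the calibrator
multistarts and returns the root with the largest rate, which at the default
$b = -11$ yields a substrate rate of about $4 \times 10^{-3}$ per S/T site
— roughly 90 substrates in a default 200-protein run, matching the scale of
a real experiment of this kind (~100 sites).

**Study-condition defaults.** 200 proteins; lengths uniform on 300–1200
residues (a peptide library samples *residues*, and the average residue
lives in a protein substantially longer than the average protein — the
length-biased mean for human is near 1,000 aa); SwissProt-average residue
frequencies; 3 technical replicates; maximum 2 missed cleavages with each
missed-cleavage variant of a phosphopeptide additionally observed with
probability 0.3 (so the missed-cleavage collapsing path is exercised);
residual background phosphorylation at 1% of non-substrate S/T sites (the
assay's dephosphorylation is thorough but incomplete; no quantitative rate
is published, so this is a free parameter); 300 contaminant
non-phosphopeptides (the threshold is calibrated on them); per-replicate
dropout 0.2; 5% of q-values drawn above 0.05 to exercise the confidence
filter. True treated/control log~2~ ratios of substrates are
Normal(6.6, 1) truncated below at 2, so most observed capped ratios pile up
at the cap of 100 — matching the observation that kinase-generated
phosphopeptides are essentially absent from the control channel.
Multiplicative log-normal ratio noise has $\sigma = 0.3$ log~2~ units per
replicate: large enough that contaminant ratios scatter visibly, small
enough that their replicate-averaged log~2~ ratios stay within the
$\pm$1 envelope this assay exhibits, which is what makes ratio 2 a sensible
fixed threshold.

**What the generator does not emulate:** spectra, intensities, retention
time, site-localization errors, isoforms, shared peptides between unrelated
proteins, and any correlation structure of real protein sequences (residues
are i.i.d.). Passing tests therefore demonstrate the correctness of the
*computation* under the stated statistical assumptions, not robustness to
every artifact of real MS data.

## Numerical and degenerate-input choices

- The gap/pad character is `-`, which cannot collide with a residue letter.
- Initial methionine is never stripped; termini are not cleavage sites.
- `X` residues are tolerated in sequences; windows containing `X` are
  excluded from motif statistics (undefined composition).
- Welch tests with zero variance in both indicator samples carry no
  information and return $t = 0$, $p = 1$.
- `residue_frequency()` at a position where every window has a gap returns
  `NA` with a warning (undefined denominator).
- Background window sampling is uniform with replacement over all pooled
  S/T positions and bit-reproducible under a seed; deduplication of
  identical windows is off by default (whether the original tooling
  deduplicated its random background is unstated) and available as an
  option.
- Empty selections propagate cleanly: the pipeline reports zero sites and
  skips logo/consensus/cross-reference stages rather than failing.

## Test design notes

The suite checks digestion against a brute-force cleavage enumerator,
the Welch statistic against `t.test()` on expanded indicator vectors,
consensus matching against regular-expression oracles, and the planted
motif frequencies through the entire pipeline at the 95% binomial CI of the
planted values. The null flag rate of the logo (foreground and background
resampled from one pool, $n = 100$ each, 200+ resamples) is required to lie
within $0.05 \pm 0.02$: indicator t-tests on residues with frequencies near
0.05 at $n = 100$ are markedly discrete, so the nominal level is only
approached, not met exactly, and a pure Monte-Carlo error band would be
misleadingly tight. Problem sizes throughout the suite (up to 200 proteins,
10,000 background windows, 250 null resamples) were chosen as the smallest
that keep every statistical check well-powered.

## Known limitations

- The additive log-odds model cannot express interactions between window
  positions; real kinase specificity includes such couplings.
- Only the three published N-terminal determinants are planted by the
  default model, so C-terminal features of the real enzyme (e.g. the acidic
  +1/+3 preference that makes ~10% of real sites match the strict CK2
  consensus) are absent from synthetic data; the simulated CK2-consensus
  fraction is near the combinatorial background instead.
- Exact-substring site mapping has no tolerance for isoforms or sequence
  variants; unlocatable peptides are excluded and reported.
- Quantification consumes search-engine ratios as given; no channel
  normalization or protein-level roll-up is attempted.
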
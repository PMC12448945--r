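---
title: "Windowed diversity and divergence hotspot scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed diversity and divergence hotspot scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

divscan implements a window-based comparative scan of a multi-species cohort
of diploid genomes that all share one reference coordinate frame, of the kind
used to study slowly evolving clades (sea turtles being the motivating case)
where a handful of genomic regions diversify much faster than the rest of the
genome. This vignette is the package's account of the underlying model, the
parameters that matter, what the synthetic cohort does and does not emulate,
and the design decisions taken where more than one reading was defensible.

## The measurement model

### Callable sites

The atom of the analysis is the per-site diploid genotype record: chromosome,
1-based position, genotype in {hom-ref, het, hom-alt, missing}, and the QC
fields (depth, mapping quality, biallelic flag) produced by a standard
gVCF-style caller. `filter_sites()` converts failing genotypes to missing
rather than dropping records: retained iff MQ ≥ 30, 8 ≤ DP ≤ 2× the average
coverage, and biallelic. Three boundary decisions are deliberate:

* the MQ rule is stated in GATK-filter idiom ("MQ > 30" names the kept
  stratum), so the kept set is MQ ≥ 30 with the boundary inclusive;
* the depth removals are strict ("lower than 8", "greater than 2×"), so DP
  exactly 8 or exactly 2× the mean is retained;
* positions never observed in the input are treated as missing, not hom-ref.
  This is the conservative reading — a caller that does not emit a position
  gives no evidence the position was callable — and it makes per-window
  missingness accounting exact, at the price of a pessimistic missingness
  estimate for sparse inputs.

`apply_mask()` then blanks variant genotypes (het or hom-alt) inside
repeat-mask intervals; non-variant sites are untouched, since the mask
excludes unreliable variant calls, not the positions themselves. All internal
intervals are 0-based half-open; VCF and GFF3 coordinates are converted at
the boundary, exactly once.

### Heterozygosity windows

`window_heterozygosity()` tiles each chromosome with non-overlapping 50-kb
windows and reports per-window het-site counts. The per-bp rate uses the full
window length as denominator — no missing-data filter is applied at this
stage — so missingness enters the scan only where a rule explicitly consumes
it (the ROH caller's cap). A callable-site denominator would conflate
coverage with diversity; it remains available by recomputing rates from the
reported counts. The chromosomal mean is length-weighted (total het sites /
total chromosome length), which equals the per-window mean everywhere except
the truncated terminal window; an unweighted variant is available via
`chromosome_mean_het(weighted = FALSE)`.

Normalized heterozygosity is the ratio of a window's rate to its chromosomal
mean. The normalization is intentionally within-chromosome: it highlights
localized hotspots rather than between-chromosome or between-species
differences in overall diversity. Chromosomes with a zero mean are flagged
degenerate and normalize to zero rather than NaN.

### Runs of homozygosity and FROH

A window is low-heterozygosity when its rate falls strictly below one-fifth
of the genome-wide mean ("fell below" is strict), and eligible when its
missing fraction is at most 0.7 (inclusive cap). An ROH is a maximal run of
consecutive eligible windows with **both** ≥ 10 windows and ≥ 500 kb span;
enforcing the minima independently means truncated terminal windows can
never create a nominally-10-window call under 500 kb. Windows over the
missingness cap break runs. Bridging them instead (treating them as
transparent) is the permissive alternative; it is available as
`bridge_missing = TRUE` but is not the default, because "adjacent windows"
reads most naturally as unbroken adjacency and because bridging can join two
short homozygous tracts across an unobserved region.

FROH is the summed ROH length divided by the length of the analyzed
chromosome frame (not the full assembly — unplaced scaffolds are outside the
frame by construction). Segments are decomposed into half-open length
classes [0.5,1), [1,2), [2,5) and [5,∞) Mb; long ROH indicates recent
consanguinity, short ROH old background relatedness. The class fractions sum
to the total exactly, by construction rather than by rounding luck.

### Interspecific distance windows

Pairwise divergence arrives as a track: interspecific single-variant
positions plus aligned-coverage intervals, both projected onto the reference
species' frame (the shape of whole-genome-aligner SNP/coverage extraction
output; running an aligner is out of scope). `window_distance()` counts
variants in 10-kb windows and divides by the **aligned** bp in the window,
not the raw window length: a window half-covered by alignment with n
variants is as divergent as a fully covered window with 2n. Windows with
aligned coverage below `min_aligned_fraction` (default 0.5, a package choice
— no canonical value exists) are masked rather than reported with a noisy
denominator. Setting `min_aligned_fraction = 0` with
`raw_length_denominator = TRUE` reproduces the plain per-window-length
ratio for sensitivity analysis.

### Hotspot calling and consensus

A 50-kb window is flagged when normalized heterozygosity strictly exceeds 4
**and** at least one overlapping unmasked 10-kb window has normalized
distance strictly exceeding 2. The two metrics live on different grids, so a
joint rule needs a convention: divscan evaluates the conjunction on the
coarser heterozygosity grid with existential overlap on the distance side.
The existential (rather than, say, majority) rule is deliberate: divergence
elevation is typically narrower than diversity elevation, and requiring all
five subwindows to be elevated would penalize hotspots abutting alignment
gaps.

Flagged windows within 100 kb merge into regions (`merge_gap`), so a single
sub-threshold window does not split one biological region in two; the value
is a tunable reported in every output sidecar, not a discovered truth.
Consensus across species is window-level voting on the shared 50-kb grid: a
window enters the consensus when flagged in at least `min_species` species
(default: the whole cohort, since the interesting regions are the ones
elevated clade-wide), then consensus windows merge as above. Raising
`min_species` can only shrink total consensus bp (tested as an invariant).
Each non-reference species is flagged using its own track against the
reference; the reference species itself has no such track and uses the
cohort's first track — with shared hotspots every track is elevated in the
same windows, so this choice is immaterial there, and it is recorded here
because for real data one would instead pick the track of the closest
relative.

### Gene density and family enrichment

Gene records reduce to the longest isoform per gene (genes without mRNA
children keep their gene-line span). Density is genes per Mb, with a gene
assigned to the window containing its start. Multicopy families are
classified from functional-term strings by case-insensitive substring
matching in fixed precedence **MHC > OR > GPCR > ZNF > IMMUNE**; precedence
resolves overlapping vocabularies deterministically — every olfactory
receptor carries G-protein-coupled-receptor vocabulary, so OR must precede
GPCR, and MHC precedes the broader immune vocabulary. The shipped keyword
list (`default_family_keywords()`) is an explicit stand-in assembled from
the families' standard InterPro/Pfam-style phrasing and is user-replaceable;
classifications on real annotations should use a curated mapping.

Enrichment of each family inside a region set is a 2×2 Fisher exact test —
(in-region, out-of-region) × (family, all other genes) — one-sided in the
enrichment direction by default (`alternative = "two.sided"` is available;
enrichment is the stated question, and an upper-tail test is what "tested
the enrichment" means operationally). A gene is in-region on ≥ 1 bp overlap.
The default scope is genome-wide (family vs all other annotated genes);
`scope = "chromosome"` restricts each test to the chromosome carrying the
region, for the reading where the background is the local gene complement.
Benjamini–Hochberg correction is applied jointly across all tests returned
by one call — correcting per chromosome only would understate multiplicity
when several regions are screened at once. The reported odds ratio is the
sample OR (a·d)/(b·c), with Inf/0 on zero cells, not the conditional MLE.

### Macro/microchromosome contrast

Chromosomes are macro iff strictly longer than 50 Mb (an exactly-50-Mb
chromosome is micro). Per-chromosome values (mean het, gene density, mean
distance) are compared between classes with a two-sided exact Wilcoxon
rank-sum test; no distributional form is defensible for ~28 per-chromosome
values, and the exact test is valid at any n. Direction is the sign of the
micro-minus-macro median difference. All-tied input returns p = 1 and
direction 0.

## The synthetic cohort

`simulate_cohort()` generates the full input bundle — genome index,
per-species site tables, repeat mask, pairwise tracks, GFF3 genes — plus a
ground-truth ledger, all deterministically from (config, seed). Each
position is het with probability

baseline_het × microchromosome multiplier × hotspot multiplier × ROH factor,

missing independently with `missing_rate`, hom-alt with `hom_alt_rate`.
Pairwise variants are Bernoulli per aligned bp at `baseline_divergence` ×
(micro multiplier) × (hotspot distance multiplier); aligned intervals cover
`aligned_fraction` of every 10-kb unit at a random offset, with a 2% sprinkle
of low-coverage (30%) units so the alignment-masking path is exercised.
Genes are placed with per-bp weights proportional to class density, and the
clustered family's weight is multiplied 10-fold inside hotspots.

Only informative positions (het / hom-alt / missing) are materialized; the
site tables carry a sparse convention (`absent = "hom_ref"`) under which the
window stage reconstructs exact denominators from the missing rows alone.
This keeps a 30-Mb cohort in the tens of megabytes while preserving exact
missingness accounting; the dense gVCF semantics (`absent = "missing"`)
remain the default for real data.

### The scaled default design

`scaled_default_config()` is the cohort the analysis scripts, tests and
acceptance script all use: 7 species on a 28-chromosome frame — 11
macrochromosomes of 2 Mb and 17 microchromosomes of 0.5 Mb (30.5 Mb total,
macro threshold 1 Mb) — baseline het 1e-3/bp, microchromosome het multiplier
3, missing rate 0.05, divergence 2e-3/bp with micro multiplier 2 and 90%
aligned coverage, and a 10-kb repeat-mask interval per chromosome. Shared
hotspots occupy one 50-kb window at [200 kb, 250 kb) on chromosomes "13",
"14" and "24", with het multiplier 8 and distance multiplier 3.

The het multiplier deserves a note: the flag rule compares a window to its
*chromosomal* mean, and a hotspot covering fraction f of its chromosome with
multiplier m has expected normalized het m / (1 − f + m·f). On a 0.5-Mb
microchromosome a one-window hotspot has f = 0.1, so m = 6 lands exactly on
the threshold 4.0 (never strictly exceeded) while m = 8 gives 4.7, clearly
above threshold yet still self-normalizing-limited. Hotspots markedly larger
than ~10% of a microchromosome cannot exceed a 4× chromosomal mean at any
multiplier (the ratio is bounded by 1/f), which is a real property of
chromosome-normalized screens, not an artifact.

Planted inbreeding mirrors a strongly and a barely inbred individual: sp02
carries six tracts (0.6, 0.9, 1.2, 1.5, 1.8, 0.95 Mb on chromosomes 1–6,
FROH 0.228) spanning both reachable length classes, sp07 one minimum-length
0.5-Mb tract (FROH 0.016), within-tract het factor 1/50. At a 2-Mb maximum
chromosome length the [2,5) and [5,∞) Mb classes are structurally empty —
a scale limitation, not a caller property.

Gene annotation: 35 genes/Mb on macro- and 70 on microchromosomes (1365
genes), families OR = 300, GPCR = 90, ZNF = 80, IMMUNE = 60, MHC = 20, the
rest OTHER, with OR as the hotspot-clustered family. The family sizes were
fixed by a design-time power calculation on the placement model: with a
10-fold placement weight over 150 kb of hotspot on double-density
microchromosomes, an OR family of ~300 genes gives essentially unit power
for a BH-corrected one-sided Fisher q < 0.05 while keeping the false-positive
risk for the unclustered families near 1%. A 300-member OR repertoire is
also simply realistic for a reptile genome.

### What the generator does not emulate

No coalescent structure: sites are independent Bernoulli draws, so there is
no linkage disequilibrium, no recombination-rate variation, no mutation
spectrum, and no genealogical correlation between species beyond the shared
hotspot placement. Missingness is independent of genotype, whereas real
missingness is depth- and repeat-correlated. Alignment coverage is
homogeneous by construction outside the planted low-coverage units. Passing
recovery tests on this cohort therefore demonstrates that the windowing,
run-calling, masking, voting and testing machinery is correct and
well-calibrated — not that the pipeline is robust to LD, reference bias, or
alignment error in real genomes.

## Numerical and testing choices

* Exactness: window counts are integer arithmetic; normalization round-trips
  to 1e-12; FROH class fractions sum to the total identically.
* Degenerate inputs are handled by flagging, not by NaN: zero-mean
  chromosomes, all-masked chromosomes (excluded from distance means with a
  warning), empty region sets, zero-cell Fisher tables (p = 1, flagged).
* Tie-breaks: window assignment of a position is by half-open membership, so
  boundaries are never double-counted; a gene belongs to the density window
  containing its start.
* The unit and acceptance tests compare every counting path against
  brute-force oracles (per-bp interval membership, per-site window scans,
  exhaustive ROH run scans, hypergeometric tail enumeration, full rank-sum
  enumeration at n ≤ 10) on small randomized instances with fixed seeds.
* Problem sizes are chosen for desk-scale runs: the default cohort is 30.5 Mb
  × 7 species (about 20 s to simulate, 10 s to analyze), and the null
  calibration of the macro/micro contrast (100 seeds, multiplier 1) runs on
  a reduced single-species frame of 28 chromosomes (400 kb / 100 kb) with 1%
  missingness — the level of a rank test does not depend on chromosome
  scale, so calibration does not need full-size genomes.

## Known limitations

* One individual per species; no multi-sample VCF handling.
* No statistical significance for hotspot calls themselves (no permutation
  null is defined for the fold-threshold screen); the thresholds are
  screening rules, and the cross-species consensus is the replication
  argument.
* The keyword classifier is vocabulary-based; genes annotated with
  nonstandard phrasing will fall into OTHER.
* ROH calling is rule-based (window runs), not model-based (HMM); length
  classes near the 500-kb minimum are sensitive to the window grid by up to
  one window.
* All species must share one coordinate frame; lift-over between assemblies
  is out of scope.
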
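---
title: "Methods: the proteoscreen candidate-identification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the proteoscreen candidate-identification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoscreen)
```

## Purpose and model

`proteoscreen` identifies genes up-regulated *specifically* by a
treatment, in a design with three conditions — untreated control, the
treatment of interest, and a comparator treatment that reproduces part of
the treatment's phenotype — each measured in biological triplicate at the
transcript level, with partially overlapping label-free proteomic
coverage. The pipeline's philosophy is evidence integration with explicit,
auditable thresholds rather than a single omnibus model: a candidate must
(i) move convincingly at the transcript level, (ii) *not* move similarly
under the comparator, and (iii) be corroborated at the protein level,
either directly or through its interaction-network neighbourhood.

### Rank products and pfp

For a contrast with $n_a$ control and $n_b$ treated replicates we form
all $k = n_a n_b$ replicate pairings, compute the per-gene intensity
ratio within each pairing, and rank genes within each pairing (rank 1 =
most up-regulated; ties averaged). The rank product is the geometric mean
$\mathrm{RP}(g) = (\prod_{i=1}^{k} r_i(g))^{1/k}$. The statistic uses
only ranks, so it is invariant under any monotone rescaling of
intensities within a pairing, and is well suited to $n = 3$ designs where
variance estimation is fragile.

Significance is expressed as the *percentage of false positives* (pfp,
an FDR-type quantity): the permutation null is built by independently
shuffling each pairing's rank vector across genes `n_perm` times (default
1000), preserving each pairing's tie structure while destroying gene
identity. For a gene at ascending RP position $r$ with observed value
$\rho$, $E = \#\{\text{null RP} \le \rho\}/\texttt{n\_perm}$ estimates
the expected number of false positives in a list cut at $\rho$, and
$\mathrm{pfp} = E/r$. We enforce monotone non-decreasing pfp down the
sorted list (step-down cumulative maximum) so that significance sets are
nested, report values uncapped above 1, and break residual ordering ties
lexicographically by gene id so reruns are identical. The variant —
unpaired two-class, all pairings, tie-averaged ranks — is the standard
construction of the statistic; the permutation count is a free parameter
and 1000 gives pfp estimates that agree to within 0.02 across seeds on a
500-gene dataset.

When an expression table is probe-level, `collapse_probes()` retains, per
gene symbol, the probe with the largest fold change in the primary
contrast (the "maximum" reporting convention) and carries its RP and pfp.

### The specificity screen

`screen_step1()` assigns every gene exactly one status, checked in a
fixed order: `excluded_comparator` (comparator FC > 2.0),
`fails_transcript` (treatment FC ≤ 2.0 or pfp ≥ 0.05),
`no_protein_data`, `fails_protein` (ratio ≤ 2.0 or p ≥ 0.05), else
`specific_candidate`. All comparisons are strict: a comparator fold
change of exactly 2.0, or 1.97551, does not exclude, and a treatment fold
change of exactly 2.0 does not qualify. The comparator rule deliberately
tests fold change only — a gene convincingly up in both treatments is
non-specific regardless of significance in the comparator contrast, and
requiring comparator significance would make the exclusion *less*
conservative. Protein ratios are computed on the untransformed intensity
scale (they are plain fold changes); only the t-test operates on
arcsinh-transformed values, with pooled variance, the conventional choice
for triplicate label-free designs. Protein absence is represented as
absence (status `no_protein_data`), never as zero intensity: such genes
cannot be primary candidates but remain eligible for network rescue.

### Partner cross-validation

Step 2 queries a local STRING-dialect edge table (`protein1 protein2
combined_score`, space- or tab-separated; integer 0–1000 or fractional
0–1 scores auto-detected). We use the inclusive threshold
combined score ≥ 0.900 — the "highest confidence" band — for partner
retrieval, and re-screen partners with exactly the transcript
sub-criteria of Step 1 (shared code path, asserted by test). Protein
evidence is *not* required here; that asymmetry is the point, since it
rescues genes excluded from the primary screen only for lack of
proteomic coverage. Partners with no contrast data are reported
`unevaluable` rather than dropped. Live database queries are out of
scope by design: a local edge table keeps runs reproducible and
database-version independent.

### Ranked enrichment

Step 3 ranks the candidate's neighbourhood by network confidence
(target first, then partners by descending score, ties broken
lexicographically) and scans every prefix depth $n = 1..N$ of each
term's membership vector, computing the exact hypergeometric tail
$P(X \ge b)$; the reported $(n, b)$ is the depth minimizing the tail
(smallest $n$ on ties, with a $10^{-9}$ relative tolerance absorbing
floating-point noise between mathematically equal tails). The enrichment
ratio is $(b/n)/(B/N)$, evaluated at that optimal depth. Terms with
$B = 0$ carriers in the universe are skipped, and the Benjamini–Hochberg
correction runs over exactly the tested ($B \ge 1$) terms.

The minimum over $N$ dependent tails is optimistic as a p-value. By
default `enrich_all()` reports the raw minimum tail — the scale on which
such screens conventionally print per-term p-values — and offers an
exact correction (`mhg_correct = TRUE`): a dynamic program over the rank
lattice counts, in $O(NB)$ log-space operations, the arrangements of $B$
members among $N$ ranks whose prefix path avoids every cell at least as
extreme as observed, giving $P(\mathrm{mHG} \le s)$ exactly. The two
options bracket the truth; both are tested against enumeration over all
$\binom{N}{B}$ rankings at small $N$.

## The synthetic-data generator

`sim_config()` defines the benchmark conditions: a three-condition
(control, treatment, comparator) triplicate design over `n_genes = 500`
genes in which intensities are drawn as
$\exp(\mathcal{N}(\mu, \sigma))$ times the planted condition fold
change — log-normal because microarray and LC-MS intensities are
positive and right-skewed. Planted structure: `n_specific = 10` genes up
2.2-fold in the treatment only, `n_shared = 10` genes up 2.3-fold in
both treatment and comparator (the non-specific response the exclusion
rule must catch), the rest null.

Parameter choices, fixed once:

* `noise_sd = 0.05` (natural-log scale, ≈5% CV). This emulates the
  tight within-condition variability of a controlled cell-culture
  triplicate design — the regime in which ≈2-fold transcript changes
  attain pfp values near zero, as in the data this screen is modelled
  on. At 5% CV the sampling standard deviation of a log fold change of
  means is $\sigma\sqrt{2/3} \approx 0.041$, so a planted 2.2-fold
  specific gene clears the 2.0 threshold with high probability while a
  planted 2.3-fold shared gene essentially never slips under it in the
  comparator. At field-plausible noisier settings (log-sd 0.10–0.15)
  the strict 2.0-fold cut sits only ≈1 sd from the planted effects, and
  recovery/exclusion necessarily degrades — that is a property of
  fixed-threshold screens on small-$n$ designs generally, not of this
  implementation; the generator exposes `noise_sd` so users can map
  that degradation.
* `proteome_coverage = 0.6`, `peptide_count_range = c(1, 8)`: label-free
  proteomics observes a fraction of the expressed genome; partial
  coverage is what makes the network-rescue path meaningful (specific
  genes without protein rows must be recovered as partners, as happens
  in real screens).
* Protein noise is independent of transcript noise with the same
  multiplicative effect (conservative coupling — correlated noise would
  make concordance too easy).
* `simulate_network()` links each planted specific gene to the *other*
  specific genes first, then fills remaining partner slots from null
  genes. Planted candidates thus form a co-regulated high-confidence
  module, the way subunits of one complex (e.g. the three fibrinogen
  chains) appear in interaction databases; decoy edges score below 900.
* `simulate_annotations()` adds a planted term covering the specific
  genes, providing a known enrichment positive.

What the generator does **not** emulate: probe-level microarray
artefacts, missing-at-random protein intensities, intensity-dependent
variance, correlated gene modules beyond the planted candidates, or
annotation hierarchies (GO DAG propagation). Passing benchmarks
therefore demonstrate correctness of the screen's logic and its
operating characteristics under the stated generative model, not
end-to-end performance on any particular real platform.

## Problem sizes and numerical choices

The shipped tests run the statistics at the design scale: brute-force
rank-product oracles at 10 genes; pfp type-I control on 20 null datasets
of 500 genes × 1000 permutations; end-to-end recovery (≥90% of planted
specific genes, no shared-gene leakage) over 20 seeded pipeline runs at
the generator defaults; exhaustive minimum-hypergeometric scans for
$N \le 40$; and the mHG correction against complete enumeration at
$N = 8$. A full 500-gene pipeline run takes under two seconds on one
CPU, and a fixed seed reproduces every output file byte for byte.

Degenerate inputs are handled explicitly: a single-gene contrast yields
pfp = E at rank 1; constant protein groups give p = 1 (equal means) or
0; a term covering no universe gene is skipped rather than scored;
`B = 0` yields an undefined (NaN) enrichment ratio, not an error; and
zero-coverage proteomes produce empty, schema-correct tables.

## Known limitations

* pfp is an estimated FDR-type quantity, not a per-gene error
  probability; with few permutations it is granular at 1/`n_perm`.
* The screen's thresholds (2.0-fold, 0.05) are field conventions exposed
  as configuration, not optimized quantities; `screen_criteria()` makes
  them explicit so sensitivity analyses are one-liners.
* Down-regulation screening is implemented by symmetry
  (`direction = "down"`) but not exercised by the default pipeline,
  which targets up-regulation.
* Identifier mapping between protein and gene namespaces is a plain
  alias table (`map_aliases()`); no fuzzy matching is attempted, and
  unmapped identifiers are reported rather than dropped.
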
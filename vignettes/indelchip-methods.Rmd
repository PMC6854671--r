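---
title: "Genotyping large InDels with a SNP-style array: models and methods"
author: "indelchip developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping large InDels with a SNP-style array: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelchip)
```

## The problem

Insertions/deletions (InDels) and presence/absence variants (PAVs) — blocks
of sequence, often 100 bp to over 100 kbp, present at a locus in one
inbred line and absent in another — carry genes and regulatory elements,
yet genotyping them on large panels is poorly served by sequencing
(expensive, computationally heavy) and by classical CGH/SNP arrays (not
designed to target PAVs). `indelchip` implements, at desk scale, the full
method chain for genotyping such events with a two-channel SNP-style
fluorescence array:

1. **breakpoint model** — base-pair-resolved junctions, classified by
   microhomology and non-homologous insert;
2. **PAR detection** — k-mer screening for probe-suitable unique regions
   inside each event;
3. **probe design** — breakpoint (BP) probes plus internal probes at
   polymorphic (OTV) and monomorphic (MONO) sites, with scoring, hit
   filters and windowed selection;
4. **calling** — Gaussian cluster models on (contrast, intensity) signals,
   with an off-target (OTV) relabelling pass and an intensity-only caller
   for monomorphic probes (Hom2OTV);
5. **consensus** — multi-probe majority genotypes, the FreqDiff01
   consistency statistic and a binomial error simulation;
6. **diversity** — marker filtering, IBD-type kinship and PCoA on 1 − IBD.

A synthetic-data module generates genomes with planted events and array
signals with known truth, so every layer is testable without proprietary
instrument output.

## Breakpoint model

An event with sequence $S$ is flanked by sequences $L$ (left) and $R$
(right) shared between the carrier and non-carrier lines; the non-carrier
may hold a short non-homologous fragment $F$ in place of $S$. Four
junction types arise from the microhomology length $m$ and insert length
$i = |F|$: type I ($m = 0$, $i = 0$), II ($m > 0$, $i = 0$), III ($m = 0$,
$i > 0$), IV (both). Types II/IV with $m > 5$ bp are excluded from design,
because no 35 bp assay can discriminate the alleles within the shift
budget.

**Two-sided scan.** Microhomology — a sequence present once in the
reference and duplicated at both junction extremities in the carrier —
is computed as $m = \max(\mathrm{lcp}(S, R), \mathrm{lcs}(S, L))$, the
longest common prefix with the right flank or suffix with the left flank.
The literature describes duplication "at both extremities" without fixing
a scan direction; the symmetric maximum is the superset and is what the
brute-force oracle in the test suite checks. Ties between sides are
resolved by the maximum itself (both sides give the same $m$). The scan is
case-insensitive and terminates at `N`, since draft assemblies contain N
runs. If the homology run consumes an entire flank the true $m$ is
unbounded and an explicit error is raised.

**BP probes.** The probe is the 35 bp of the *absence* allele
($L\,F\,R$) centred on the interrogated base. The assay discriminates only
when the base at the interrogated position differs between alleles
($S[1+s] \neq (FR)[1+s]$ at shift $s$). Shift 0 is attempted first —
types I/III succeed there whenever the junction base differs — then the
junction is shifted one base at a time, at most 5 times, into the
microhomology; exhaustion yields an explicit design failure. Both strands
(FW and reverse complement) are returned. Probe length 35 bp is fixed by
the platform (it equals the minimum internal-probe region length).

## PAR detection

Internal probes only work where the event's sequence occurs nowhere in the
non-carrier genomes. Presence/absence regions (PARs) are maximal runs, at
least 35 bp long, of positions *not covered* by the 17-mers of the other
lines. Conventions, each of which the per-position brute-force oracle
pins down:

* **k-mers are canonical** (strand-collapsed to the lexicographic minimum
  of a k-mer and its reverse complement): probes hybridise both strands,
  and this guarantees mirror-symmetric PAR coordinates under reverse
  complementation.
* **Coverage is per-position via overlapping windows**: a position is
  uncovered only if *every* 17-mer window containing it is absent from the
  other-line indexes. The upstream utility this emulates does not document
  its convention; ours is declared and oracle-tested.
* **Dual evidence per line** (assembly index at min occurrence 1, ~5x read
  index at min occurrence 5) is OR-combined by default — presence in
  either marks coverage, which is conservative against false PARs — with
  `combine = "all"` available.
* K-mers containing `N` are never indexed; annotated repeats are removed
  from PARs by interval subtraction, and fragments under 35 bp are
  discarded.

## Probe scoring and selection

The published pipeline scores probes with a proprietary random-forest
conversion model ("p-convert"). The learned model is not the reusable
method — the thresholds and selection policy are — so `indelchip`
substitutes a transparent surrogate with the same range and semantics:

$$\mathrm{score} = \max\!\big(0,\; 1 - 0.35\,p_{GC} - 0.25\,p_{HP}
  - 0.15\,p_{DI} - 0.25\,p_{16}\big)$$

where $p_{GC} = |GC - 0.45|/0.55$ penalises base-composition extremes,
$p_{HP}$ grows linearly with the longest homopolymer beyond 2 bp
(saturating at 10, where the probe is `not_possible`), $p_{DI}$ is the
fraction of the probe covered by its longest perfect dinucleotide tandem,
and $p_{16}$ is the normalised excess of the 16-mer hit count over the
number of windows (a genome-unique probe scores zero penalty). Each term
is monotone in a defect that lowers conversion probability on a real
array. The classification rules are the published ones: *recommended* at
score ≥ 0.6 with no expected flanking polymorphism; *neutral* at ≥ 0.4
with fewer than 3 flanking polymorphisms, all ≥ 21 bp from the
interrogated base; otherwise *not recommended*.

The 16-mer hit count sums, over all 16 bp windows of the two ≤30 bp
flanks of the interrogated base, the window's occurrence count in the
reference — the expected degree of non-specific binding.

**Selection policy.** Internal candidates must be recommended/neutral,
have strictly more than 70% of their footprint inside a PAR, and pass the
reference hit caps (≤ 1 hit for deletion probes, 0 for insertion probes);
BP probes are all kept as long as they have < 3 hits, regardless of score.
MONO probes are then thinned for even coverage: each PAR is tiled with
75 bp windows (last partial window kept) and the best-scoring candidate
per window is selected; when an event ends up with fewer than 4 probes the
pass is redone at 50 bp, then 25 bp, and the final pass's selection stands
even if still short. A candidate belongs to every window its footprint
overlaps and per-window winners are unioned — this keeps trailing windows
shorter than a probe targetable, which a start-position assignment cannot
do. Events still untargeted get a rescue pass among their *not
recommended* candidates (hit and PAR filters retained — whether the
original rescue relaxed the overlap filter is unstated, so we keep it).
Exact-sequence duplicates collapse to the highest-scoring carrier, ties
broken by probe id; all orderings use declared tie-breaks so the design is
a pure function of its inputs.

## Cluster calling

Per probe, samples form clusters in (contrast, intensity) space, where
contrast $= \log_2(A/B)$ and intensity $= \tfrac12 \log_2(A \cdot B)$ for
channel signals $A$, $B$ (the transforms are declared and configurable;
the callers only ever see the two axes). The model is a mixture of up to
4 bivariate Gaussians (diagonal covariance), seeded by k-means
(deterministic given a seed) with the component count chosen by BIC;
fewer than 10 usable samples flags the probe `CallRateBelowThreshold`.
Samples are assigned their maximum-posterior component when the posterior
reaches 0.85, else `NoCall`.

Geometric labelling: components at the top intensity level are presence
clusters, labelled `AA`/`BB` by contrast sign (contrast-neutral → `AB`);
a component at least `hom2otv_gap_sd` pooled within-cluster SDs below the
top level is the off-target absence cluster `OO`; for BP probes,
components at intermediate intensity are hemizygous `OA`/`OB` by contrast
sign. The **OTV pass** additionally relabels an `AB`-looking cluster as
`OO` when it sits more than `het_so_cut` (−0.3) below the mean homozygous
intensity — the published miscalled-AB mechanism. **Hom2OTV** handles
monomorphic (MONO) probes: with exactly two homozygous-looking clusters
separated *primarily in intensity* (|Δintensity| > |Δcontrast|) and by at
least `hom2otv_gap_sd` (default 3) pooled SDs, the lower cluster is
recalled `OO` and the upper presence; a single cluster is monomorphic; a
contrast-separated pair is an unexpected SNP and is labelled like an OTV
probe. The original function is described as parameter-free, but any
re-implementation needs a separation criterion — the gap threshold and
dominance test are our documented deviation. Hom2OTV never emits
heterozygous calls; hemizygous calling for internal probes is deliberately
not implemented (the published algorithms do not genotype hemizygotes with
OTV/MONO probes).

The **inbred penalty** (0 = fully heterozygous prior to 16 = fully
homozygous) down-weights the heterozygous component's prior by
$2^{-\mathrm{penalty}/4}$ — a documented surrogate for the vendor's
unpublished mechanism — with 4 used in the BP/OTV relabel pass and 16 in
the MONO pass; increasing it can only reduce AB calls (a tested
monotonicity property). Probesets are classified into a reduced
8-category taxonomy (PolyHighResolution, MonoHighResolution, NoMinorHom,
OTV, CallRateBelowThreshold, UnexpectedHeterozygosity, Hom2OTV, Other)
by explicit, ordered rules; the vendor's `HetvMAF`/`AB.varY.Z` cut values
(1.9, 2.6) are retained as configuration with transparent surrogates.
Samples with a call rate below 0.9 fail QC and are excluded.

## Consensus and error model

Calls map to presence dosages (`AA`/`AB`/`BB` → 1, `OO` → 0, `OA`/`OB` →
0.5, `NoCall` → missing; the 0.5 weight for hemizygotes is our choice —
the published conversion lists three states without weights). Per event
and line, the presence frequency is the dosage mean over non-missing
probes; the consensus is the majority allele, with an exact tie (0.5)
treated as **missing, not an error**. This tie policy is what reconciles
the printed two-probe error of 0.2% with $P(\text{both wrong}) = 0.05^2 =
0.25\%$; counting ties as errors, or restricting the denominator to
non-missing calls, would give 9.7% or 0.276% respectively. Accordingly
the reported error rate is (erroneous consensus calls)/(all
observations). FreqDiff01 — the fraction of lines whose presence
frequency is neither 0 nor 1 — measures probe inconsistency and has the
closed form $1 - (1-e)^k - e^k$ under independent per-probe errors.

`simulate_probe_errors()` reproduces the published design exactly: per
(line, event) the number of wrong probes is a Binomial($k$, $e$) draw
over 362 × 10,000 observations, for $k$ from 2 to 50 and $e \in \{1, 3,
5, 10\}\%$. The suite checks the simulation against the exact binomial
tails (error $= P(X > k/2)$, missing $= P(X = k/2)$) within 3 Monte-Carlo
standard errors; at $e = 5\%$ this yields 0.25% for 2 probes, 0.725% for
3 and 0.116% for 5 — printing (to one decimal, in percent) as 0.2/0.3,
0.7 and 0.1. The two-probe value sits exactly on the rounding boundary,
so its one-decimal form is seed-dependent; this is a property of the
stated design, not of the implementation.

Genotyping-by-sequencing comparison aligns probes to assemblies with the
< 5% mismatch rule (≤ 1 mismatch on 35 bp, either strand, no indels);
probes spanning unassembled gaps come out absent, the documented
false-absent mechanism of draft genomes. Concordance excludes cells
missing in either matrix and is symmetric. The Mendelian check predicts
F1 genotypes from parental presence dosages (present × absent →
hemizygous) and excludes probes with missing or hemizygous parental
calls.

## Diversity

Markers (one best probe per event, ranked by call rate, concordance,
score, id) are filtered at < 20% missing, < 15% heterozygous, MAF > 5%,
and treated as bi-allelic present/absent. Kinship uses the Astle–Balding
genomic estimator
$$K_{ij} = \frac{1}{M}\sum_m \frac{(x_{im}-p_m)(x_{jm}-p_m)}{p_m(1-p_m)}$$
pairwise-complete over missing data, skipping fixed markers — a
documented substitute for the cited (archived) GenABEL `ibd` function,
whose exact formula is not published. Note that with frequencies
estimated from the panel itself the off-diagonal mean is biased by
$-1/(n-1)$; supplying true frequencies removes it. PCoA is classical
metric MDS on $1-K$ rescaled to $[0,1]$ (double-centred $-D^2/2$,
eigendecomposition via `cmdscale`); negative eigenvalues — expected, as
$1-\mathrm{IBD}$ is generally non-Euclidean — trigger a warning and only
positive axes are returned.

## The synthetic world

`generate_genomes()` plants events on a shared random backbone:
defaults are 100 bp–10 kbp events (the desk-scale analogue of the
published 37 bp–129.7 kbp spectrum), a breakpoint type mix dominated by
types II and III as observed in discovery data (5/53/42/0.2%),
microhomologies of 1–5 bp (the designable range), inserts of 1–50 bp,
37% deletions vs. the reference, and 300–600 bp shared spacers.
Junctions are engineered so classification recovers the planted type and
$m$ exactly; with `repeat_fraction = 0` every event interior is one full
PAR by construction. Signals use the cluster geometry of a real array:
presence at intensity 10 ± 0.3 and contrast ±1.5 ± 0.2, absence at
7 ± 0.4 and 0 ± 0.5, hemizygous midway — about 6–7 within-cluster SDs of
separation, i.e. a *clean* probe. What a green test establishes is
therefore parameter recovery under the stated geometry, independence of
probe errors, and correctness of the decision rules; it does **not**
establish robustness to overlapping clusters, intensity drift, correlated
probe failures, or biological inconsistencies (local rearrangements)
seen in real data — the published empirical call rates and concordances
require the real 445-sample dataset and are out of scope. All generators
are pure functions of (configuration, seed).

## Numerical choices and limitations

* SD floors of 0.02 keep degenerate single-point clusters finite; BIC
  uses $6k - 1$ parameters per $k$-component model.
* All selections and callers use stable sorts with declared tie-breaks;
  pipelines rerun bit-identically given (config, seed).
* Pipeline configuration is JSON (no YAML parser is available in the
  supported dependency set); every run writes a provenance record.
* Interval arithmetic is 0-based half-open internally; 1-based only in
  VCF/GFF output.
* Known limitations: no hemizygous calling for internal probes, no
  thermodynamic binding model behind the surrogate score, no CEL/vendor
  binary parsing (signals enter as TSV summaries), and the 8-category
  probeset taxonomy is a subset of the vendor's 14.
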
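---
title: "Phenotype-locus association networks: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-locus association networks: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoloci)
```

## The model

`phenoloci` links three node layers through edges that only cross adjacent
layers:

* **phenotypes** — HPO terms, connected to every patient annotated with the
  term or with any descendant of it;
* **patients** — the middle layer; the population whose co-membership
  patterns carry all the statistical information;
* **loci** — maximal genomic segments covered by a constant set of patient
  CNVs.

Deletions and duplications are modelled as separate subnetworks because the
same region can produce opposite phenotypes under loss and gain (classic
microdeletion/microduplication mirror traits such as macro- versus
microcephaly). Only de novo CNVs enter a network by default: inherited
variants are also present in an unaffected parent and are weaker evidence
for the pathological phenotype.

The fitted object scores each connected phenotype-locus pair with the
Hypergeometric Index

$$\mathrm{HyI} = -\log_{10} P(X \ge k), \qquad
  X \sim \mathrm{Hypergeom}(N, K, n),$$

the minus log probability that a phenotype carried by $K$ of the $N$
subnetwork patients would share at least the observed $k$ patients with a
locus carried by $n$, if locus carriers were an unbiased draw. The tail is
inclusive ("equal or greater overlap"), and the log base is 10 so that the
conventional significance rule reads $\mathrm{HyI} \ge 2 \iff p \le 0.01$.

### Assumptions worth stating

* Patients are exchangeable under the null: the score does not model
  relatedness, ascertainment differences between referring centres, or
  correlations between a patient's several phenotypes beyond what ontology
  propagation induces.
* Each CNV contributes independently to the loci it covers; a patient with
  two CNVs over one locus still contributes a single patient-locus edge
  (edges are patient-level, set semantics).
* The population universe $N$ is the subnetwork's patient layer — patients
  carrying at least one de novo CNV of the class — not all annotated
  patients. Phenotype degrees $K$ are computed inside that universe. An
  annotated patient with no CNV of the class carries no information about
  any locus of the class, so admitting them would only dilute every tail
  probability by a constant inflation of $N$.

## Ontology handling

Annotations are propagated to all is_a ancestors. The ontology root is
excluded from every propagated set: it would connect all patients to one
term and can only produce $K = N$, i.e. HyI $= 0$. Only `is_a` edges are
read; HPO's other relationship types express composition, not subsumption,
and must not transfer patient annotations. HPO is a DAG rather than a tree,
so ancestor closure uses set semantics — a term reachable along several
paths counts once. Obsolete terms are mapped through `replaced_by` when one
is given and otherwise dropped with a warning; a retired vocabulary entry
should not invalidate the rest of a patient's record.

Reports partition each locus's phenotype list with `most_specific()`: a
term is *parental* (`->`) if another reported term descends from it, else
*most specific* (`+`). Clinicians read the `+` rows as the concrete
findings and the `->` rows as their ontological context.

## Loci as maximal constant-coverage segments

The locus definition is operationalised as breakpoint segmentation: per
chromosome, every CNV start and end is a cut point; elementary intervals
between cuts carry the set of CNVs covering them; empty intervals are
dropped and adjacent intervals with identical sets are merged. Two
invariants pin the construction down and are enforced by tests against an
independent per-base oracle:

* the loci tile the covered genome exactly (union of loci = union of CNVs,
  base for base);
* each CNV is exactly tiled by the loci it supports.

Merging adjacent equal-set segments cannot change any patient-locus edge —
the merged segment has the same supporting set — so scores are invariant to
whether the raw elementary segments or the maximal merged ones are used; we
use maximal segments because they make loci a canonical partition.

Coordinates are 0-based half-open internally (exact interval arithmetic,
no ±1 bookkeeping); the readers accept 1-based inclusive input, the common
convention of clinical CNV tables, and convert on entry.

### Locus overlap for queries

`map_query()` reports `locus_overlap_pct` with the **locus length as
denominator**: 100% means the query CNV contains the whole locus. The
alternative (query-length denominator) would make a large CNV overlapping a
small locus score near 0% even though the locus is fully affected, which
contradicts how full-overlap rows are reported in practice; with the
locus-length denominator a marginal clip of a large locus is the case that
scores low, which is exactly the situation that warrants caution when
reading the associated phenotypes.

## Scoring choices

* **Connected pairs only.** Pairs with $k = 0$ cannot be significant and
  are omitted by default (`include_disconnected = TRUE` restores them).
* **No multiple-testing correction gates the report.** The significance
  flag is the raw HyI $\ge$ 2 rule; a Benjamini-Hochberg column
  (`p_adjust`) is emitted alongside for users who want it, but it never
  changes the flag.
* **Numerics.** The tail is evaluated with `stats::phyper(log.p = TRUE)`
  and divided by $\log 10$, so probabilities far below the double-precision
  underflow limit of direct summation still yield finite scores; reported
  HyI is capped at 300 (a configurable ceiling recorded on the output) to
  absorb the region where even log-space evaluation saturates. Tests check
  the tail against exact rational enumeration — integer binomial-coefficient
  sums over the common denominator $\binom{N}{n}$, all below $2^{53}$ for
  $N \le 30$ — at $10^{-12}$ relative error.
* **% max** is computed within one variant-class subnetwork, after all loci
  of a phenotype are scored; ties all receive 100.
* **Ordering.** Rankings sort by HyI descending with ties broken by term id
  ascending, so reruns are bit-identical. The recovery report instead uses
  competition ranking (1 + number of strictly greater scores at the locus):
  a planted leaf term can tie exactly with one of its own propagated
  ancestors (identical $N, K, n, k$), and both legitimately share rank 1.

## Query ranking and case comparison

Queries are scored against the fitted reference network; query patients are
**not** added to it, mirroring the clinical situation where a new case is
read against an existing cohort. Each overlapped locus reports its
significant phenotypes separately; the union over loci feeds the
diagnosed-versus-identified comparison:

* *matched* = observed ∩ identified (observed terms are propagated first,
  so a diagnosed child matches its identified parent term);
* *novel* = identified under the strict filter (HyI > 2, penetrance = 100,
  locus overlap = 100) minus observed — the candidates worth a follow-up
  examination;
* *missed* = observed minus identified.

Because one HPO term can recur across patients, cohort counters are emitted
in both countings — unique terms and patient-term pairs — explicitly
labelled. The cohort grid assigns each (phenotype, patient) cell one of
five tiers; *detected below threshold* means the pair was scored
($k \ge 1$) at an overlapped locus but fell short of HyI 2, a tier kept
separate because prevalent phenotypes often land there.

## The synthetic cohort generator

Real cohorts of this kind are access-controlled, so validation runs on
generated cohorts with known truth. `sim_config()` defaults describe the
study conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| patients | 200 | large enough for deep tails, small enough for second-scale fits |
| CNVs per patient | 1-3 uniform | multi-CNV patients exist but are the minority |
| chromosomes | 10, 8, 5 Mb | small synthetic genome keeps segmentation dense |
| filler CNV length | 50 kb - 1 Mb uniform | medium-size events that overlap often enough to form shared loci |
| planted loci | 2, on different chromosomes, 8 carriers, penetrance 1.0 | a clean specific association per subgenome |
| background phenotypes | 10 at prevalence 0.3 | high-prevalence terms that must *not* associate |
| sporadic terms | 2 per patient | private noise; exercises propagation breadth |
| toy ontology | random tree, depth 3, ≤ 4 children | planted phenotypes are leaves, so reports exercise the `+`/`->` marking |

Two generator choices matter for interpreting results. First, carrier CNVs
contain the planted interval with random flank extensions, while filler
CNVs are placed uniformly but rejection-sampled so they never overlap a
planted interval: the locus containing the planted interval is therefore
supported by exactly its carriers, making the truth table exact
($k = n =$ carriers at full penetrance). Second, all randomness flows from
one seeded stream, so a config is a complete, byte-reproducible description
of a cohort.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: realistic human CNV length and recurrence
distributions (hotspots, segmental-duplication-mediated recurrent events),
genome-scale coordinates, phenotype co-occurrence structure beyond the
ontology, diagnostic ascertainment bias, and noisy or incomplete clinical
annotation. Recovery of planted associations demonstrates correctness of
the machinery, not clinical performance.

## Problem sizes and runtime envelope

The test suite exercises: exhaustive hypergeometric verification for all
$\sim 87{,}000$ admissible $(N \le 30, K, n, k)$ tuples; 500 random small
cohorts (≤ 20 CNVs, coordinates ≤ 1000) against the per-base segmentation
oracle; five seeded 200-patient cohorts for planted recovery; and a
20-seed sign test that spreading a planted phenotype over 40% of
non-carriers lowers its HyI. These sizes were chosen so the full suite runs
in well under a minute per property while still covering the argument
space exhaustively where exhaustion is feasible.

## Known limitations

* Significance is per-pair; with tens of thousands of scored pairs, the
  HyI ≥ 2 rule will admit false positives at roughly the 1% rate the
  calibration implies (the measured background rate on synthetic cohorts is
  below that, since most background pairs are far from the decision
  boundary). The `p_adjust` column exists for stricter use.
* Loci inherit the cohort's breakpoint resolution: two cohorts genotyped on
  different platforms segment the same region differently, and scores are
  not comparable across differently built networks.
* Phenotype propagation treats all is_a paths equally; no term-specificity
  weighting (information content) is applied — a deliberate choice to keep
  the score a pure co-occurrence statistic.
* Translocations and complex rearrangements are out of scope; only
  deletion/duplication intervals are modelled.
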
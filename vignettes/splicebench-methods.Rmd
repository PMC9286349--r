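---
title: "Benchmarking cis-spliced peptide identification: models and methods"
author: "SpliceBench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cis-spliced peptide identification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceBench)
```

# The problem

Proteasome-catalysed peptide splicing (PCPS) ligates two non-contiguous
fragments of parental proteins into a peptide that is not encoded as a
contiguous stretch of any protein. Claims about the abundance of such
cis-spliced peptides in HLA class I immunopeptidomes vary over an order of
magnitude, and much of that variation traces back to the identification
pipeline: a target database of candidate spliced peptides is generated from
de novo sequencing output, and a database search engine then assigns MS2
spectra against it under target-decoy FDR control. Every stage — candidate
filtering, database construction, engine scoring, FDR estimation — can
inflate or deflate the final spliced-peptide yield.

SpliceBench provides the machinery to study this *in silico*: a splice
mapper that classifies any peptide against a proteome, a constructed
ground-truth database builder in which the true category of every peptide is
known, the two published candidate-selection workflows (here called AP and
MBS after their originating groups' strategies), a transparent stand-in
search engine with the standard reversed-decoy FDR estimator, and seeded
generators for every input, so the full benchmark runs on synthetic data
with known answers.

# The splice mapper

A peptide of length $n$ is split at every position into an ordered pair of
splice reactants, $[1{+}(n{-}1)], [2{+}(n{-}2)], \dots, [(n{-}1){+}1]$; for
a 9-mer these are the eight combinations $[1{+}8]$ through $[8{+}1]$. Each
reactant is matched exactly against every protein:

* a whole-peptide occurrence is a **non-spliced** explanation;
* two occurrences in the *same* protein are a **cis** explanation — in
  *normal* order when the left (N-terminal) reactant lies upstream in the
  protein, in *reverse* order otherwise — provided the intervening stretch
  between the occurrences is at most `maxIntervening` residues
  (default 25);
* occurrences in two *different* proteins are a **trans** explanation.

When several explanations exist, the hierarchy prefers non-spliced over any
spliced explanation and cis over trans; `classifyPeptide()` reports the
winning category with all of its explanations, in deterministic (split
point, entry, position) order.

Parameter choices that were genuinely open:

* **Reverse-order intervening length** is measured symmetrically to normal
  order — from the protein-upstream reactant's end to the downstream
  reactant's start — and the same cap applies to both orders.
* **Overlapping reactant occurrences** (negative intervening length) are
  excluded by default; two reactants cannot come from overlapping residues
  of one molecule. `allowOverlap = TRUE` lifts the restriction for
  exploratory use.
* **Same-protein pairs beyond the intervening cap** are, by default, not
  explanations at all. Whether a long-range same-protein pair should count
  as trans is genuinely ambiguous; the switch `longCisAsTrans` exposes both
  readings without guessing.
* **Minimum reactant length** defaults to 1, matching the $[1{+}8]$ split
  convention.
* Adjacent reactants (intervening length 0) are legal cis explanations;
  peptides explained that way are normally also whole-peptide matches, and
  the hierarchy resolves them as non-spliced.

Coordinates are 0-based and half-open throughout, which keeps the
intervening-length arithmetic free of off-by-one cases:
`intervening = right.start - left.end`.

All sequence comparison happens after isoleucine→leucine collapse
(`collapseIL()`), because MS cannot distinguish the isobaric pair; the
mapper refuses to classify an I-containing peptide against a collapsed
database rather than silently mis-matching.

# Constructed ground-truth databases

To measure precision and recall one needs spectra whose true peptide *and*
true category are known. The builder starts from a reference database and a
list of target peptides (in practice: confidently identified non-spliced
peptides), and rewrites the database so that each target is identifiable
only as its assigned category:

1. **Collapse** I/L in database and targets.
2. **Partition** the targets into non-spliced, cis and trapping categories
   by a seeded shuffle, in equal thirds by default.
3. **Elide** every target from the database: every substring equal to a
   target is replaced by a random residue string of the same length,
   redrawing until no target occurs anywhere. Lengths never change.
4. **Plant** each target: non-spliced targets are appended whole to the N-
   or C-terminus of a random protein; cis targets are split at a random
   site and planted as `reactant1 + intervening + reactant2` (intervening
   length uniform on 1..25, residues uniform) as one contiguous block at
   one terminus, which guarantees the cis explanation by construction;
   trapping targets have their two reactants appended to termini of two
   distinct proteins, leaving only a trans explanation.
5. **Verify after every plant** that no target — planted or pending — can
   now be assigned a category above its intended one; a violating plant is
   rolled back and re-sampled with a fresh host, terminus, split and
   intervening sequence (up to `maxRetries` attempts).

Because plants only append residues, explanations are only ever *added* as
construction proceeds: a target's observed category can move up the
hierarchy but never down. Verification after each plant therefore only
needs to look inside the one or two just-modified proteins, which keeps the
construction near-linear; a final `verifyCategories()` pass classifies
every target against the finished database as an independent check.

Two practical subtleties surfaced in randomized testing and are handled
explicitly:

* **Elision remnants.** When two targets overlap in the source database,
  eliding one destroys the other's full occurrence and leaves a long
  partial remnant in place. A remnant is a perfectly good long splice
  reactant, and the complementary short reactant will sit within the
  intervening window by chance alarmingly often (for a single-residue
  complement, with probability $1-(18/19)^{25}\approx 0.74$). A repair pass
  after elision therefore scrambles any occurrence pair that gives a target
  an above-intent explanation, before planting begins.
* **Near-duplicate targets.** A target nested inside another, or sharing a
  long terminal stretch with another (peptides from overlapping source
  loci), cannot be held in a lower category than its partner: whenever the
  partner is planted, the nested/overlapping target becomes explainable
  too. The synthetic peptide sampler consequently draws targets from
  disjoint source intervals and rejects nested draws; user-supplied target
  lists containing such pairs fail construction with a clear error after
  the retry budget.

The uniform random replacement and intervening residues use the 19-letter
post-collapse alphabet. Real proteomes are not composition-uniform; a
frequency-table hook would be the natural extension, but uniformity is the
cleanest null and introduces no external data dependency.

# Candidate selection: the AP and MBS workflows

Both workflows start from a table of up to five de novo candidates per MS2
spectrum, each with an ALC score (average local confidence, 0–100) and
per-residue LCS scores, and from a first-pass database search that
identifies spectra confidently explained as non-spliced peptides. Those
spectra are excluded from candidate selection (the exclusion rule is a
generic spectrum list, so externally produced first-pass results can be
substituted).

**AP**: candidates with ALC strictly above a data-derived cutoff are mapped
against the reference; if *any* candidate of a spectrum is non-spliced the
whole spectrum is discarded; otherwise the single highest-ALC cis candidate
is retained, else the single highest-ALC trans candidate, else nothing — at
most one candidate per spectrum. Retained candidates are concatenated into
in-silico proteins of `chunkSize = 25` candidates and appended to the
reference. The ALC cutoff is the 5% quantile (order statistic) of the ALC
values of rank-1 candidates that agree with the confident database
assignment of their spectrum — the published rule states only that the
cutoff derives from that agreeing distribution, so the quantile and its
level are this package's stated choice, recorded in every run manifest.
Concatenation creates junction artifacts (database substrings spanning two
candidates); chunking bounds their scope, and provenance records which
entry holds which candidate.

**MBS**: every candidate whose per-residue LCS values are all at least 80
and that maps as cis-spliced (intervening ≤ 25) is retained — several per
spectrum are possible — and each becomes its own database entry. Whether
the original strategy concatenated candidates is not documented;
one-entry-per-candidate is the simpler reading and avoids junction
artifacts entirely.

The asymmetry between the two filters is the scientific crux: a mean-based
ALC filter passes nearly every correct candidate, while a per-residue
minimum is punishing when local confidence is bursty. With the default
error model the AP database is several-fold larger than the MBS database
and contains most true cis peptides plus trans and erroneous material,
while the MBS database is small and nearly pure — which is exactly the
precision/recall trade the downstream search inherits.

# The stand-in search engine and FDR estimation

Commercial engines are out of scope, and the benchmark machinery only needs
a deterministic, monotone score. The stand-in engine digests the target
database (reference + spliced entries) and its whole-protein reversed decoy
(accessions prefixed `DECOY_`) into all substrings of 8–15 residues
(unspecific cleavage), indexes them by monoisotopic mass, and scores each
candidate whose mass lies within 5 ppm of the precursor:

$$\mathrm{score} = -\log_{10} P\!\left(X \ge m\right),\qquad
X \sim \mathrm{Hypergeom}(N, K, 2(n-1))$$

where $m$ of the $2(n-1)$ theoretical singly-charged b/y ions are matched
within 0.02 Da, $K$ is the spectrum's peak count and $N$ the number of m/z
bins of width twice the fragment tolerance spanning the spectrum's m/z
range. The best-scoring candidate per spectrum is retained, with ties
broken target-over-decoy, then by lexicographic peptide, then by first
accession. Candidates matching no fragment at all are not reported: a PSM
with zero shared peaks carries no evidence, and retaining such ties would
let the deterministic tie-break, not the data, decide between target and
decoy. Target PSMs are annotated with their splice category against the
reference portion of the database.

The FDR estimator is the published one: both databases are searched
simultaneously, and at each score threshold
$\mathrm{FDR} = 100\cdot 2D/(T+D)$ percent, where $T$ and $D$ count
assigned target and decoy sequences. Note what this quantity is: because
$T$ and $D$ together exhaust the accepted PSMs, $2D/(T+D)$ estimates the
false fraction among *all* accepted PSMs (each decoy assignment is false by
construction, and false assignments are assumed to split evenly between the
two databases). Against the target-side-only false rate $D/T$ it is
conservative by a factor approaching 2 when $T \gg D$. The calibration
test in the suite compares the estimator against the quantity it actually
estimates, on an entrapment design: half of the sampled peptides are elided
from the search database, so their spectra can only mis-match, and the true
false fraction is computable from the answer key.

The default threshold schedule spans scores 1–12. The score is a
$-\log_{10}$ tail probability, so the schedule runs from barely-significant
matches (two shared fragments in a noisy spectrum) to matches whose chance
probability is below $10^{-12}$, covering estimated FDRs from tens of
percent to zero — the analogue of the wide engine-specific scoring
schedules used for FDR-vs-PSM curves.

# The synthetic data generator

The generator emulates the statistical structure the benchmark rests on,
with every default chosen once as a realistic rendition of an HLA-I
immunopeptidomics experiment:

* **Proteome**: i.i.d. uniform residues over the 19-letter I-free alphabet;
  default 60 proteins of 80–200 residues for workflow benchmarks.
* **Peptides**: 8–15-mers (the HLA-I size window) sampled uniformly from
  disjoint proteome loci; default 120 targets, split in equal thirds.
* **Spectra**: each theoretical b/y ion is observed with probability 0.8
  (typical fragment coverage of a well-fragmented HLA-I peptide), with
  Gaussian m/z jitter of 0.005 Da (well inside the 0.02 Da match
  tolerance); a Poisson(30) count of uniform noise peaks; log-normal
  intensities with signal about a decade above noise; charge states mostly
  2+; precursor m/z jittered by ~1 ppm. One spectrum per peptide.
* **De novo candidates**: with probability 0.7 the true sequence is the
  rank-1 candidate, otherwise it is absent (a failed sequencing run);
  erroneous candidates are single substitutions, adjacent swaps, or
  isobaric replacements (N↔GG, Q↔AG/GA, … — generated from the residue
  mass table within a 0.02 Da window, never hard-coded). Per-residue LCS
  is drawn around mean 90 with sd 8 for correct residues and depressed by
  ~25 points at erroneous positions; ALC is the mean of the LCS values by
  construction. The sd of 8 matters: local confidence is bursty, so even
  correct candidates regularly dip below 80 at single residues, which is
  what makes the per-residue MBS gate much stricter than the mean-based AP
  gate — the documented size gap between the two target databases depends
  on this feature of real local-confidence traces.

What the generator deliberately does **not** emulate: homology and repeat
structure of real proteomes, realistic fragment intensity patterns,
retention time, chimeric spectra, and post-translational modifications.
Tests passing on this generator therefore validate the *bookkeeping and
statistics* of the benchmark — category separation, FDR calibration,
selection-rule fidelity, the direction of the AP/MBS trade-offs — not
engine behaviour on real biological sequence space.

# Known limitations

* **Trapping misassignment direction.** On real data, the AP strategy
  wrongly assigns more trapping (unidentifiable) spectra to cis-spliced
  than to non-spliced sequences. The driving mechanism is that de novo
  error variants of a trapping peptide are frequently cis-explainable
  against the full human proteome (~$10^7$ residues, with extensive
  homology), enter the AP target database as cis candidates, are
  mass-identical to the trapping precursor, and win the final search. For
  a uniform random proteome of desk scale ($10^4$–$10^5$ residues) the
  probability that a random variant has a cis explanation is of order
  $(n{-}1)\cdot 52\cdot N_{res}/19^{n}$ — about $10^{-4}$ — so this
  misassignment channel is effectively closed and both trapping
  misassignment counts are near zero in every seeded run. The
  corresponding directional check in the test suite is expected to fail
  and documents this scale limitation; reproducing it would require
  importing real-proteome sequence statistics, which is outside the
  generator's design.
* **Engine realism.** The hypergeometric shared-peak score has no
  intensity model and no machine-learned rescoring; imported PSM tables
  from real engines can be benchmarked through the same interfaces
  (`readPsmTable()`, `precisionRecall()`, `misassignmentTable()`).
* **Mass arithmetic** is monoisotopic, singly-charged b/y only — adequate
  for the simulator's own spectra, not for exotic fragmentation.

# Numerical and reproducibility choices

* Quantiles use the order-statistic definition (type 1), so the ALC cutoff
  is always an observed ALC value.
* The de novo table reader enforces `length(lcs) == nchar(sequence)` and
  `|ALC - mean(LCS)| <= 0.51` (one rounding unit at the 0.01 precision the
  tables carry).
* Every generator accepts `seed = NULL` to draw from the current RNG
  stream; pipelines set one top-level seed, making every stage — FASTA,
  MGF, candidate tables, PSM tables — byte-reproducible. Run manifests
  record package version, parameters, seed and input digests.
* Degenerate inputs are defined, not accidental: empty peak lists score 0,
  spectra with no mass-matching candidate produce no PSM, thresholds
  accepting nothing yield an FDR of 0 with an `empty` flag, and
  zero-assignment precision points are dropped from PR curves rather than
  coerced to 0 or 1.
* Validation problem sizes: oracle-equivalence runs use 1,000 random
  (proteome, peptide) pairs on proteomes of up to 20 proteins × 100
  residues; the construction contract is exercised on 300 targets over 500
  proteins across five seeds; FDR calibration uses 20 replicates of 100
  spectra; the workflow comparison uses ten seeded datasets of 120
  peptides. These sizes give stable Monte-Carlo estimates while keeping a
  full suite run in the minutes range.
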
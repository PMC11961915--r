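---
title: "Deriving Pol III promoters and quantifying the editing they enable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving Pol III promoters and quantifying the editing they enable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pol3kit` derives novel RNA polymerase III promoters from a training set of
monocot U6/U3 snRNA promoters and quantifies the CRISPR/LbCas12a editing
outcomes they enable. This vignette is the package's account of the methods:
the models and their assumptions, the parameters that matter, the synthetic
data the tests rely on, and the choices made where the design was genuinely
open.

## The promoter grammar and its coordinates

Monocot U6/U3 Pol III promoters carry three conserved upstream elements: a
TATA box near position −30, the upstream sequence element (USE, consensus
`TCCCACATCG`) whose end-to-TATA spacing is tightly constrained, and at least
one monocot-specific promoter element (MSP, consensus `RGCCCR`) 5′ of the
USE. All internal coordinates are 0-based half-open; every user-facing
position is TSS-relative with negative = upstream, so "TATA at −30" reads
the way the field writes it.

Element definitions are config-exposed (`element_def()`):

* TATA: `TATAWA`, 0 mismatches, expected −30 ± 10. The training literature
  does not pin a single TATA consensus; the canonical minimal hexamer is the
  default and can be replaced wholesale.
* USE: `TCCCACATCG`, up to 2 mismatches, expected −62 ± 40. The tolerance of
  2 is a documented default, not an inferred value.
* MSP: `RGCCCR`, exact, broad search interval. MSPs vary in number and
  position, so *all* matches are reported and validity requires at least one
  entirely 5′ of the USE.

Spacing validity is an interval check on two gaps: USE end → TATA start and
TATA start → TSS. Defaults (15–35 and 20–35 bp) merely bracket the canonical
layout; in normal use `learn_spacing()` replaces them with min–max observed
gaps from annotated training promoters widened by ±2 bp. The slack absorbs
the jitter seen in real promoter sets without letting the rule drift far
from the evidence.

## Motif discovery

`discover_motifs()` is a position-aware overrepresentation scan:

1. the training window is cut into `n_bins` (default 5) equal-width
   positional bins — position sensitivity is the point, since each grammar
   element lives in a characteristic window;
2. every word of `word_length` (default 6) is counted per bin in foreground
   and background; background sequences of the same length are binned
   identically, others are pooled into a positionally uniform rate;
3. enrichment is a one-sided binomial upper tail at the background
   per-position rate with pseudocount 0.5;
4. enriched words are merged greedily, most enriched first, absorbing words
   within Hamming distance 1 of the seed into an IUPAC consensus whose
   counts are then recomputed over its full expansion.

Everything is deterministic given inputs; p-value ties break
lexicographically by consensus. Whether the original binning was anchored
differently is unknowable from the available description; equal-width bins
are the implemented contract, shared verbatim with the scoring model so the
two stay coherent. When no background is supplied, seeded
dinucleotide-preserving shuffles of the training set stand in — the
enrichment term then measures structure beyond dinucleotide composition.
Only the given strand is scanned: Pol III elements are orientation-specific.

## The scoring model

`train_model()` builds two `4^6 × n_bins` tables:

* **frequency** — each sequence contributes a pseudocount-smoothed word
  distribution per bin, and sequences are averaged. Per-sequence averaging
  (rather than pooled counting) makes the model invariant to duplicated
  training sequences and keeps each bin an exact probability distribution.
* **enrichment** — the natural-log ratio of training to background smoothed
  frequency; pseudocounts (0.5 everywhere, symmetric) keep it finite.

`score_sequence()` returns the three terms and their weighted sum. The
frequency and enrichment terms are per-position *means*, not sums — an open
choice settled in favor of averaging so that the default weights (1, 1, 1)
are length-scale-free and a 290-bp trimmed promoter is comparable with its
500-bp parent. Entropy is computed over the global dinucleotide composition
(the simplest reading of a dinucleotide-entropy term); its ceiling is
log 16 ≈ 2.77 nats. Sequences shorter than the model window are scored in a
partial-window mode anchored at the 3′ end, because trimmed promoters end at
the TSS.

There is deliberately no train/test split: the model is a descriptive
position-specific profile, closer to Naive Bayes than to a cross-validated
classifier, and the package documents it as such.

## Sequence design by simulated annealing

`design_promoter()` draws a uniform random sequence (default 500 bp, the
design's 3′ end sitting at the TSS), seeds one MSP, USE and TATA instance at
positions drawn from training-consistent TSS-relative intervals
(MSP ∈ [−160, −90], USE ∈ [−63, −61], TATA ∈ [−31, −29]; degenerate letters
resolved uniformly), locks those positions, and runs a Metropolis loop of
single-base substitutions with geometric cooling.

Numerical/algorithmic choices:

* **Kernel.** Single-base substitution only; length is an invariant. The
  inner loop is incremental C++ (each move touches ≤ 6 table entries and two
  dinucleotide counts) and draws from R's RNG, so a run is bit-reproducible
  from its seed.
* **Schedule.** Geometric cooling reaching `t_final` (1e−3) exactly at
  `n_steps` (default 20 000). The default `t_initial = 2.0` follows the
  initial-acceptance heuristic: one substitution can swap up to six 6-mer
  terms at once, giving adverse deltas on the order of one score unit on
  short designs, which should still be accepted frequently early on. On
  rugged short-sequence landscapes this start temperature measurably reduces
  trapping in local optima relative to colder starts.
* **Seeding intervals** keep the USE→TATA gap inside the learned spacing
  rule, so locked elements guarantee an annotatable design skeleton and
  annealing optimizes the rest.

`trim_promoter()` cuts from the 5′ end only — the grammar is concentrated in
the TSS-proximal ~160 bp, so the distal arm is the dispensable one. Among
in-range lengths (default 280–300 bp) that keep all elements valid it picks
the best partial-window score, ties to the longest; if no in-range length
works it returns the shortest longer one with a warning flag rather than
silently dropping an element.

`screen_design()` implements generic, transparent composition screens
(homopolymers ≥ 6, T-runs ≥ 4 — a Pol III terminator lookalike —, GC outside
[0.25, 0.75], user-listed forbidden sites). Proprietary
allergenicity/toxicity screens are out of scope; this hook is where such a
screen would attach.

## Cassette and construct assembly

`build_cassette()` implements two grammars with exact length arithmetic:
simplex (promoter + 21-nt LbCas12a repeat + one 17–30-nt spacer + poly-T)
and flanked arrays in which every 23-bp spacer is flanked by repeats on both
sides (m spacers ⇒ m + 1 repeats). The stored repeat
(`GAATTTCTACTAAGTGTAGAT`) already carries the initial G required for proper
U6-driven expression. The poly-T terminator defaults to 7 T's — a common
Pol III terminator length, config-exposed since only "poly-T" is specified
by convention. `stack_construct()` concatenates cassettes in either
orientation, emits the `{n}PX{m}` shorthand, and flags repeated promoter
sequences (clonal-instability risk). Constructs are emitted as FASTA plus
GFF3 features via `rtracklayer`, a parser-round-trippable annotated-sequence
representation.

## Editing analysis

`call_reads()` aligns each mate glocally (global in the read, local in the
reference) with affine gaps (+2/−3, gap open −6, extend −1); both
orientations are tried and the better kept. A fragment carries an indel iff
either mate's alignment has an inserted or deleted base intersecting the
PAM + protospacer window — amplicons are kept under 200 bp precisely so 2×150
reads cover the target from at least one direction, and a fragment counts
once. Deletions are left-aligned (leftmost-indel convention) so ambiguous
placements are deterministic; insertion placement is taken as aligned, which
matters only at window edges. Ns are never indels; mates under the score
threshold are dropped and counted, never called.

Downstream statistics are deliberately thin, exact arithmetic:
`Indel% = 100 × indel reads / total reads`; the advanceable rule is strictly
"over 10%" (10.0 is not advanceable); luciferase QC is inclusively "at least
100-fold"; active-promoter calling thresholds at control mean − SD,
inclusive, at *every* supplied site. Report percentages round half-up to one
decimal (hit rate to the nearest integer) with full precision retained in
`*_full` columns — half-up matching how such tables are conventionally
printed, while base R's `round()` is half-even. Group comparisons delegate
to `kruskal.test`, exact `wilcox.test` and Spearman's `cor.test`.

## What the synthetic data emulates — and what it does not

`generate_training_set()` (defaults: 42 U6 + 24 U3, −500/+50 windows) plants
TATA at −30 ± 1, a USE with end-to-TATA gap 22 ± 1, and one MSP uniform in
[−160, −90] over a first-order Markov background (mildly AT-rich with CpG
and TpA depletion, a generic plant-intergenic caricature). Offsets respect
MSP < USE < TATA < TSS by construction and are validated at spec time.

`generate_edited_reads()` plants `round(rate × n)` edited fragments —
deterministic by default so generator-versus-caller comparisons are exact
bookkeeping, with a `binomial` flag restoring sampling — carrying 8–10-bp
deletions centered on the upstream Cas12a nick, optional short insertions,
and uniform substitution errors. `generate_population()` draws per-plant
indel rates from scaled Beta distributions whose exact advanceable fraction
is known in closed form.

What passing tests on these generators shows is *internal* correctness:
planted motifs are found where planted, planted edits are counted exactly,
learned spacing closes over generated and designed promoters. What they do
not show: real promoter sets have correlated element variants, non-Markov
background, and unannotated regulatory content; real reads have
quality-correlated errors, adapter artifacts, and alignment ambiguity beyond
left-shifting; and no in-silico score predicts wet-lab promoter activity —
the activity hit rate of designed promoters is a wet-lab quantity that this
package only reproduces arithmetically from reported counts.

## Problem sizes and numerical tolerances

The test suite uses a fixed-seed synthetic study: the 66-promoter default
training set; 20 annealing runs for design-validity properties; an
exhaustive-search oracle on a length-10 design problem (all 4^10 sequences
scored by independent vectorized arithmetic) against 20 annealing runs of
200 000 steps; and 2000-fragment read sets for caller closure. Scoring is
reproducible to machine precision; the brute-force comparison uses 1e−9;
profile peak location is measured as the midpoint of the maximal plateau,
since uniform-length deletions centered on one point produce a flat top that
makes a first-index argmax ill-defined.

## Known limitations

* The position-binned discovery scan and the annealer reproduce described *roles*
  (position-sensitive overrepresentation; score-guided mutation) — original
  internals such as bin anchoring, step counts and placement policy are
  unpublished, so all are config-exposed defaults rather than replicated
  constants.
* No EM/PWM motif models, no HMM or learned generative sequence models.
* Indel calling is presence/absence within a window; no SNV outcome
  classes, no off-target discovery, no base-level variant calling.
* Multi-objective design (e.g., jointly minimizing cross-promoter homology
  across a stacked construct) is out of scope; `stack_construct()` only
  flags exact repeated promoters.
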
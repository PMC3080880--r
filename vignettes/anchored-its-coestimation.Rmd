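---
title: "Anchored alignment and co-estimation for divergent fungal ITS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored alignment and co-estimation for divergent fungal ITS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorlign)
```

## The problem

The fungal barcode region ITS1–5.8S–ITS2 is a difficult substrate for
multiple alignment across divergent lineages. The two spacers evolve fast
and accumulate indels; the 5.8S rRNA gene between them is short (~160 nt)
and highly conserved. When whole-ITS sequences are aligned, the conserved
core can dominate the optimization and pull the hypervariable spacers out of
register, and the resulting misalignments propagate into the phylogeny:
spurious long branches, weakly supported backbones, and misplaced
environmental sequences.

anchorlign implements and compares four strategies on the same input:

1. **`baseline_whole`** — one pass of progressive alignment on the whole
   ITS, followed by tree building. This is the untuned control.
2. **`coest_whole`** — iterative co-estimation: align on a guide tree,
   re-estimate the tree from the alignment, rescore, repeat, keeping the
   best-scored (alignment, tree) pair over several independent runs.
3. **`coest_anchored`** — before co-estimation, the 5.8S region of every
   record is excised and replaced by one short constant **anchor** string,
   so the aligner keeps ITS1 and ITS2 separated and registered without any
   5.8S-driven distortion.
4. **`coest_58s_reincluded`** — the excised 5.8S sequences are aligned among
   themselves (they are conserved, so one progressive pass suffices) and
   spliced back into the best anchored alignment in place of the anchor;
   tree and support are then computed on the combined alignment.

Support-aware placement of unlabeled ("environmental") records into labeled
reference clades, alignment/tree quality metrics, and a synthetic ITS
simulator with known truth complete the pipeline.

## Alignment engine

All alignment — pairwise similarity and progressive profile merging — goes
through one affine-gap dynamic programme (Gotoh's three-state recursion).
Conventions, all deliberate and tested:

* **End-to-end**: end gaps are penalised, so the alignment is truly global.
* **Gap cost** `open + L * extend` for a run of length `L`; defaults
  `open = 10`, `extend = 0.5` with an identity substitution matrix
  (match 5, mismatch −4), the standard EMBOSS values for DNA.
* **Deterministic tie-breaking**: diagonal over up over left, both when
  filling the matrices and at traceback, so exactly one optimal alignment is
  produced for a given input order. Because equally optimal alignments can
  differ in their match count, `global_similarity()` additionally orders its
  two inputs canonically before the DP, which makes the similarity exactly
  symmetric.
* **Profiles** are per-column residue frequency vectors; a gap contributes
  nothing ("gap as absence"), and "once a gap, always a gap" holds through
  the merge order given by the guide tree. On two sequences the profile
  machinery reduces exactly to the pairwise DP.
* Ambiguity codes only score as matches against the identical literal
  character, and are treated as missing data everywhere that states are
  counted (distances, likelihood, column classification).

## Trees, score, and support

Guide trees and per-iteration trees come from **neighbor-joining** with a
documented deterministic tie rule: when pairs tie on the Q criterion, the
pair whose cluster labels (each cluster is labelled by its smallest leaf id)
sort lexicographically lowest is joined. Negative branch lengths are clamped
to zero. Distances are Jukes–Cantor: `d = -3/4 log(1 - 4p/3)` with pairwise
deletion and a saturation cap (`d_max = 5` substitutions/site) for
`p >= 0.75` — the standard guard against undefined log arguments on
saturated ITS pairs.

The co-estimation **selection score** is the Jukes–Cantor log-likelihood of
the alignment on the current NJ tree (Felsenstein pruning; columns
independent; gaps and ambiguity codes as missing data, so an all-gap column
contributes exactly 0). This is a desk-scale analog of the ML scores used by
full co-estimation software: the same monotone intent, but with closed-form
transition probabilities that can be verified against a brute-force
state-summation oracle. Independent runs differ only by seeded ±5%
multiplicative noise on the initial k-mer distance matrix; the first run is
left unperturbed so that `runs = 1, iterations = 1` is exactly the
deterministic single-pass baseline. Iterating realigns from scratch on the
new tree each time (no decomposition/merging of the previous alignment);
since the alignment depends on the guide only through its topology,
repeated topologies within a run are cached.

**Branch support** is the bootstrap frequency of each bipartition of the
point-estimate tree across column-resampled replicates (default 100). It
fills the support slot that a Bayesian analysis would fill with posterior
probabilities; the significance convention (support strictly above 0.94)
and every decision rule downstream are estimator-agnostic, so a different
support estimator could be substituted without touching the rest.
Majority-rule consensus trees contain exactly the bipartitions with
frequency strictly above the threshold (default 0.5).

## The anchor

The anchor must satisfy one hard requirement — constancy across taxa — and
one soft one discovered the hard way: **aperiodicity**. A periodic motif
(e.g. repeated `ACGT`) matches itself well under small shifts, so the
aligner can slide the anchor block a few columns in some rows at no great
cost; the default 16-mer (`CTAGTCGATCTCAGGC`) matches itself in at most 3
positions under any nonzero shift. Anchor integrity is *checked*, never
assumed — with one deliberate tolerance. Because the anchor's boundary
characters can coincide with flank characters, equally optimal alignments
exist that slide a single anchor residue across an adjacent gap run; such
gap slides change no aligned residue pair, so they are canonicalized (every
row's anchor moved onto the modal block) before verification.
`reinsert_58s()` refuses to splice into an alignment whose anchor is broken
beyond that — anchor residues interleaved with flank residues — and the
anchored co-estimation accepts only iterates whose anchor survived (an
alignment that genuinely broke the anchor has failed the anchor's purpose
of keeping ITS1 and ITS2 registered). All iterations still appear in the
trace.

Re-insertion aligns the excised 5.8S substrings with the same progressive
aligner, guided by the anchored strategy's tree, and replaces the anchor
columns in place, so each combined row degaps back to the original
full-length residues — an invariant asserted on every simulated dataset.

## Query placement

Environmental queries are placed by walking from the query leaf toward the
root of the midpoint-rooted support tree (midpoint, because simulated data
have no outgroup; outgroup rooting can be used instead). The first enclosing
clade with support strictly above the threshold that contains at least one
labeled reference assigns its label if all its references agree; mixed-label
clades are passed over rather than voted on — matching the conservative
practice of reporting an isolate as "grouped with" a single genus — and a
query with no such clade stays unassigned with a reason. Raising the
threshold can therefore never turn an unassigned query into an assigned one.

## The simulator

`simulate_its()` generates data with known truth: a Yule tree (`n_taxa`
leaves, height rescaled to `depth_scale` expected substitutions/site at the
5.8S rate), Jukes–Cantor substitutions with per-region rate multipliers,
and per-region indels (Poisson event counts per branch, geometric lengths,
insertion/deletion equiprobable), with the true alignment tracked through
every insertion. Reference groups are clades cut from the true tree;
`n_queries` leaves are masked as environmental such that every group keeps
at least two references. Optional artifact injection mimics public-database
defects: reverse-complemented submissions, ITS2-truncated records, and
too-short fragments, each flagged in a truth table (plus a chimera flag for
ITS2 swaps; no chimera detector is provided).

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `region_lengths` | 220 / 160 / 240 nt | typical ITS1 / 5.8S / ITS2 sizes |
| `rate_multipliers` | 8 / 1 / 8 | conserved core vs hypervariable spacers |
| `indel_rate` | 0.5 / 0 / 0.5 per site per unit branch | indel-rich spacers, length-conserved 5.8S |
| `indel_length_mean` | 3 nt | short indels dominate spacer evolution |
| `depth_scale` | 0.04 | calibrated against the pairwise-similarity oracle so simulated whole-ITS similarities sit in the regime reported for divergent ascomycete ITS data: generally below 70% between groups, with the most divergent pairs around 55–62% (deeper scales push the bulk of pairs far below that envelope; shallower ones push the median above 70%) |
| `n_taxa`, `n_queries`, `n_groups` | 32, 8, 4 | a desk-scale reference-plus-environmental sampling |

What the simulator does **not** emulate: among-site rate heterogeneity
within a region, base-composition bias, sequencing error, and realistic
chimera breakpoints. Tests passing on these data therefore demonstrate the
pipeline's internal correctness and its relative ranking of strategies under
a conserved-core/variable-flank regime, not performance on any particular
real dataset.

## Problem sizes used by the test suite

The directional comparison (does 5.8S re-inclusion match or beat whole-ITS
co-estimation on accuracy and support?) is run on 20 seeded simulations of
32 taxa with flank rate multiplier 8, each analysed with 2 runs × 10
iterations and 100 bootstrap replicates — the package's chosen desk-scale
study; the full-scale analog of published practice (6 runs × 20 iterations)
remains the `coestimate()` default. `scripts/acceptance.R` reruns a
condensed version of the same study (8 simulations) from a single seed.

## Numerical and degenerate-input choices

* Distances: saturated or incomparable pairs are capped at `d_max`, never
  dropped; the k-mer distance of a record shorter than `k` is 1 (warned).
* Likelihood: per-node rescaling prevents underflow; zero-length branches
  are allowed (a conflicting zero-length configuration scores `-Inf`).
* Column classification: columns with fewer than two unambiguous residues
  are counted separately (`n_other`) rather than forced into a class; the
  reported informative percentage rounds half away from zero, matching how
  such percentages are conventionally printed.
* Long branches: a leaf is flagged when its terminal branch is strictly
  longer than `factor ×` the median terminal branch (default 5) — "extremely
  long" has no standard definition, so the rule is explicit and
  configurable.
* Record filters: "too short" is strict (`length < min_length`, default
  200 nt, a config value rather than a biological claim).

## Known limitations

NJ on JC distances is a fast, deterministic stand-in for ML/Bayesian tree
estimation, and bootstrap frequencies are not posterior probabilities; both
slots are designed so heavier estimators can be swapped in. The co-estimation
loop realigns from the guide topology alone, a stated simplification of
divide-and-conquer co-estimation software. Placement is clade-membership
based, not likelihood-weighted.
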
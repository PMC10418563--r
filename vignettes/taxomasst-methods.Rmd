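---
title: "Searching MS/MS spectra against monoculture libraries: methods and design"
author: "taxomasst authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching MS/MS spectra against monoculture libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxomasst)
```

## The problem

A tandem mass spectrum is a fingerprint of a molecule: the m/z pattern
of its fragment ions. When the same fingerprint recurs in LC-MS/MS
files acquired from microbial monocultures, the molecule can be
attributed to those taxa even if its structure is unknown. `taxomasst`
implements this attribution as a local, fully inspectable pipeline:
spectral similarity scoring, indexed library search, taxonomic
aggregation, and a differential workflow for extracting candidate
microbial spectra from host-associated studies.

This vignette documents the model, the tunable parameters, the
synthetic data used for validation, and the design decisions that were
genuinely open.

## Modified cosine similarity

Let spectra $q, r$ have precursor m/z $m_q, m_r$, peak m/z values
$x_i, y_j$ and weights $w_q(i), w_r(j)$. With fragment tolerance $t$
and $\Delta = m_q - m_r$, the candidate pairs are

* **direct**: $|x_i - y_j| \le t$;
* **shifted** (analog pairing only): $|x_i - y_j - \Delta| \le t$.

A pair eligible both ways counts once, as direct (this matters only
when $|\Delta| \lesssim 2t$). Over a one-to-one assignment $P$ of peaks
maximizing $\sum_{(i,j) \in P} w_q(i)\,w_r(j)$,

$$\mathrm{score}(q,r) \;=\; \frac{\sum_{(i,j)\in P} w_q(i)\, w_r(j)}
{\lVert w_q \rVert\, \lVert w_r \rVert},$$

with norms over the complete peak lists. By Cauchy–Schwarz the score
lies in $[0,1]$ and equals 1 exactly for a spectrum against itself.

**Weighting.** $w = \sqrt{\text{intensity}}$ by default, the molecular
networking convention that tempers the dominance of base peaks. `"raw"`
intensity and a general $I^p \cdot (m/z)^q$ form are available.
Intensities are stored raw at I/O; weighting happens only inside
scoring, so libraries are transformation-agnostic.

**Assignment.** The default is greedy selection in descending pair
weight with deterministic tie-breaks (smaller query index, then smaller
reference index), as common molecular-networking implementations do.
An exact branch-and-bound maximum-weight assignment is available via
`method = "exact"`. Greedy can in principle be suboptimal when one peak
participates in several near-equal-weight candidate pairs; with a 0.05
Th tolerance and realistic peak spacing such conflicts are rare, and on
thousands of random and perturbed-copy pairs the greedy score matches
the exhaustive optimum to floating-point noise (the test suite and the
acceptance script both measure this gap rather than assume it).

**Tolerances** are absolute Th, not ppm, matching the search defaults
below.

## Search engine

The reference library is indexed by precursor m/z (a sorted array with
binary-search range queries). A query retrieves candidates within
`precursor_tol` (exact mode) or `analog_window` (analog mode), scores
them with the modified cosine (shifted pairing enabled in analog mode),
and reports matches passing both thresholds. Results sort by descending
score, then ascending $|\Delta|$, then reference id — fully
deterministic.

Default parameters (also printed by the `params` CLI subcommand):

| parameter | default | meaning |
|---|---|---|
| `precursor_tol` | 0.05 Th | exact-mode candidate half-window |
| `frag_tol` | 0.05 Th | fragment pairing tolerance |
| `min_cosine` | 0.7 | minimum reported score |
| `min_matched_ions` | 3 | minimum matched fragment pairs |
| `analog` | off | precursor-mass-shift-tolerant search |
| `analog_window` | 200 Th | analog-mode half-window (symmetric) |

The analog window is a design choice: analog search is defined by a
boolean in the upstream tool description without a stated window; 200
Th spans common modifications (glycosylation, acylation, halogenation)
while keeping candidate sets small. Indexing is by precursor m/z only;
charge is taken as given, and intensity-aware candidate pruning is
deliberately not implemented because it could change result sets —
index and brute-force linear scan must return identical results, and a
dedicated oracle test enforces exactly that.

## Taxonomic aggregation

File metadata follows a 10-column schema (repository path, unique file
id, dataset id, submitted and alternative taxon names, NCBI id,
automatic/manual assignment flag, harmonized-metadata flag, blank flag,
QC flag). Lineages come from a pre-exported table mapping NCBI ids to
ranked `rank:name:id` chains — a one-time export, so no live taxonomy
service is needed at search time. Resolution tries the record's NCBI
id, then the alternative and submitted names against a name-to-id map
(the "closest accurate taxon" route used when a strain is absent from
the taxonomy and curated to its species), then a generic domain
placeholder when the name only says "bacterium" or "fungus".

Kept ranks are domain/superkingdom, kingdom, phylum, class, order,
family, genus, subgenus, species, subspecies, varietas, strain. The
domain level is retained on purpose although it sits above "kingdom to
strain": the three domains of life anchor the displayed tree and the
bacteria/fungi classification of matches needs those subtrees; other
intermediate ranks are dropped, with their files re-attached to the
nearest kept ancestor.

**Counting.** `n_samples` of a taxon is the number of biological files
in its subtree. Blank, QC and human-cell-line files live under
dedicated children of the root (negative synthetic ids avoid NCBI
collisions) and are excluded from biological totals, root included.
This is a documented choice on a question the upstream description
leaves open (whether blanks count in parent totals): excluding them
keeps every proportion interpretable as "fraction of biological files
of this taxon containing the molecule" and bounded by 1.

**Match propagation.** A match is credited to distinct *files*, not
scans — a file matched by three scans counts once — and propagated to
every ancestor. Each biological node's matched-file set is therefore
the union of its children's sets, counts are non-increasing from
ancestor to descendant, `n_matched ≤ n_samples` everywhere, and
`proportion · n_samples = n_matched` in exact integer arithmetic.
Per-scan detail is still available in `dataset_matches.tsv`. Matches to
blank/QC/cell-line files are recorded on their special nodes and
reported separately; they do not enter the root's biological count.

**Filtering.** `filter_tree()` collapses ranks finer than `max_rank`
(counts at kept nodes are already upstream-propagated, so they are
unchanged) and prunes nodes with fewer than `min_matches` matched
files; because counts are monotone along lineages, ancestors of
surviving nodes always survive, and pruning is monotone in the
threshold.

## Differential pipeline

The mining workflow chains four set refinements, each stage's output a
subset of its input:

1. `condition_unique()` — spectra present (abundance > a configurable
   floor, default 0) in at least one target-condition sample and in no
   other sample, e.g. spectra unique to colonized (SPF) versus
   germ-free animals.
2. `remove_control_analogs()` — drop spectra linked by a
   molecular-network edge to a control spectrum with cosine strictly
   above 0.7 **and** |precursor delta| ≤ 0.02 Da; both criteria are
   required. Edges are consumed as input (the network is upstream).
3. `microbial_screen()` — search survivors against the monoculture
   library; partition into matched, matched-but-also-in-cell-lines
   (set aside as not unambiguously microbial), and unmatched, with
   bacteria/fungi/both domain labels. A spectrum matching only
   cell-line files counts as the cell-line class, not as unmatched.
4. `cross_dataset_persistence()` — of the clean matches, which recur in
   a second study (any match at the engine's thresholds), and which of
   those occur only in untreated (no-antibiotics) samples. The
   similarity thresholds for this step are unspecified upstream; the
   engine defaults (0.05/0.7/3) are reused and configurable.

Compound-class prediction is out of scope; an optional user-supplied
class-label table can be joined onto the stage outputs by spectrum id.

## Synthetic repository and what it does (not) show

`make_repository()` generates the validation bed: a taxonomy of
bacterial and fungal genera (6 + 3 by default, 2 species each), 10
files per species, 10 scans per file, plus 10 blanks sharing a media
spectrum, 5 QCs, and 5 human cell-line files — about 200 files and
2,000 spectra, a scale chosen so the full validation suite runs in
well under a minute on one CPU. Ten marker molecules are planted, each
in half the files of one producer species (so the species-level match
proportion is exactly 0.5); two molecules also get analog variants
(precursor and a random subset of fragments shifted by +14.0157 Th, a
methylene homolog) planted in additional producer files — found by
analog search, invisible to exact search. One "host" molecule is
planted in both a bacterial species and the cell-line files to
exercise overlap detection. Everything is deterministic given the seed
and recorded in a truth table.

The default noise model is zero (planted occurrences are exact copies),
which is what the exactness checks — recovery equals truth, proportions
equal planted fractions — require. A documented noise level (fragment
jitter SD 0.005 Th, 5% peak dropout, 10% decoy-peak rate) is exercised
in a regression test, where recall stays ≥ 0.95 with no false files.
What the fixture does **not** emulate: chromatography, isotope
envelopes, adducts, co-isolation chimeras, instrument-dependent
fragmentation variability, or realistic spectral density near a given
precursor. Passing tests therefore demonstrate correctness of the
algorithms and plumbing, not real-world recall against repository-scale
data, where tolerance and threshold choices dominate.

`make_differential_fixture()` plants a full funnel (defaults: 100
consensus spectra → 40 target-unique → 25 after analog removal → 12
with microbial matches, 2 of them cell-line-overlapping → 10 clean → 8
recurring in the second study → 6 untreated-only) with decoy edges that
fail exactly one of the two removal criteria. Microbial members are
copies of distinct repository templates so no accidental cross-matches
inflate later stages.

## Numerical and degenerate-input choices

* Peaks closer than 0.002 Th are merged on request
  (`normalize_spectrum()`), intensity-summed at the intensity-weighted
  centroid, iterated to a fixed point so the operation is idempotent;
  the precursor region (everything above precursor − 17 Th) can be
  stripped. Both steps are off the search path by default — queries
  and libraries are scored as given.
* Two empty spectra have no defined cosine: that is an error, not a 0.
  An empty query is an input error; empty reference spectra are
  skipped.
* Boundary ties on the precursor window are kept (closed interval).
* Scores are clamped to 1 against floating-point overshoot.
* Zero-sample taxa report proportion 0 rather than NaN.
* All row sorts (matches, taxa tables, tree children) are total orders,
  making every output byte-reproducible; the acceptance script runs the
  CLI twice and compares bytes.

## Known limitations

* Attribution is only as good as the reference collection: a molecule a
  monoculture never produced (wrong substrate, wrong conditions) cannot
  match, and specimen misidentification upstream propagates silently.
* MS/MS does not distinguish stereoisomers; matches speak to molecular
  family, not configuration.
* The greedy/exact agreement is measured, not proven; pathological
  spectra with many near-equal candidate pairs could in principle open
  a gap, which the oracle tests would surface as a recorded nonzero
  maximum.
* Bit-compatibility with any hosted implementation of this search is
  not promised: weighting and pairing conventions differ between
  servers and are not fully specified publicly.
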
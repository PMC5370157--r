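---
title: "Evaluating SSU primers against shotgun rRNA reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating SSU primers against shotgun rRNA reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnaprimer)
```

## The method

PCR amplicon surveys stand or fall with their primers. Because public rRNA
databases are themselves dominated by PCR products, evaluating a primer
against them overstates its coverage: sequences a primer misses are
underrepresented in the very database used to score it. Shotgun metagenome
and metatranscriptome reads sidestep that circularity — no primer selected
them — but they are short, arrive on either strand, and only a fraction of
them touch an rRNA gene at all. The pipeline in this package turns such
reads into primer-coverage statistics in two stages, with an optional
prescreen in front.

### Prescreen

Roughly 0.2 % of metagenome reads derive from SSU rRNA genes, so aligning
everything is wasteful. The prescreen keeps a read iff the fraction of its
distinct *k*-mers (default *k* = 11) shared with any member of a small
representative set — on either strand — reaches `min_shared` (default
0.10). The representative set comes from greedy incremental clustering of
a reference database at 75 % global identity, longest sequence first, ties
by id: a sequence joins the first representative it matches at or above
the threshold, else founds a new one. Greedy order and tie rules are fixed
so the output is deterministic. Identity is defined as identical columns
over the global-alignment length (match +1, mismatch −1, linear gap −2
per base); the clustering threshold is conventional for rRNA
representative sets, and the screen itself is deliberately permissive —
its only job is recall, since everything it passes is re-scored exactly
downstream. Metatranscriptomes, where rRNA dominates, skip the screen, as
do amplicon sets.

### Stage I: orient, classify, project

**Search score.** For a query against a template database the score is
`100 × |query's distinct 8-mers found in the template| / |query's distinct
8-mers|`, the best template taken over the set (ties by template id). Each
read is scored on both strands against the SSU reference — in
metatranscriptome mode also against the LSU reference, giving four scores
— and the global maximum fixes strand, gene and template. Reads whose best
score falls below the cutoff (default 30 on the 0–100 scale) are not
considered rRNA. Among equal-scoring candidates, SSU is preferred over
LSU, then the lexicographically smaller oriented sequence: that last rule
looks arbitrary but is the one that makes orientation strand-symmetric —
a read and its reverse complement always resolve to the same oriented
sequence, so downstream results cannot depend on which strand the
sequencer happened to report.

**Classification.** A Wang-style naive-Bayes classifier is trained at the
lowest taxonomy rank (genus): `P(w | g) = (n_g(w) + 0.5) / (N_g + 1)`,
with `n_g(w)` the number of genus-g training sequences containing 8-mer
`w`. A read is assigned to the genus maximizing the joint log-probability
of its distinct 8-mers. Confidence comes from 100 bootstrap resamples of
⌈m/8⌉ of the read's m 8-mers; the bootstrap value at a rank is the
percentage of resamples agreeing with the winning lineage at that rank
(and all ranks above it). A read passes iff its domain is Bacteria,
Archaea or Eukarya and the *domain-level* bootstrap reaches the cutoff —
60 by default, switching automatically to 50 for reads shorter than 250
bases. Gating at the domain rank (rather than the deepest rank) is the
reading of the acceptance rule we adopted; all ranks are reported, so
stricter users can filter further. Within a bootstrap resample, ties
between genera — resamples carrying no discriminating 8-mer — are broken
uniformly at random (seeded, hence reproducible): breaking them
deterministically would let entirely uninformative reads accumulate
spurious agreement on whichever genus sorts first.

**Projection.** Accepted reads are placed into the reference alignment's
fixed column space so that coordinates are comparable across reads
(NAST-style). The oriented read is globally aligned to its best template's
ungapped sequence — match +1, mismatch −1, gap open −2, gap extend −1,
free terminal overhangs on both sides, traceback ties resolved diagonal,
then up, then left — and the pairwise alignment is threaded through the
template's gap pattern. Read insertions relative to the template fill the
template's gap columns left to right; insertions exceeding the available
gap columns are recorded as rejected-insertion bases and omitted from the
projected string. Nothing is lost: degapping the projection and
re-inserting the rejected bases at their recorded read positions
reconstructs the read exactly, an invariant the test suite enforces for
every simulated read. Free overhangs matter here: a read that runs off the
end of its gene into flanking genomic sequence has that tail gapped out
free rather than smeared across the template as noise.

### Stage II: binding sites and match types

A full-length anchor sequence (for 16S work, conventionally the
*E. coli* gene) is carried as a row of the reference alignment, giving a
bijection between its ungapped positions and alignment columns. Each
primer is expanded into its non-degenerate variants — parenthesized
alternatives and IUPAC codes both accepted — and anchored by sliding each
variant (reverse-complemented for R-orientation primers) along the anchor
sequence; the best placement must have at most 2 mismatches or the run
aborts before any read is touched, since every downstream number depends
on the interval being right.

For each projected read, the bases occupying the primer's columns are
extracted together with up to `pad` flanking bases per side (default 4,
allowed 3–5): the pads absorb small base slips left over from the
multiple-alignment step. The variant is then re-aligned to this padded
site and typed per primer position: `=` match, uppercase read base for a
substitution, `d` for a primer base absent from the read, lowercase read
bases for extra read bases between primer positions, `.` for primer
positions the read does not cover. Completeness is the covered fraction of
primer positions. Mismatches are counted with substitutions at one each
and indels at one per event; the last-4 window is the four primer
positions nearest the 3' end, in primer coordinates regardless of
orientation, and an indel event counts there if it touches the window.
A site is *matched* iff it is complete and has zero mismatches, or exactly
one mismatch outside the last-4 window — the standard PCR-efficiency
rationale that 3'-terminal mismatches are the disqualifying ones. The
degenerate primer inherits its best variant's typing, best meaning the
lexicographic minimum of (total mismatches, last-4 mismatches, variant
index); the recorded score is `100 × total + last4`, which linearizes that
key. Sites whose re-aligned identity over covered positions falls below
50 % are judged poorly aligned and dropped with a logged reason.

Three numerical choices in the site re-alignment deserve a note. First,
only the *site's* flanks are free in this alignment; the variant itself
must be consumed in full, otherwise a variant's mismatching 3' terminus
could dangle unaligned at zero cost and a terminal mismatch would
silently vanish. Second, the gap-open cost is −3 rather than the −2 used
in projection: at −2 a terminal substitution and a gap-plus-pad-match
slip score identically, and the free-end tie-break would choose the slip;
at −3 the substitution reading wins strictly. Third, pads may absorb
terminal indels — that is their stated purpose — so an insertion
adjacent to a pad is not charged to the primer.

### Reports

Per primer, a `.Match_type` table (one row per read: match string, site
span, mismatch counts, degree, completeness, taxonomy, score) and a
`.Stat` file of six tables: matched/mismatched counts, the completeness
distribution, the most frequent mismatch type, the most common match
string, per-position mismatch counts by type, and coverage over taxonomy
levels. Only complete sites (completeness 1) enter the matched/mismatched
counts and the coverage table — a fragment that cannot show the whole
site cannot testify about it — while tables 3–5 use every site with at
least one covered position, so partial evidence still informs the
mismatch spectrum. All taxa are listed with no abundance floor; deletion
events are charged to the first position of their run. Completeness is
tabulated by exact distinct values rather than histogram bins, which
keeps small outputs exact. `compare_composition()` supplies the Pearson
chi-squared goodness-of-fit test (Σ(O−E)²/E, df = categories − 1,
upper-tail p) used to validate recovered mock-community compositions.

## The simulator

`default_mock_community()` mirrors the validation design the pipeline is
tested under: 13 organisms — two Archaea, nine Bacteria, two Eukarya —
with equal abundance, 400-base reads, 6-fold per-genome coverage, and an
exact (error-free) read model. Coverage is per-genome fold coverage
scaled by relative abundance, so a genome of length L contributes
⌈coverage × abundance × L / read length⌉ uniformly placed, randomly
stranded reads; a `uniform` model substitutes bases i.i.d. at a given
rate. The rRNA gene family is generated by evolving one random
1.5-kb ancestor at 10 % per-site divergence per genus — enough for
genus-unique 8-mer profiles, comfortably within the divergence range of
real SSU genes — with the two V4 primer binding sites implanted as
conserved motifs at their familiar coordinates (515 and 787), the
biological picture being that universal primers target conserved regions.
Genomes are 20 kb of uniform ACGT background with one embedded gene.
An optional switch engineers a single 3'-terminal primer mismatch into
one member's gene, giving a constructive fixture whose correct coverage
answer (that genus 0 %, the rest 100 %) is known by design. The gene
family, the genome backgrounds and the read draws use three decoupled
seeded streams — backgrounds must not replay the draws that built the
genes, or background would contain ghost rRNA.

What the simulator does not emulate: real genomic composition (GC skew,
repeats, low-complexity tracts), multiple rRNA operons per genome,
sequencing error profiles of any particular platform, chimeras, and
length variation among rRNA genes (the generated family is
substitution-only, so the bundled reference alignment is gapless; the
gap/projection machinery is exercised by dedicated gapped fixtures in the
unit tests instead). Passing tests on this mock therefore demonstrate the
pipeline's internal correctness and its behavior under idealized
conditions, not performance on real platform error or real taxonomic
breadth.

Problem sizes in the tests and the acceptance script — 20-kb genomes
(3,900 reads), 1,000-read property suites, 1,000 randomized typing sites
— were chosen as the package's own desk-scale defaults: large enough for
the statistics being checked (hundreds of classified reads across 13
genera), small enough to rerun routinely.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` (prescreen) | 11 | word size of the shared-*k*-mer screen |
| `min_shared` | 0.10 | minimum shared-*k*-mer fraction to keep a read |
| `identity` | 0.75 | representative-set clustering threshold |
| `k_search` | 8 | word size of search score and classifier |
| `search_cutoff` | 30 | minimum search score (0–100); 10–30 across published runs |
| `bootstrap_cutoff` | 60 / 50 | domain-level bootstrap gate; 50 below 250 bases |
| `n_boot` | 100 | bootstrap resamples |
| `pad` | 4 (3–5) | flank bases per side of an extracted site |
| `min_identity` | 0.5 | poor-alignment drop threshold over covered positions |
| `max_mismatch` | 2 | anchor-placement validation threshold |

## Other design decisions

* The primer-list file syntax (name, sequence, orientation; whitespace
  separated; `#` comments) is this package's own convention — no standard
  exists for degenerate primer lists with orientations.
* BLAST is not a dependency: the prescreen is an internal shared-*k*-mer
  filter with equivalent recall behavior at these scales, and the main
  stage re-scores everything anyway. Pairwise alignment is implemented in
  compiled code inside the package because the method requires fixed
  scoring *and* a stated traceback tie order for bit-for-bit
  reproducibility; `Biostrings::pairwiseAlignment` serves as an
  independent score oracle in the test suite.
* The command-line front end exposes flags only; every option defaults
  sensibly and scripted runs are expected to go through the R API, so a
  separate config-file layer was left out.
* FASTQ qualities are parsed but unused: the method never filters on
  quality, and silently dropping them would surprise users less than
  pretending to use them.
* `U` is normalized to `T` on input; `.` and `-` are both accepted as
  alignment gaps (reference files mix them) and normalized to `-`
  internally — the `.` of a match-type string means "missing", an
  unrelated concept.

## Known limitations

* The search score is a *k*-mer containment fraction, not an alignment
  identity; very short queries (near the word size) score coarsely.
* Naive-Bayes classification at small reference scale is sensitive to the
  genus inventory: with very few genera, spurious *k*-mer hits concentrate
  instead of spreading, inflating bootstrap values for junk reads (the
  random tie-break mitigates, but a reasonably sized reference is the
  real fix).
* Reads spanning an rRNA gene boundary carry genomic tails; free-end
  projection parks them outside the template, but a tail that happens to
  resemble the reference can survive the 50 % identity drop and
  contribute a noisy site. At default cutoffs this did not occur in any
  tested condition; at permissive cutoffs (search score 10) it remains
  possible.
* Thermodynamic primer scoring (ΔG, melting temperature) is out of
  scope: coverage here is purely sequence-match-based.
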
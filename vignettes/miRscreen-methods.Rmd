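---
title: "Functional miRNA annotation and seed scanning: models, parameters and design"
author: "miRscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional miRNA annotation and seed scanning: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRscreen)
```

## Scope and assumptions

`miRscreen` implements two related procedures. The first classifies
precursor miRNAs as functional by combining four independent evidence
channels into a composite score; the second scans user sequences for
7-mer seed-complementary target sites and ranks candidate interactions.
Both operate strictly on offline files: miRBase-dialect FASTA, a
tab-delimited read-count table, a gene2pubmed-style association table, a
plain high-confidence id list and a 3′-UTR FASTA. Nothing is fetched
from the network.

The underlying assumptions are worth stating explicitly:

- **Literature self-correction.** Genuinely functional miRNAs are
  repeatedly described by independent studies, while false discoveries
  accumulate few or no further citations. We operationalise "independent
  studies" as distinct PubMed record ids, because the available mapping
  carries no study-independence metadata.
- **Conservation implies function.** A mature miRNA with an ortholog in
  another vertebrate is more likely functional. Since 3′ ends of mature
  miRNAs are post-transcriptionally modified and annotation of the exact
  3′ terminus is unstable, orthology requires perfect identity of the
  5′-end 19 nt only.
- **Expression implies processing.** A miRNA consistently detected
  across many small-RNA-seq experiments is at least produced; pooled
  reads-per-million (RPM) is the abundance unit.
- **Curated structural evidence is complementary.** The high-confidence
  flag is consumed as an input list; we deliberately do not re-derive it
  (that is a structural analysis of precursor processing, a different
  method).

## Scoring model

Per precursor: PubMed score 0–3 (brackets at 2, 3, 4 records),
conservation score 0–2 (brackets at 1, 2 other species), expression
score 0–2 (1 for 1–10 RPM inclusive, 2 strictly above 10), miRBase score
0–1. The composite is their sum, and `composite >= 3` defines a
functional call. All brackets, the threshold, the prefix length and the
arm-selection thresholds live in `scoringParams()` and can be overridden
(including from a YAML config through the CLI), so boundary behaviour is
directly testable.

Granularity: PubMed counts and the high-confidence flag attach to the
precursor; conservation and expression are properties of mature arms, and
the precursor takes the **maximum over its arms**. This matches the
gene-level granularity of the literature and curation inputs while
letting either arm provide biogenesis evidence.

Arm selection: the dominant arm is the one with the highest pooled RPM.
A secondary arm is kept iff its RPM is at least 10% of the dominant
arm's *and* at least 5 RPM, both inclusive ("no less than" readings of
the rule). Ties at exactly equal RPM prefer the 5p arm, then the
lexicographically smaller name — the rule is arbitrary but deterministic,
which matters for byte-identical re-runs.

The contribution analysis removes one criterion score at a time: a
criterion is *required* for a precursor iff the precursor is functional
but the composite minus that criterion's score falls below the
threshold. Removal can never increase the composite, and a required
criterion necessarily has a nonzero score; both facts are asserted as
properties in the test suite.

### Decisions on under-specified points

Three details of the scoring rules admit more than one literal reading;
we fixed each once:

- **RPM aggregation across experiments** is *pooled*: total counts over
  total library size, times 10⁶. Pooling weights experiments by depth
  and is robust to very shallow libraries, where per-experiment RPMs are
  noisy. The mean-of-RPMs alternative is implemented and selectable
  (`rpmAggregation = "mean"`), but pooled is the default everywhere.
- **Bracket boundaries**: "1–10" is inclusive on both ends, "over 10" is
  strict; the secondary-arm thresholds are inclusive.
- **Sub-bracket inputs score 0** (one PubMed record, zero orthologs,
  0.4 RPM): only positive brackets are defined, so zero is the forced
  complement.
- **Sub-19-nt matures** (the accepted range is 17–30 nt) compare over
  `min(19, len_a, len_b)`; the relation stays symmetric and degrades
  gracefully rather than excluding short matures outright.

## Seed scanning

A miRNA submission must be 17–30 nt, a target submission 100–30 000 nt
(both bounds inclusive, both configurable); sequences are whitespace
stripped, case folded, and T→U normalized, so DNA input is accepted.
The seed is miRNA positions 2–8 (1-based), the standard 7-mer
convention; the positions are configurable because conventions differ
(1–7, 2–8, 2–8 with an A1 anchor). Screening finds every occurrence of
the Watson–Crick reverse complement of the seed on the target sense
strand; overlapping occurrences all count, and no G:U wobble is allowed
— the screen is literal complementarity. Internally coordinates are
0-based half-open; all written reports are 1-based inclusive.

Ranked results need a score. The prediction model that would normally
provide one is a trained classifier out of scope here, so the package
uses an explicit surrogate on the conventional 50–100 presentation
scale:

$$\mathrm{score}(n, L) = 50 + \mathrm{round}\!\left(50\,(1 - e^{-x/4})\right),
\qquad x = n\left(1 + \frac{1000}{L}\right)$$

for $n$ seed sites on a target of length $L$. It is monotone in site
count at fixed length, rewards site density, and is clamped to the scale
by construction. It is labelled `surrogate_score` in every output and
should be read as a deterministic ranking device, not a calibrated
confidence. Ties break by ascending target id (miRNA-mode) or miRNA
name (target-mode), so output is diff-stable and permutation-invariant
to input order.

## Synthetic study conditions

`fixtureSpec()`/`generateFixtures()` produce every input the pipeline
consumes, with exported ground truth. The defaults are the package's
fixed study conditions:

| parameter | default | rationale |
|---|---|---|
| species | hsa, mmu, rno, cfa, gga | the five supported vertebrates |
| nFamilies | 30 | ~150 precursors across species: genome-like diversity at desk scale |
| orthologFraction | 0.5 | even mix of conserved and species-specific families |
| nExperiments | 81 | the size of the public expression compendium being emulated |
| rpmRange | 0.05–100, log-uniform | spans all three expression brackets |
| nbDispersion | 2 | strong overdispersion typical of small-RNA-seq counts |
| libSizeRange | 2×10⁵–2×10⁶ | realistic small-RNA library depths |
| pubmedZeroProb / pubmedLambda | 0.4 / 3 | sparse, zero-inflated citation counts spanning the brackets |
| highconfFraction | 0.3 | a curated minority |
| utrCount / utrLenRange | 25 / 300–3000 nt | typical 3′-UTR lengths |
| plantedSitesPerUtr | 2 | guaranteed recoverable sites |

Orthologous family members share each arm's 5′ 19-mer and re-draw
nt 20–22 independently, emulating 3′-end divergence. Counts are negative
binomial around `trueRPM × librarySize / 10⁶`. UTRs are written as
RefSeq-style DNA to exercise T→U normalization, with seed-complementary
sites planted at recorded, non-overlapping coordinates. Incidental
(unplanted) seed matches are *not* suppressed — suppressing them would
bias base composition — and are reconciled in tests against a naive
all-window oracle instead.

Ground truth is computed by `oracleScores()`, a deliberately plain
straight-line restatement of the scoring rules (literal if/else
brackets, character-by-character prefix loops, explicit RPM arithmetic)
that shares no code with the scoring implementation. Test fixtures are
therefore checked by two independent routes, and the end-to-end gate
requires exact (100 %) agreement of classification labels with ground
truth — attainable because the procedure is deterministic.

What the generator does **not** emulate: real miRBase name/locus
idiosyncrasies (e.g. one mature hosted by several loci), real citation
distributions, UTR base composition and repeat structure, and any
correlation between criteria (in real data conservation and expression
are strongly correlated). Passing tests therefore demonstrate
correctness of the rules and plumbing, not performance on real
annotation snapshots; genome-scale headline counts from any particular
miRBase/PubMed snapshot are out of scope by design.

## Numerical and degenerate-input choices

- Scores are small integers throughout; the only floating-point quantity
  is RPM, compared against brackets with plain `>=`/`>` (no epsilon —
  inputs are ratios of integers, and test fixtures use library sizes
  that make bracket values exact).
- An empty count table is valid (zero matures); missing library sizes
  default to column sums with a warning, floored at 1 so the
  zero-matures case stays well-defined.
- A precursor with no joined mature arms cannot be scored and raises a
  validation error rather than silently scoring 0: an unjoined input is
  almost always a name-stem mismatch the user should see.
- Duplicate precursor names, non-integer or negative counts, unknown
  species prefixes and alphabet violations are all rejected at parse
  time with the offending record or cell named.
- All randomness flows from a single integer seed; re-running any
  subcommand on the same inputs is byte-identical.

## Problem sizes used in the test suite

The oracle-equivalence suite runs 20 random fixture specs of 4–12
families over 2–5 species; the seed-site oracle comparison runs 1000
random miRNA/target pairs (a third with a planted site); the end-to-end
gate runs the full default conditions (30 families × 5 species, 81
experiments). These sizes keep the whole suite under a couple of
minutes on one CPU while exercising every bracket boundary and both
scan modes.

## Known limitations

- The surrogate score is intentionally naive; it ranks by seed-site
  count and density only and ignores context features (AU flank
  content, position in UTR, pairing energy, conservation of the site).
- Orthology by exact 19-nt prefix identity misses orthologs with a
  single 5′-region substitution and treats paralogs with identical
  5′ ends as orthologs; both behaviours are inherent to the rule, not
  bugs.
- PubMed evidence is as good as the supplied association table; the
  package does no text mining.
- The high-confidence criterion is only as current as the supplied list.
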
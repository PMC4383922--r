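# miRscreen

Functional microRNA annotation and seed-match target scanning, entirely
from offline, file-based inputs.

## The problem

miRBase accepts essentially any miRNA reported in a peer-reviewed study, so
a large fraction of catalogued miRNAs are unlikely to play a functional
regulatory role — some are outright artefacts of noisy small-RNA-seq
experiments. Screening libraries and genome-scale computational analyses
are both degraded by these entries. `miRscreen` addresses this with a
transparent evidence-combination score over four independent criteria, plus
a companion workflow for scanning user-provided sequences for candidate
miRNA target sites.

## The model

For each precursor miRNA *i*, four integer criterion scores are computed:

- **PubMed score** `P_i ∈ {0..3}` from the number of distinct PubMed
  records associated with the miRNA (gene2pubmed-style map): 1 point for
  two records, 2 for three, 3 for four or more.
- **Conservation score** `C_i ∈ {0..2}` from the number of *other* species
  (among hsa, mmu, rno, cfa, gga) carrying an ortholog: 1 for one species,
  2 for two or more. Because the 3′ end of a mature miRNA is
  post-transcriptionally variable, orthology is defined as **perfect
  identity of the 5′-end 19 nt** of the mature sequence.
- **Expression score** `E_i ∈ {0..2}` from pooled abundance over all
  RNA-seq experiments, `RPM = 10⁶ · Σ_e c_e / Σ_e N_e`: 1 point for
  1–10 RPM (inclusive), 2 for > 10 RPM.
- **miRBase score** `M_i ∈ {0,1}`: 1 if the precursor appears on the
  curated high-confidence list.

The composite score `S_i = P_i + C_i + E_i + M_i ∈ {0..8}`, and a
precursor is called **functional** when `S_i ≥ 3`. For every functional
precursor the dominantly expressed mature arm is selected; the second arm
is also kept iff its pooled expression is ≥ 10 % of the dominant arm's
**and** ≥ 5 RPM. A criterion-removal analysis reports, per precursor, the
criteria whose removal would drop the composite below the threshold.

The target-scanning workflow validates a user miRNA (17–30 nt) or target
sequence (100–30 000 nt), screens for **7-mer seed complementarity**
(Watson–Crick reverse complement of miRNA positions 2–8, sense strand,
overlaps allowed) and ranks hits by a documented monotone surrogate score
on the conventional 50–100 presentation scale
(`50 + round(50·(1 − e^(−x/4)))` with `x = n·(1 + 1000/L)` for `n` sites
on a target of length `L`). The surrogate ranks by site count and density
only; it is not a trained target-prediction model.

## Worked example

Generate a seeded synthetic evidence bundle (three species, ten
experiments), annotate it, and scan one of its miRNAs against the bundled
3′-UTRs:

```r
library(miRscreen)

d <- file.path(tempdir(), "fix")
res <- generateFixtures(fixtureSpec(rngSeed = 11L, nFamilies = 6L,
                                    species = c("hsa", "mmu", "rno"),
                                    nExperiments = 10L, utrCount = 6L), d)

mat  <- readMatureFasta(res$paths[["mature"]])
pre  <- readHairpinFasta(res$paths[["hairpin"]])
expr <- readExpressionTable(res$paths[["counts"]])
pm   <- readPubmedMap(res$paths[["pubmed"]])
hc   <- readHighConfList(res$paths[["highconf"]])

ann <- annotateFunctional(pre, mat, expr, pm, hc)
head(ann[, c("name", "pubmed_score", "conservation_score",
             "expression_score", "mirbase_score", "composite",
             "is_functional", "dominant_mature", "secondary_mature")])
#>       name pubmed_score conservation_score expression_score mirbase_score
#>  hsa-mir-1            3                  2                1             1
#>  mmu-mir-1            3                  2                2             1
#>  rno-mir-1            3                  2                2             0
#>  hsa-mir-2            1                  0                1             0
#>  mmu-mir-3            0                  0                0             0
#>  mmu-mir-4            2                  0                2             0
#>  composite is_functional dominant_mature secondary_mature
#>          7          TRUE      MIMAT00115             <NA>
#>          8          TRUE      MIMAT00123             <NA>
#>          7          TRUE      MIMAT00133       MIMAT00135
#>          2         FALSE      MIMAT00213             <NA>
#>          0         FALSE      MIMAT00325             <NA>
#>          4          TRUE      MIMAT00425       MIMAT00423
```

`mir-1` is a conserved family planted across all three species, so each
copy collects the conservation points (2), literature points (here 3, from
four or more simulated PubMed records) and expression points; every copy
clears the threshold of 3. `mmu-mir-3` has no supporting evidence and is
called non-functional. `rno-mir-1` also keeps its second arm: that arm is
above 10 % of the dominant arm's expression and above 5 RPM.

```r
utrs <- readUtrFasta(res$paths[["utr"]])
scanCustomMirna(mirSequence(mat)[[1]], utrs, mirnaName = mirName(mat)[1])
#>  rank surrogate_score   mirna_name target_id gene_symbol n_sites site_positions
#>     1              66 hsa-miR-1-5p NM_000004       GENE4       1      1498-1504
#>  matched_7mers
#>        GGGUAGA
```

One UTR contains a site complementary to the query's seed, at positions
1498–1504 (1-based, inclusive); the matched 7-mer is the reverse
complement of miRNA positions 2–8.

The same operations are available from a shell via the thin wrapper
`inst/scripts/mirscreen.R` (subcommands `annotate`, `scan`, `fixtures`;
exit codes 0 = success, 2 = usage/missing input, 3 = validation failure).

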
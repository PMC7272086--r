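# hccpm

Phosphorylated-biomarker prediction for hepatocellular carcinoma (HCC).

Hepatocellular carcinoma is the predominant primary liver cancer and is
usually diagnosed late; candidate biomarkers that are both HCC-associated
and plausibly phosphorylated (and therefore druggable through their
kinases) are of particular interest. `hccpm` implements a desk-scale,
fully testable version of a two-axis evidence-scoring system for such
candidates, for bioinformaticians who have per-protein evidence
annotations, pathway gene sets and cell-cycle expression profiles and
want reproducible, rule-based prioritization rather than a black box.

## The scoring model

**Phosphorylation correlation.** Protein sequences are scanned with
Prosite-syntax phosphorylation motifs (sliding window, all overlapping
matches, S/T/Y/H phosphoacceptor check); each matched motif proposes its
kinases. Every (query, kinase) pair is scored on three components:

* tissue evidence `St ∈ {0, 2, 6, 10}` — weaker of the two evidence tiers
  (protein-level T1, mRNA-level T2, sequence-origin T3, absent);
* subcellular localization `Sl ∈ {0, 2, 4, 6, 8, 10}` — best shared GO
  cellular-component term scored by the weaker evidence class L1–L4, with
  a category-overlap fallback worth 6;
* cell-cycle phase `Sp ∈ {0, 10}` — 10 iff both profiles are positive at
  a shared grid point of the 100-point interpolated cycle.

These combine into the kinase-correlation score

```
Sk = (Wt·St + Wl·Sl + Wp·Sp) / (Wt + Wl + Wp),   Wt = 5, Wl = 3, Wp = 2
```

and the best kinase classifies the query (strongly suggestive /
suggestive / not supported; `Sk = 6.8` and `4.8` are the corresponding
score boundaries).

**Marker evaluation.** In each pathway containing the query, the other
genes' HCC evidence (wet-lab E1, large-scale E2) sets the per-pathway
score: `Sc = W1(Ne + 0.8·Nm)/Np + W2` when E1 evidence is present,
`Sc = W2·Nm/Np` for all-E2 pathways (`W1 = 5`, `W2 = 3`; `Np` counts the
other genes). Per-pathway scores aggregate as the step-weighted mean
`Scm = Σ Sc·W(Sc) / Σ W(Sc)`; `Scm ≥ 4.25` is strongly suggestive,
`≥ 3` suggestive. A query with its own E1/E2 evidence is pinned at
`Sc = 10` / `8`.

**HCCPM call.** Strongly suggestive only when both axes are; not
supported only when both are; otherwise suggestive. Drug-target rows
(liver-cancer / cancer / non-cancer) are joined per gene.

## Worked example

```r
library(hccpm)

fx <- makeCorpus(fixtureConfig(nProteins = 30, nKinases = 5, seed = 7))
fx$corpus
#> HCCCorpus with 35 proteins ( 5 kinases )
#>   sequences:     30
#>   GO rows:       57
#>   motifs:        5
#>   pathways:      2
#>   drug rows:     6
#>   cycle grids:   22

res <- runPipeline(fx$corpus)
res$summary$phospho
#> STRONGLY_SUGGESTIVE          SUGGESTIVE       NOT_SUPPORTED
#>                   1                   4                  25
res$summary$hccpm
#> STRONGLY_SUGGESTIVE          SUGGESTIVE       NOT_SUPPORTED
#>                   0                   5                  25
```

Of the 30 synthetic candidates, one pairs with a kinase that passes all
three component rules (tissue, localization, phase), four pass tissue and
localization only, and the rest lack sufficient evidence; combining with
the pathway axis leaves five suggestive HCCPM candidates. The generator
also returns a constructively computed ground-truth ledger
(`fx$ledger`), and `runPipeline()` reproduces it exactly — that recovery
is the package's central correctness test.

Individual steps are available as plain functions:

```r
scanSequence("[RK](2)-x-[ST]", "AARRASAA", siteOffset = 2)
#>   start end matched_span site_position site_residue
#> 1     3   6         RASA            6            S   # acceptor = S at 6
kinaseCorrelation(6, 6, 10)
#> [1] 6.8
pathwayScore("NONE", Np = 4, Ne = 1, Nm = 0)
#> [1] 4.25
```

A thin CLI over the same functions is in `inst/scripts/hccpm-cli`
(subcommands `simulate`, `validate`, `scan`, `run`, ...), operating on
plain-text corpus bundles (FASTA + TSV + GMT).

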
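---
title: "Evidence-based scoring of phosphorylated HCC biomarkers: methods and design"
author: "hccpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based scoring of phosphorylated HCC biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccpm)
```

# The problem and the model

Hepatocellular carcinoma (HCC) biomarker discovery faces two orthogonal
questions about a candidate gene: *is it plausibly HCC-associated*, and
*is it plausibly phosphorylated by a kinase it can actually meet in the
cell*? `hccpm` scores both questions with transparent rules over curated
evidence, then combines them. Nothing in the package is fitted; every
score is a deterministic function of the input annotations, which makes
the system auditable and exactly testable.

## Phosphorylation correlation

A motif match alone (a Prosite-style consensus hit whose phosphoacceptor
is S, T, Y or H) only proposes a kinase; whether the kinase and substrate
can really interact depends on environment. Three components capture
this:

* **Tissue (`St`)**: both partners need evidence of expression in liver,
  blood or the lymphatic system. Evidence tiers are protein-level (T1),
  mRNA-level (T2) and sequence-origin-only (T3). The pair scores by the
  *weaker* tier — 10/6/2 — because an interaction is only as credible as
  its least-supported partner, and 0 if either partner is not expressed
  there at all (no opportunity to meet).
* **Subcellular localization (`Sl`)**: two layers reflect two data
  sources of different depth. Layer 1 scores the best GO
  cellular-component term shared by the pair, by the weaker evidence
  class: both experimental (L1) 10; weaker computational (L2) 8; weaker
  curatorial (L3) 4; any automatic (L4) 2. Scores of 8 or better are
  final. Otherwise layer 2 consults the curated localization categories
  (Secreted, CellMembrane, ER_Golgi, Mitochondrion, Cytoplasm, Nucleus):
  a shared category is worth 6, never lowering the layer-1 result.
* **Phase (`Sp`)**: kinase and substrate must be present at the same
  time. Profiles are log2(synchronous/asynchronous) ratios over percent
  of the cell cycle, interpolated to a 100-point grid; the pair scores 10
  iff both ratios are positive at some shared grid point, else 0. A
  missing profile scores 0 — absence of data is not evidence of
  co-expression.

The combined score is the weighted mean
`Sk = (Wt·St + Wl·Sl + Wp·Sp)/(Wt + Wl + Wp)` with defaults `Wt = 5`
(tissue restriction carries half the total weight for a liver-cancer
marker), `Wl = 3`, `Wp = 2` (phase data are scarcer than localization
data, so phase is down-weighted). The best kinase's scores classify the
query.

### Two classification readings

The class definitions can be read two ways that are *not* equivalent:

* **criteria** (default): strongly suggestive iff `St ≥ 6 ∧ Sl ≥ 6 ∧ Sp
  = 10`; suggestive iff `St ≥ 6 ∧ Sl ≥ 6` (phase ignored); else not
  supported.
* **threshold**: `Sk ≥ 6.8` / `6.8 > Sk ≥ 4.8` / below.

On the discrete component lattice the minima of the criteria regions are
exactly 6.8 and 4.8, so the two readings agree *at the boundaries*; but
e.g. `St = Sl = 10, Sp = 0` gives `Sk = 8` — suggestive by criteria,
strongly suggestive by threshold. Both modes are implemented
(`classifyPhospho(mode =)`); criteria is the default because the class
definitions are stated in terms of component conditions. The divergence
is asserted, not hidden, in the test suite.

## Marker evaluation

A gene is judged by the company it keeps. In each containing pathway,
let the OGSPs be the *other* genes of that pathway, `Np` their number,
`Ne` and `Nm` the counts with wet-lab (E1) and large-scale (E2) HCC
evidence. An unconfirmed query scores

* `Sc = W1·(Ne + 0.8·Nm)/Np + W2` if the pathway holds any E1 evidence,
* `Sc = W2·(Nm/Np)` if it holds only E2 evidence,
* 0 otherwise,

with `W1 = 5`, `W2 = 3`. Counting OGSPs (excluding the query) makes two
identities exact: an unconfirmed gene tops out at `W1 + W2 = 8`
(all-OGSP E1), and an all-E2 pathway yields exactly `W2 = 3` — which is
precisely the suggestive class floor. Including the query in `Np` would
make both bounds unattainable, so the exclusive reading is the one
implemented. A query that is itself E1/E2 is pinned at `Sc = 10`/`8` in
every containing pathway: its own evidence outranks any neighbourhood.

Across pathways, `Scm = Σ Sc·W(Sc)/Σ W(Sc)` with the step weights
`W(10) = 10`, `W(8) = 8`, `W([5,8)) = 5`, `W(<5) = 3`, so high-evidence
pathways dominate the mean. The open interval (8, 10) is unreachable for
an unconfirmed gene (the E1-branch maximum is exactly 8) and is mapped to
weight 5 by extending the `[5, 8)` band upward; only exact 8 and 10
receive the larger weights. Classes: `Scm ≥ 4.25` strongly suggestive
(the value of a single pathway with one E1 OGSP among four), `≥ 3`
suggestive, else not supported.

## The HCCPM combination

Strongly suggestive requires both axes strong; not supported requires
both axes unsupported; every mixed case is suggestive. The table is a
pure function of the two class labels, so the combined sets obey exact
set algebra (strong set = intersection of the strong sets, etc.), which
the tests assert on randomized inputs.

# Motif engine

Prosite syntax is parsed into an element list (literal, class `[...]`,
negated class `{...}`, wildcard `x`; repeats `(n)`/`(n,m)`; terminal
anchors `<`/`>`). Matching is a hand-written recursive sliding-window
scanner — the matcher is a core deliverable, and keeping it independent
of regular expressions lets the test suite use a separately written
regex translation (run overlapped under PCRE) as a true oracle; the two
agree on 1000 random pattern/sequence pairs per run.

Conventions, fixed deliberately where upstream semantics are
undocumented:

* coordinates are 1-based inclusive; all overlapping matches and all
  variable-length realizations are reported;
* the phosphoacceptor is the element at `site_offset` (0-based element
  index, repeats counting once); for a repeated site element the *first*
  matched residue is the site;
* `skip_flag` motifs are excluded from scanning by default (the name
  suggests exclusion), overridable with `includeSkipped = TRUE`;
* `max_repeat` is stored but not enforced unless `enforceMaxRepeat =
  TRUE`, which caps matches per motif per protein at that count;
* motifs whose matches never place S/T/Y/H at the site contribute no
  kinases.

The motif patterns shipped by the generator are synthetic fixtures
(literal tag motifs), not curated content.

# Cell-cycle profiles

Profiles are interpolated linearly onto integer percents 0–99. The cycle
is periodic (100% = cytokinesis = 0%), so the default interpolation
closes cyclically — the segment from the last raw point wraps to the
first; a non-cyclic flat-extrapolation mode exists for non-periodic
inputs. Degenerate inputs (fewer than two points, duplicate times, times
outside [0, 100)) are errors, not guesses. "Expressed at the same time"
is implemented as strict positivity of both log2 ratios at a shared grid
point with a configurable threshold (default 0, i.e. enrichment over the
asynchronous baseline); presence/peak/correlation readings were the
open alternatives, and positivity was chosen as the weakest assumption
that makes the score decidable from the ratios alone.

# Numerical and tie-breaking choices

* All classifications are computed on full-precision scores; printed
  tables round to 3 decimals.
* Equal-`Sk` kinases tie-break by lexicographic accession for
  reproducibility; self-pairs (autophosphorylation candidates) are
  scored normally and flagged.
* GO terms are compared as opaque identifiers (no ancestor propagation);
  a gene appearing in a pathway under several identifiers counts once.
* Unknown GO evidence codes map to the most conservative class L4 with a
  warning; the default code→class map follows the standard GO taxonomy
  and can be replaced via `readEvidenceMap()`.
* Validation is report-based (`validateCorpus()`): dangling
  cross-references are errors that abort `runPipeline()` unless forced;
  missing optional data (e.g. sequence-less proteins) are informational.

# The synthetic generator and what passing tests mean

`makeCorpus()` emulates the *structure* of a real corpus: evidence-tier
mixes, shared-annotation probabilities, pathway membership, half-cycle
square-wave expression profiles, drug rows. Defaults are chosen to
resemble a genome-scale candidate set (1000 candidates, 50 kinases, 7%
E1 / 3% E2 evidence, 25-gene pathways, half of pairs sharing a GO term);
tests that need smaller corpora say so explicitly. Each kinase carries a
unique literal tag motif and each candidate's sequence is tag-free
except at the planted site, so the candidate-kinase relation is exact by
construction. The expected component scores and classes are computed
*constructively while generating* — from literal copies of the rule
tables, not by calling the scoring engine — and the central test is that
the full pipeline recovers this ledger exactly on a seeded 1000-gene
corpus.

What this does **not** show: robustness to real-data messiness
(conflicting annotations, motif cross-matching between homologous
kinases, non-square expression profiles, pathway overlap). The generator
makes no attempt to mimic real UniProt/KEGG content distributions; it
is a correctness instrument, not a realism benchmark.

# Known limitations

* Kinase specificity is motif-set membership only; no position-specific
  scoring matrices or profile support.
* Dephosphorylation (phosphatase) motifs are not scored.
* Pathway topology is ignored; membership is the only signal.
* The published corpus-scale class counts depend on specific 2018
  database snapshots and are out of scope; the package reproduces the
  *rules* and their analytic anchor values, and its arithmetic on the
  published count triples, not the snapshot-dependent totals.
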
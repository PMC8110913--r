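---
title: "Inferring competing endogenous RNA networks with cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring competing endogenous RNA networks with cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The model

Competing endogenous RNAs (ceRNAs) are transcripts that share miRNA
response elements: a long non-coding RNA that binds a miRNA sequesters it
away from the mRNAs carrying the same element, so the lncRNA and the mRNA
are expected to be *positively* co-expressed and co-dysregulated while
both being predicted targets of the *same* miRNA. `cernet` formalises
that as the **ceRNA triplet** $(l, m, g)$: a lncRNA $l$ and an mRNA $g$
that

1. are each differentially expressed between the two study groups,
2. form a positively correlated expression pair, and
3. are both predicted targets of one retained miRNA $m$.

Triplets are assembled into an undirected typed graph whose topology is
then mined for hub and key-regulator lncRNAs, and the key lncRNAs are
layered with enriched pathways and transcription-factor regulators of
their partner mRNAs.

The package was designed around small two-group designs (three case vs
three control animals is the default everywhere), where moderated or
count-based differential machinery is unavailable or unnecessary because
the screening statistic of record is a plain fold change plus Student's
t-test.

## Stages and their parameters

**Differential screen** (`de_screen`). Fold changes use the signed-ratio
convention: $FC = \bar{x}_{case}/\bar{x}_{ctrl}$ reported as $FC$ when
$\ge 1$ and $-1/FC$ otherwise, so $|FC| \ge 1$ always and one threshold
covers both directions. The t-test runs on log2 intensities by default
(ratio-scale data have multiplicative noise; logging stabilises the
variance), with a `log_transform = FALSE` escape hatch and a `welch`
flag; the default is the classical equal-variance form. Defaults:
$|FC| > 1.5$, $p < 0.05$, both strict. No multiple-testing correction is
applied at this stage — the screen is a candidate filter, not an
FDR-controlled discovery list, and downstream refinement (|FC| > 2 plus
correlation and target evidence) is what controls false triplets. Genes
that are constant in both groups are reported with $p = 1$ and direction
`ns` rather than raising an error, so flat probes pass through real
matrices harmlessly.

**miRNA catalogue** (`reconcile_mirna`). Differential miRNA calls pooled
from several published datasets are reconciled by three rules, applied in
this order: (i) a miRNA reported up in one dataset and down in another is
dropped outright — with a handful of heterogeneous studies there is no
defensible majority vote; (ii) a precursor-level name with several
annotated mature forms is replaced by its children, each inheriting the
precursor's direction and counted individually; (iii) any mature name
absent from the target-prediction database universe is dropped, because
it can contribute no target edges downstream. The database check runs
after expansion since it is a property of mature names. Reconciliation is
order-independent and keeps per-dataset provenance.

**Target filtering** (`filter_targets`). miRNA→mRNA predictions arrive on
a 0–100 confidence scale with the conventional strict cutoff of 80.
miRNA→lncRNA predictions have no conventional cutoff and tool-specific
scales, so the default cutoff is the 0.9 quantile of the supplied score
distribution (top decile); the realised cutoff is recorded in the result's
`thresholds` attribute so outputs are self-describing. Duplicate
predictions across sources collapse to the maximum score — the most
confident call.

**Correlation pairing** (`coexpression_pairs`). Pearson correlation of
every DE lncRNA × DE mRNA combination across *all* samples pooled
(maximising $n$; with 3+3 samples, $n = 6$), $p$ from the exact $t$
transform with $n-2$ degrees of freedom, retention at $r > 0.99$ and
$p < 0.05$, both strict. The $r$ threshold is read as the correlation
coefficient and is positive-only, because the sponge model predicts
positive co-expression; an `abs_r` flag admits anti-correlated pairs for
exploratory use. Zero-variance vectors are skipped with a warning rather
than producing NaNs.

**Assembly and refinement** (`assemble_triplets`). Every
(pair, shared miRNA) combination becomes a triplet if both pair members
additionally satisfy $|FC| > 2$ and $p < 0.05$ — the stricter ceRNA-grade
cut applied on top of the screening threshold. The miRNA's own direction
is *not* constrained by default: literature miRNA calls carry no fold
change, and mixed-direction miRNAs legitimately attach to both lncRNA
classes. A `strict_mirna_direction` flag enforces the sponge-consistent
rule (miRNA opposite to the pair) when wanted.

**Topology** (`network_centralities`, `select_hubs`,
`select_key_lncrnas`). The triplet network is undirected and simple,
matching how interactive network analyzers treat ceRNA graphs. Node
betweenness is normalised by $(n-1)(n-2)/2$ to land in $[0,1]$;
closeness follows the within-component convention
(reachable count / summed distances), so disconnected networks are
handled without special cases. Hubs are nodes with degree strictly
greater than 5. "High degree together with high betweenness" is
operationalised deterministically: within each dysregulation direction,
hub lncRNAs are ranked by degree with betweenness as tie-break (then id),
and the top 3 per direction are the key lncRNAs; an absolute betweenness
floor is available via `min_betweenness`.

**Enrichment** (`hypergeom_enrich`). Classic over-representation
analysis: upper-tail hypergeometric $p = P(X \ge k)$ with universe $N$,
term size $K$, query size $n$, hits $k$; Benjamini–Hochberg within each
namespace separately (GO branches and pathway collections are distinct
testing families); significance requires *both* raw and adjusted
$p < 0.05$. The background is the conservative choice of genes present
in both the annotation collection and the measured data.

**Regulatory layers** (`pathway_network`, `extract_axes`, `tf_network`).
The pathway layer restricts triplets to key lncRNAs and attaches each
partner mRNA to the significant terms that contain it; axes are the
resulting lncRNA→miRNA→mRNA chains with pathway and TF annotations.
TF→mRNA edges come from promoter binding-site count tables (window
recorded as provided, conventionally 1000 bp upstream / 100 bp
downstream); with no published count cutoff the default `min_sites = 1`
keeps every predicted pair, and TFs are ranked by out-degree with total
site count as tie-break.

## The synthetic study generator

`generate_bundle(sim_config(...))` produces every input of the chain with
a planted ground truth, so each filter can be tested against a known
answer without any external download.

The expression model is log-normal: log2 baseline uniform on $[5, 9]$,
multiplicative group effect equal to the planted fold change, i.i.d.
Gaussian log2 noise (`noise_sd`, default 0.25). Planted triplet members
draw fold-change magnitudes from the part of `fc_range` above the
refinement cutoff (so planting guarantees $|FC| > 2$), one hub lncRNA
receives an extreme fold change in the hundreds — re-annotated lncRNA
probes do show such values — and partner mRNAs are rescaled copies of
their lncRNA's profile with residual noise at one tenth of `noise_sd`,
making pairs exactly collinear at zero noise and gracefully degrading as
noise grows. Defaults: 60 lncRNAs, 80 mRNAs, 30 miRNAs, 3+3 samples, 12
planted triplets arranged as two 6-triplet hub lncRNAs (one up, one
down), miRNA evidence spread over 9 datasets.

Decoys are planted **per filter**, each engineered to fail exactly one
rule so unit tests can attribute a leak to a single stage: a
non-dysregulated partner pair; a pair with $|FC|$ between 1.5 and 2
(passes the screen, fails refinement); an anti-correlated pair; a pair
whose miRNA→mRNA edge scores exactly 80 (strictness check); a pair whose
miRNA→lncRNA edge scores below the lncRNA cutoff; DE genes with no
shared miRNA; and bulk low-score edges onto background genes. The bulk
lncRNA decoy edges are emitted at ≥ 19× the planted edge count with
scores in 50–150 against planted scores in 160–200, which pins the
default upper-decile cutoff safely between the two ranges. Evidence
corruption (`conflict_fraction`, `missing_db_fraction`) adds
opposite-direction calls in second datasets and database absences, never
touching planted miRNAs, and conflicted miRNAs additionally receive
high-score edges onto a planted pair — edges that only the catalogue
conflict rule can remove.

A single integer seed drives everything; identical configurations write
byte-identical files, and the generator restores the caller's RNG state.

What the generator does *not* emulate: probe-level microarray artifacts,
normalisation effects, correlated noise between unrelated genes,
sequence-level miRNA binding, and realistic score distributions of any
particular prediction tool. Passing the recovery tests therefore shows
the *logic* of the chain is right — that each filter rejects what it
should and retains what it should — not that the thresholds are optimal
for any real platform.

## Numerical choices and degenerate inputs

* All printed thresholds are strict inequalities (a score of exactly 80
  is rejected; degree exactly 5 is not a hub).
* Constant genes: $p = 1$, direction `ns`; perfectly separated
  zero-variance genes report the smallest positive double rather than 0
  so $p \in (0, 1]$ holds.
* $r = 1$ pairs: the $t$ transform guards the $1-r^2$ denominator with
  the machine epsilon, yielding a vanishing $p$ instead of a division by
  zero.
* Ties are broken lexicographically everywhere (triplet tables, rankings,
  top-term reports), making every output order-deterministic and
  row-order-invariant.
* Empty inputs flow through: empty evidence gives an empty catalogue,
  an empty triplet set gives an empty network and valid (empty) exports.

## Verification

The test suite checks each stage against an independent oracle computed
by a different route: betweenness and closeness against Floyd–Warshall
distances with explicit shortest-path counting (tolerance 1e-9, 50 random
graphs of up to 15 nodes); hypergeometric $p$ against direct
combinatorial summation (1e-12); Benjamini–Hochberg against the literal
step-up recipe; triplet assembly against exhaustive triple enumeration
(exact set equality); screen $p$-values against a hand-computed pooled
$t$ statistic and CDF call. Property tests cover label-swap antisymmetry
of fold changes, threshold monotonicity, order independence of
reconciliation and rankings, filter idempotence, and the degradation of
triplet recall as generator noise grows (20 seeds at three noise levels).
End-to-end, a noise-free bundle must be recovered with triplet precision
and recall exactly 1, and the screen's null type-I rate is checked at
$0.05 \pm 0.02$ over 5000 simulated null genes. These problem sizes keep
the whole suite under ten seconds while leaving every oracle exhaustive
at its scale.

## Known limitations

* The screen tests each gene independently; with $n = 3$ per group the
  t-test is fragile and the raw-p filter is permissive. The refinement,
  correlation and target filters carry the specificity burden, which is
  exactly the published workflow's logic — but treat single-gene calls
  with caution.
* Correlation at $n = 6$ pooled over groups conflates group effect and
  within-group co-variation; a pair of same-direction DE genes can clear
  $r > 0.99$ on group effect alone. The shared-miRNA requirement is what
  keeps such pairs out of triplets.
* The lncRNA score cutoff is distribution-relative by default; when two
  prediction sources with different scales are mixed in one table, pass
  an explicit `lncrna_score` instead.
* Literature miRNA evidence is treated as binary up/down per dataset;
  within-dataset inconsistencies are not modelled (they should be
  resolved before building the evidence table).
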
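---
title: "Methods: gene-family histories for tardigrade heat-soluble proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family histories for tardigrade heat-soluble proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famhist)
```

`famhist` implements the decision rules used to reconstruct duplication and
loss histories of tardigrade desiccation-tolerance protein families (CAHS,
MAHS, SAHS, EtAHS alpha/beta, MRE11) at the genus level. This vignette is
the package's own account of each method, the parameters that matter, the
choices made where the design was genuinely open, and what the synthetic
generator does and does not establish about real data.

## Working at the genus level

All inference operates on genera, not species or samples. Leaf names follow
the pipe convention `Genus|sample|localid` (`leaf_genus()` interprets it; a
TSV sidecar can override metadata). The motivation is practical: sampling in
this group is sparse and uneven, and sample-level conclusions would mostly
reflect assembly quality. The consequence is that a clade of sequences from
*different samples of one genus* still counts as genus-exclusive.

## Homology screening

Screening operates on precomputed BLAST tabular (outfmt 6) files — running
the searches is out of scope. Three rules, in order:

1. **Primary screen** — keep queries with any hit against known family
   members at `e_primary` (default `1e-10`) or better.
2. **Reciprocal confirmation** — the *best* hit against an nr-style database
   (lowest e-value; ties by bitscore, then input order, and the tie-break is
   deterministic) must be annotated with the target family and reach
   `e_reciprocal`. A candidate with no hits at all gets the distinct reason
   `no_reciprocal_hit` rather than being conflated with an out-of-family
   best hit.
3. **Divergent screen** — for intrinsically disordered families, ordinary
   similarity search fails; the sensitivity rule keeps sequences strictly
   longer than 80 aa whose best annotated hit is not another family and
   whose e-value qualifies.

Two threshold ambiguities in the source protocol are resolved in config
rather than silently. The printed threshold "10e−10" literally equals
`1e-9`; the default here is the conventional `1e-10` and the literal value
is one `screen_config()` argument away. Likewise, the sensitivity screen's
"e-values >1" is read as `<= 1` — retaining only hits *worse* than 1 would
contradict the point of a sensitivity search — but
`literal_divergent_gt = TRUE` restores the literal reading.

## RCFV compositional screening

With per-taxon gap-excluded state frequencies $f_{s,t}$ and dataset means
$\mu_s$ over $n$ taxa:

$$\mathrm{tRCFV}_t = \frac{1}{n}\sum_s |f_{s,t} - \mu_s|, \qquad
  \mathrm{csRCFV}_s = \frac{1}{n}\sum_t |f_{s,t} - \mu_s|, \qquad
  \mathrm{RCFV} = \sum_t \mathrm{tRCFV}_t = \sum_s \mathrm{csRCFV}_s.$$

Frequency deviations shrink like $1/\sqrt{m}$ with alignment length, so the
default normalization is $\mathrm{ntRCFV}_t = \mathrm{tRCFV}_t\sqrt{m}$ with
the dataset value $\mathrm{nRCFV}$ the mean of the per-taxon scores. The
normalization is a pluggable function, and deliberately so: the screen
compares each taxon's score to the dataset mean in units of the population
standard deviation of the same scores, so *any* common positive scaling
yields the identical flag set (a tested invariant). Matching a particular
external tool's constant is therefore unnecessary for screening outcomes and
is a non-goal.

Flagging is one-sided — `ntRCFV > nRCFV + k·SD` with `k_sd = 3` — because
unusually *low* heterogeneity is not evidence of anything problematic. The
SD is taken over the per-taxon score distribution in population form. One
structural fact is worth knowing: the maximum possible deviation above the
mean in population-SD units for $n$ values is $\sqrt{n-1}$, so a strict
3-SD screen can only ever fire with at least 11 taxa, and a 10-taxon dataset
can reach exactly 3.0 SD but never exceed it. Calibration tests therefore
use the packaged 13-genus tree ($\sqrt{12} \approx 3.46$ headroom). Gaps and
`X` are excluded from counts; quartiles use Tukey hinges (median counted in
both halves), reported because third-quartile membership is a useful
descriptive bin below the significance threshold.

## Support collapse and rooting

Edges whose child support is **strictly below** 0.7 posterior probability /
70 ultrafast bootstrap are contracted to polytomies; boundary values
survive, and unlabelled nodes (e.g. a root split) are never collapsed —
absence of evidence is not low support. The support scale is auto-detected
on read (all values ≤ 1 is probability; all ≥ 1 is percent; a mix is an
error requiring an explicit declaration). Collapse is idempotent and
leaf-preserving (tested properties).

Rooting comes in two forms. With an outgroup, the root goes on the edge
separating a (checked) monophyletic outgroup, supports treated as edge
labels so they stay with their bipartition. Without one — the common case
for tardigrade-specific families — every edge of the unrooted tree is tried
and the rootings minimizing the reconciliation duplication count are all
returned. Ties are returned in full rather than silently broken; the
pipeline logs which one it proceeds with.

## Reconciliation and duplication/loss calls

`lca_reconcile()` maps each gene-tree node to the last common ancestor of
its descendant genera on the species tree. A binary node is a duplication
iff its mapping equals a child's mapping; losses are counted per gene edge
as `dist(M(parent), M(child)) − 1 + [parent is duplication]` and attributed
to the species branch where the unobserved lineage vanished. Duplications
mapping to a genus tip are *independent*; internal ones are *shared*. The
test suite checks these counts against an independent dynamic program that
searches the full space of valid reconciliation maps.

Polytomies produced by support collapse are treated as *soft* — uncertainty,
not simultaneous divergence. Each is resolved to the binary refinement
minimizing duplications (then losses): exact search over all rooted binary
arrangements up to degree 6 (945 shapes), and above that a greedy pairing
that repeatedly joins the pair with the most recent non-duplicating joint
mapping, with a warning. Degree 6 keeps the exact search inexpensive while
covering every polytomy the collapse stage realistically produces on
genus-level trees.

The genus-exclusive rule is separate from reconciliation and matches how
practitioners read these trees: each maximal clade whose leaves all belong
to one genus contributes `size − 1` independent duplications. Presence-based
loss calls are also kept separate: a genus absent from a homolog group is a
loss only if its best assembly completeness reaches the guard (default 0.8 —
the protocol names no number, only a precedent of refusing loss calls for a
genus with poor completeness; 0.8 is a conventional "good assembly" line and
is configurable). Below the guard the absence is reported as
`unknown_low_completeness`, never as evidence.

The >98%-identity merge guards against assembly artifacts inflating
duplication counts: for samples under 40× coverage, same-family sequences
are clustered by single linkage at pairwise global identity strictly above
0.98 (Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5) and each
cluster collapses to its longest member (ties lexicographic). Identity is
computed on amino acids; the threshold is configurable for nucleotide-based
workflows. Single linkage is the conservative choice here: it merges the
most, which is the right bias when the goal is *not to overcall*
duplications.

Habitat mapping uses exact small parsimony (unit-cost Sankoff, valid for
multifurcations). `count_transitions()` additionally minimizes the count of
one named transition among all minimum-change assignments, optionally with
the root constrained — the marine-root constraint reflects outgroup
knowledge (other ecdysozoan phyla are ancestrally marine) that the tips
alone cannot supply; unconstrained parsimony on the packaged cladogram
prefers a limnoterrestrial root with one fewer change, which is why the
constraint is exposed as an explicit argument rather than baked in.

## Consensus motifs

The consensus caller is deterministic: per column, over non-gap residues
where coverage ≥ 0.8 — a unanimous residue is fixed; otherwise up to 4
distinct residues jointly covering the column become an alternative set
ordered by descending frequency (ties alphabetical); otherwise `X`. The
external conservation-scoring web tool it replaces is not reproducible
bit-for-bit; the caller is a documented stand-in and the downstream phrase
extraction accepts any consensus entries, so the caller is swappable.

The longest uninterrupted phrase is the longest window with no two adjacent
`X` entries, where a leading/trailing `X` is disallowed if it pairs with an
`X` just outside the window; ties break leftmost; an all-`X` consensus
degenerates (with a message) to the first column. Reported coordinates are
1-based and inclusive, both in alignment columns and on a named reference
row (reference gaps are skipped; a phrase starting on a gap maps to the next
residue). Percentages are rounded for display only; exact fractions stay in
the data.

## The synthetic generator

`simulate_gene_tree()` runs a per-copy birth–death process along the species
tree: duplications split a lineage, losses kill it, survivors become leaves;
every event is recorded with its branch and time, so inference can be scored
against truth. Unit branch lengths are assumed where the cladogram has none,
and rates are per unit length. Default rates (λ = 0.1, μ = 0.05 per unit
branch) give histories of a few events per family on the 24-branch default
tree — the regime the real families occupy — and the calibration tests that
need loss-free histories set μ = 0 explicitly. `distort_tree()` degrades a
chosen fraction of internal-edge supports below the collapse threshold
(optionally with NNI moves on those edges), emulating poorly resolved
consensus trees.

`simulate_alignment()` is a star process: a uniform-composition root
sequence, each taxon independently resampling each site with probability 0.5
from its own target composition; biased taxa draw from a mixture putting
weight `bias_strength` on a four-state preferred subset {K, E, Q, P}. The
gene-tree argument supplies the taxon set only — topology does not shape
site patterns. This is sufficient for what the generator exists to do
(exercise the compositional screen with a controllable effect size) and is
deliberately not a realistic evolutionary model: no rate heterogeneity, no
indels, no phylogenetic covariance. Consequently, passing tests demonstrate
that the screen detects strong lineage-specific compositional shifts at the
stated rates under i.i.d. sites; they do not establish its behaviour under
correlated evolution or alignment error on real data.

The packaged species tree is a 13-genus cladogram with marine / freshwater /
limnoterrestrial states per genus; users can substitute any rooted genus
tree with `read_species_tree()`.

## Problem sizes and numerical choices

The test suite verifies the reconciliation against the mapping-space oracle
on 500 random instances of up to 8 leaves over 3–5 genera; min-duplication
rooting against per-edge enumeration on trees up to 12 leaves; phrase
extraction against an $O(m^2)$ window scan on 200 random consensi; Fitch
counts against exhaustive assignment enumeration up to 8 tips and 3 states;
RCFV marginal-sum conservation at `1e-9` relative tolerance; and the two
calibration rates (duplication recovery, flag power) on 200 simulated
replicates each. These sizes were chosen so that the oracles stay exact and
exhaustive; the implementations themselves have no such limits.

Determinism is a contract throughout: a seed fixes every simulated artifact
byte-for-byte, screening tie-breaks are by bitscore then input order, merge
representatives by length then name, alternative sets by frequency then
alphabet, and rooting ties are returned in full.

## Known limitations

* Reconciliation assumes the genus cladogram is correct and binary; losses
  are attributed assuming a binary species tree.
* The greedy refinement above polytomy degree 6 is a heuristic (warned
  about); exact behaviour is only guaranteed at degree ≤ 6.
* Presence-based loss calls depend on one completeness number per genus; a
  family-specific detectability model is out of scope.
* The consensus caller is a stand-in with documented thresholds, not a
  reimplementation of any external conservation scorer.
* Identity-based merging uses global alignment; families with large length
  variation between true paralogs may need a different identity definition.
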
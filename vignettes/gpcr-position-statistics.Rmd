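---
title: "Position statistics on generic-numbered GPCR alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position statistics on generic-numbered GPCR alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcralign)
```

# The setting

G protein-coupled receptors share a seven-transmembrane-helix fold, and
a structure-informed multiple sequence alignment of the TM helices plus
the short intracellular helix 8 lets positions be compared across
receptors through generic Ballesteros–Weinstein labels: `helix.index`,
with the most conserved class A residue of each helix anchored at index
50. `gpcralign` takes such an alignment as given — an aligned FASTA, a
column-to-label map, and per-receptor metadata — and computes
conservation, covariation and association statistics over user-selected
subsets. It does not build alignments; the alignment (and its gap
placement) is an input and every statistic is conditional on it.

All selections run over one universe object (`gpcr_alignment`):
sequences over the 20 standard residues plus `'-'`, a position map that
labels every column exactly once, and metadata carrying the receptor
class (A/B/C/F), a taxonomic group, an olfactory flag and slash-joined
classification paths per scheme (e.g. `fredriksson = "alpha/amine"`).
Ambiguity codes (B, J, Z, X, U, O) are rejected at load rather than
recoded, so every denominator below is unambiguous. Olfactory receptors
are excluded by default because they would otherwise dominate class A
statistics; taxonomic sets are cumulative (Human ⊂ Mammals ⊂
Vertebrates ⊂ Eukaryotes ⊂ All), which makes selection sizes monotone
along that chain — a property the tests exercise.

# The gap policy, stated once

Every statistic uses the same denominator convention: a sequence
contributes to a query only if it is gap-free at *all* queried columns
(list-wise deletion over the queried position set). A motif match
against a gapped tuple is *undetermined*, not false, and the sequence
drops out of both numerator and denominator. For pair statistics the
marginals are recomputed on the jointly gap-free subset, which keeps
observed and expected counts summing to the same N. The alternative —
whole-column marginals — would make OMES's expected counts sum to a
different total than the observed ones whenever gap patterns differ
between the two columns.

# Conservation

The entropy of a position (or an ordered tuple of positions, treated as
a single joint symbol — no independence is assumed) is

$$H(i) = -\sum_x p_x(i)\,\log_{b} p_x(i), \qquad b = 20^{\,n},$$

with $n$ the number of queried positions and $p_x(i)$ the gap-free
frequency of residue (tuple) $x$. The base $20^n$ scales $H$ into
$[0,1]$: 0 for a fully conserved position, 1 only for a uniform
distribution over the full $20^n$ alphabet. Internally the natural log
with the ratio $\ln/\,(n\ln 20)$ is used, and $0\log 0$ is defined as 0.
Percent occurrence of a motif is $100\,m/N$ over the same denominator,
kept at full precision internally and printed to one decimal.

Motifs use seven one-character physicochemical wildcards (`X @ ~ + - *
^`, sizes 20/4/6/3/2/5/12). The classes are taken verbatim as
conventions of the field; they overlap (F is both aromatic and apolar)
and no attempt is made to "correct" that. `~` excludes Gly and Met by
convention. The `-` character is the negative-charge wildcard inside a
motif string and a gap inside a sequence; the contexts never mix
because motif strings cannot contain gaps.

The consensus residue of a column is the modal gap-free residue; ties
are broken lexicographically by one-letter code and flagged, and an
all-gap column gets consensus `'-'` with frequency 0. Tie-breaking by
code rather than, say, chemical similarity is arbitrary but
deterministic, which matters more here: snake-plot renders must be
byte-stable.

# Covariation

For two positions (or tuples) with $N$ jointly gap-free sequences:

$$\mathrm{OMES}(i,j) = \frac{1}{N}\sum_{x,y}\bigl(N^{obs}_{x,y} -
N^{exp}_{x,y}\bigr)^2, \qquad N^{exp}_{x,y} = N\,p_x(i)\,p_y(j),$$

$$\mathrm{MI}(i,j) = \sum_{x,y} p_{x,y}\,
\ln\frac{p_{x,y}}{p_x\,p_y} \;\;\text{(nats)},$$

$$\mathrm{MIp}(i,j) = \mathrm{MI}(i,j) -
\frac{\mathrm{MI}(i,\cdot)\,\mathrm{MI}(\cdot,j)}{\overline{\mathrm{MI}}},$$

the average-product correction (APC), where $\mathrm{MI}(i,\cdot)$ is
the mean MI of $i$ against the other background columns and
$\overline{\mathrm{MI}}$ the mean over all unordered background pairs.
The APC removes the shared-entropy/phylogenetic component: a uniform
background cancels exactly, and MIp can legitimately be negative. When
a target is itself a multi-position tuple, $\mathrm{MI}(i,\cdot)$ is
the mean of MI(tuple, c) over background columns outside the tuple;
for single columns this reduces to the standard definition.

Significance is assessed empirically: the same score is computed for
**all unordered pairs of single mapped columns** of the selection (the
only finite, canonical background; cached on the alignment object since
it is $O(L^2)$), and the target's Z-score is its deviation from that
background's mean in units of the *sample* standard deviation
(`stats::sd`; the choice between sample and population SD is
immaterial for the backgrounds of hundreds to thousands of pairs this
is used with, and the sample SD is the conservative one). The p-value
is the one-sided upper tail of the standard normal — high scores mean
covariation. Degenerate backgrounds (fewer than 3 pairs, zero SD, zero
mean MI for the APC) are errors, not silent zeros.

# Association

Two motifs at two position sets define a 2×2 presence/absence table
(a: both present, b: first only, c: second only, d: both absent) over
the jointly gap-free sequences. The association is summarized by the
odds ratio $ad/bc$ with the Woolf (log) 95% interval
$\exp(\ln OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. The Woolf method was
chosen among the standard 2×2 interval constructions because it exactly
reproduces the reference worked example this package tests against
(a table (14, 3, 1, 4) of 22 sequences giving OR 18.67, CI 1.50–232.3);
it is also the construction whose width shrinks predictably as counts
scale, which the tests check by duplicating tables. If any cell is
zero, the Haldane–Anscombe correction (+0.5 to all four cells) is
applied and flagged; a table with an entirely zero margin has no
defined association and is reported as such — per sibling/child
category as a status marker, and as an error for the primary selection.

# Level comparisons

Classification schemes are encoded as slash paths, and selection is by
whole-component path prefix, which realizes any scheme depth without
hard-coding one. "Same level" of a node means its siblings: the other
branches under the node's parent, or the other receptor classes when
the node is a class. "Sub level" means the node's children. Each
category is analyzed by an independent selection-plus-query, so the
reported numbers are exactly what the corresponding direct query would
return — a cross-check the tests perform — and when children partition
the parent, their match counts add up to the parent's.

# Snake plots

The plot is one circle per mapped generic position: TM helices as
vertical zigzag columns (odd helices drawn top-down, even bottom-up, as
the chain snakes through the membrane), helix 8 as a horizontal
intracellular row, loops as straight connectors (the alignment covers
TM + helix 8 only, so there are no loop residues to draw). Two
conservation channels: the letter's gray level is the displayed
residue's frequency in a reference class set, the outline's blue level
its frequency in the selection. Both gradients are linear over 8
discrete bins, frequency 0 lightest and 1 darkest — monotonicity is a
tested invariant; the bin count and exact colors are conventions, not
claims. In single-receptor mode, positions where the receptor deviates
from the selection consensus are filled green and gapped positions are
omitted. Geometry constants are fixed so renders are byte-stable.

# The synthetic generator

`fixture_spec()`/`generate_fixture()` produce a fully validated
alignment set from: per-category column profiles (named probability
vectors over the 20 residues), coupled column pairs, per-column gap
rates, taxon compositions (exact counts or probabilities), scheme
paths and a seed. Coupling is generative: with probability equal to the
coupling, the residue at column j is replaced by a *fixed permutation*
(cyclic shift by one on the sorted alphabet) of column i's residue.
The fixed permutation makes closed-form targets available — at coupling
1 the joint table is a permutation matrix, so MI equals the source
column's entropy and the empirical table has no off-partner pairs.

`default_fixture_spec()` fixes the study conditions used throughout the
examples and tests: 66 mapped positions on helices 1–8 with conserved
h.50 anchors (N1.50, D2.50, R3.50, W4.50, P5.50, P6.50, P7.50, each at
weight 0.95), 215 receptors over four classes with Fredriksson-style
paths, an olfactory class A branch, a class C set of 111 sequences of
which 22 are human — deliberately the small-count regime where
odds-ratio intervals become very wide — and the pair (3.40, 6.44)
coupled at 0.9 within class C, with a 3.40 profile dominated by
aromatics (Y 0.50, F 0.27). Non-anchor, non-overridden columns get a
random peaked profile (dominant residue weight 0.45–0.85) drawn from
the same seed. Gap rates are 0.02 at a few helix-edge columns and 0
elsewhere.

What the generator emulates: class- and branch-structured composition,
conserved anchors, a tunable coevolution signal, small-sample strata,
missing data at helix edges. What it does not emulate: phylogenetic
correlation between sequences (rows are i.i.d. given the category),
realistic substitution-matrix structure, alignment error, or
indel-driven gap blocks. Consequently, passing the recovery tests shows
the estimators detect a generative coupling signal against an
independent background; it does not show robustness to shared ancestry
— the main confounder MIp's APC only partially addresses on real data
— nor to misalignment.

# Problem sizes and numerical choices

The test suite checks the scores against independent brute-force
re-implementations (plain loops sharing no code with the package) on
100 random alignments of 10–50 sequences × 5–10 columns at relative
tolerance 1e-10, and signal recovery on 50 replicates of 200 sequences
× 8 columns with one pair coupled at 0.9 — sizes at which every run
completes in seconds while the empirical recovery rate (the coupled
pair attaining the top OMES Z-score) is stably at or near 100%.
Internally, columns are 1-based R indices; the on-disk position-map TSV
is 0-based, and since users address positions only by generic labels,
no off-by-one surface exists. All randomness flows through explicit
seeds; the same spec and seed reproduce byte-identical files.

# Known limitations

- No sequence weighting or phylogenetic correction: closely related
  sequences count fully, in covariation and association alike.
- The normal approximation behind the Z-score p-values is a ranking
  device; background score distributions are skewed, so p-values should
  be read comparatively, not as calibrated error rates.
- Odds ratios from tables with counts near zero are dominated by the
  Haldane–Anscombe correction; the corrected flag should be surfaced to
  readers.
- Range queries expand purely by the position map: columns where many
  sequences are gapped are not treated specially beyond the per-query
  gap policy.
- The snake plot draws mapped positions only; N-/C-termini and loop
  residues are outside the alignment and outside its scope.
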
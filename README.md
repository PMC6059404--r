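# gpcralign

Position-wise sequence statistics for G protein-coupled receptors
(GPCRs) over a structure-informed multiple sequence alignment of the
seven transmembrane (TM) helices and helix 8, indexed by
Ballesteros–Weinstein generic position numbers (`helix.index`, e.g.
`3.50`). The package is aimed at molecular pharmacologists and
structural biologists who want to ask, for a chosen receptor class,
taxonomic set and classification branch: how conserved is a position or
motif, do two positions covary, and is the presence of one motif
associated with another — for example, across the `3.40 / 5.50 / 6.44`
"transmission switch" triad that couples ligand binding to receptor
activation.

## What it computes

For a selected group of receptors (class A/B/C/F, cumulative taxonomic
sets Human ⊂ Mammals ⊂ Vertebrates ⊂ Eukaryotes ⊂ All, hierarchical
classification-scheme paths, olfactory receptors excluded by default):

- **Conservation.** Residue/motif percent occurrence at one or more
  generic positions (with one-character physicochemical wildcards:
  `X` any, `@` aromatic W/Y/F/H, `~` apolar I/L/V/A/F/P, `+` R/H/K,
  `-` D/E, `*` charged, `^` polar), and Shannon entropy scaled to
  [0, 1]:

  H(i) = −Σₓ pₓ(i) log_b pₓ(i), with b = 20ⁿ for n queried positions.

- **Covariation.** For positions i, j with N jointly gap-free
  sequences:

  OMES(i,j) = (1/N) Σₓ,ᵧ (N obs(x,y) − N exp(x,y))²,
  MI(i,j) = Σₓ,ᵧ p(x,y) ln [p(x,y) / (p(x) p(y))],

  plus the average-product-corrected MIp(i,j) = MI(i,j) −
  MI(i,·)·MI(·,j)/MI̅, with Z-scores and one-sided p-values against
  the background of all unordered column pairs of the selection.

- **Association.** A 2×2 presence/absence table of two motifs at two
  position sets, its odds ratio OR = ad/bc with the Woolf 95%
  confidence interval exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d)), and the
  Haldane–Anscombe +0.5 correction when a cell is zero; results are
  also reported per sibling and child classification category.

- **Snake plots.** SVG diagrams, one circle per generic position, with
  conservation encoded in a gray letter gradient (class-wide frequency)
  and a blue outline gradient (selection frequency); in single-receptor
  mode, residues that deviate from the group consensus are green.

- **Synthetic data.** A seeded generator of GPCR-like alignment sets
  (column profiles, coupled column pairs, gap rates, classification
  tree) so that every analysis is testable without any download.

## Worked example

```r
library(gpcralign)

aln  <- default_fixture(seed = 42)            # synthetic GPCR-like universe
cset <- select_receptors(aln, gpcr_class = "C", taxon = "Human")

percent_occurrence(cset, "3.40", "@")
#> @ at 3.40: 77.3% (17/22 gap-free sequences)

shannon_entropy(cset, "3.40")
#> Shannon entropy H = 0.4264 (base 20^1)

covary(select_receptors(aln, gpcr_class = "C", taxon = "All"),
       "3.40", "6.44")
#> Covariation 3.40 vs 6.44 (N = 111 gap-free pairs)
#>   OMES = 15.3007  (Z = 3.65, p = 0.000133)
#>   MI   = 1.1211 nats
#>   MIp  = 1.0719  (Z = 31.34, p = 6.66e-216)

odds_ratio(contingency_table(14, 3, 1, 4))
#> odds ratio 18.67 (95% CI 1.50 to 232.3)
```

Reading the output: 77.3% of the 22 human class C receptors in the
synthetic set carry an aromatic residue at 3.40, with moderate
variability (H = 0.43). The coupled pair built into the class C fixture
at (3.40, 6.44) stands out from the all-pairs background on both OMES
and MIp (Z ≫ 2, upper-tail p < 0.001). The odds-ratio line is the 2×2
table (a=14, b=3, c=1, d=4): a strong but — with only 22 sequences —
very imprecise association.

The same analyses are available from the shell via the installed
`exec/gpcralign` script:

```sh
gpcralign fixtures --seed 42 --outdir data/
gpcralign conserve --fasta data/fixture.fasta \
    --posmap data/fixture_positions.tsv --metadata data/fixture_metadata.tsv \
    --positions 3.40 --motif "@" --class C --taxon Human
```

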
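---
title: "Genome-based genus and species demarcation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based genus and species demarcation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Prokaryotic taxa are increasingly demarcated from whole-genome evidence
rather than single-marker identity. For anaerobic, metal-reducing soil
bacteria of the kind this package was built around (rod-shaped,
red-pigmented strains of the *Geobacteraceae* and their relatives), 16S
rRNA identity is known to under-resolve genera: intra- and inter-genus 16S
identity bands overlap, so the classic 94.5–95% genus and 98.65% species
cut-offs misplace taxa. The remedy in current practice is to combine
several whole-genome similarity indices with tree-based evidence, and to
demand that the two agree before a name is changed.

`genotax` implements that workflow end to end:

1. **Similarity indices.** Fragment-based average nucleotide identity
   (ANIb), average amino-acid identity over reciprocal best hits (AAI),
   percentage of conserved proteins (POCP), and pairwise 16S identity.
2. **Demarcation.** Labelled similarity matrices; "parting-line" threshold
   inference between intra- and inter-genus pair values; average-linkage
   clustering cut at the genus threshold; threshold-based classification
   of query genomes (genus: AAI 70% primary with POCP 65% and ANI 74%
   corroborating; species: ANI 95% *and* AAI 95%; 16S advisory only).
3. **Phylogeny.** Kimura two-parameter distances, neighbor-joining trees,
   rooting-free per-genus monophyly via tree bipartitions, MLSA marker
   extraction and concatenation (fusA, gyrB, recA, rpoB).
4. **Consensus.** A genome keeps its genus only when its similarity
   cluster coincides with its nominal genus-mates *and* the genus is
   monophyletic; singleton clusters on their own branches become novel-genus
   proposals; coherent genera nested inside another family's clade become
   transfer proposals; everything else is surfaced as a conflict, never
   silently resolved.

## Index definitions and filters

* **ANIb** — the query genome is cut into consecutive 1,020 bp fragments
  (a trailing fragment is kept when ≥ 100 bp). Each fragment is searched
  against the subject genome on both strands; fragments whose best hit
  reaches ≥ 30% identity over ≥ 70% of the fragment are retained, and the
  directional ANI is their mean identity. The reported value is the mean
  of the two directions. These are the fragment conventions of the
  BLAST-based ANI lineage of tools.
* **AAI** — best hits are computed in both directions between proteomes; a
  reciprocal best-hit pair is kept when each protein is the other's best
  hit and the alignment reaches ≥ 30% identity over ≥ 70% of the shorter
  protein. AAI is the mean identity over those pairs (averaging the two
  directional identities of each pair).
* **POCP** — `100 * (C1 + C2) / (T1 + T2)`, with `C` the number of
  proteins of one proteome having any hit in the other with E-value
  < 1e-5, identity > 40% and an aligned region > 50% of the query length,
  and `T` the proteome sizes.
* **16S identity** — global (Needleman–Wunsch, affine gaps) alignment;
  identity over aligned columns after discarding terminal gap columns.
  Sequences shorter than 1,200 nt trigger a warning but are processed.

An index with no qualifying units (no retained fragment, no reciprocal
best hit) is **undefined and reported as `NA`**, never as 0 — a bad input
must not masquerade as evidence of novelty. A POCP of 0 is, by contrast, a
legitimate value.

### Search backends

The hit generation behind ANIb/AAI/POCP has two interchangeable backends.
The default shells out to the BLAST+ suite (`makeblastdb`, `blastn`,
`blastp`), the same engine behind the web services practitioners use, and
the only realistic option for fragment-vs-genome searches at megabase
scale. A pure-R backend (`backend = "alignment"`) computes full
Smith–Waterman dynamic programming via Biostrings with E-values from
Karlin–Altschul statistics (`E = K m n e^{-λS}`, with published gapped
parameters: λ = 0.267, K = 0.041 for BLOSUM62/affine(11,1); λ = 1.28,
K = 0.46 for +1/−2, affine(5,2)). The DP backend is the reference
implementation: the unit tests drive it against hand-enumerated oracles,
and the BLAST backend is expected to agree within alignment-dialect
differences.

## Threshold inference ("parting lines")

Given a similarity matrix and genus labels, off-diagonal pair values are
split into intra- and inter-genus sets. If the two are separable the
threshold is the midpoint of the gap and there are no violations;
otherwise the reported threshold is the observed value minimizing the
number of misclassified pairs (pairs at or above the threshold count as
same-genus), with ties resolved toward the lower threshold and the
violation count reported. The midpoint/minimum-violation rule is this
package's formalization of reading a parting line off the intra/inter
distributions; published analyses typically do this by inspection, which
is why an inferred threshold should be quoted together with its violation
count.

Clustering uses average linkage (UPGMA) on dissimilarity `100 − s`, cut at
`100 − threshold`. Average linkage matches the dendrogram style of the
bacterial-taxonomy R tooling this mirrors; the cut produces disjoint
clusters, and cutting at a higher similarity always refines the partition
obtained at a lower one.

## Classification logic

AAI is the primary genus criterion; POCP and ANI corroborate. This
ordering reflects the common situation (observed in the order this package
was designed around) where POCP splits an otherwise coherent genus while
AAI and the phylogenomic tree keep it together: amino-acid identity is the
more stable rank signal, and a 70% AAI cut-off is the recommended genus
boundary. When the available verdicts disagree, the call is `conflict`
with every verdict listed — discordant evidence is reported, not
adjudicated. The species call requires ANI ≥ 95 *and* AAI ≥ 95 against the
same reference; 95 is the conservative low end of the commonly printed
95–96% ANI band, so borderline strains lean toward novelty. 16S identity
is attached as advisory evidence only and never decides a call.

## The synthetic generator

Because the real inputs are multi-megabase NCBI assemblies, every stage is
exercised against a seeded synthetic collection with planted truth. The
generator builds an ancestor genome of protein-coding genes (ATG + body
codons + stop) laid end-to-end with intergenic filler, then evolves it
down a two-level tree: inter-genus branches at substitution probability
`p_inter`, intra-genus branches at `p_intra`, transitions:transversions
2:1 (so K2P is the matching distance), gene loss only on inter-genus
branches, and a 16S-like marker at one tenth of the genomic rate (a slow
marker, qualitatively reproducing 16S under-resolution). Substitutions
that would create an in-frame stop or destroy a start codon are reverted —
a minimal stand-in for purifying selection that keeps proteomes
translatable. Because the three stop codons are A/T-rich, body-codon
sampling recalibrates its base bias so the realized G+C hits the target.

Default study conditions, chosen once: 3 genera × 3 species, 200 kb
single-contig genomes, 200 genes of mean length 250 aa (≈ 75% coding),
G+C 60% (the range of the soil taxa motivating the package), `p_intra` =
0.02, `p_inter` = 0.10, gene loss 0.15 per inter-genus branch, 16S length
1,500 nt. These sizes keep a full matrix build to minutes on one CPU while
leaving every closed-form expectation testable:

* sibling ANI ≈ `100 (1 − p_intra)²` ≈ 96.0;
* inter-genus POCP ≈ `100 (1 − loss)` = 85 under saturated detection;
* sibling AAI ≈ 91, inter-genus AAI in the low 60s, so the planted AAI gap is
  wide and the parting line is separable with zero violations.

Held-out query tips are drawn either from an existing species tip at
`p = 0.005` (conspecific; within-species strain divergence, ANI ≈ 99) or
from a genus ancestor at `p_intra` (congeneric novel species, ANI ≈ 96
but AAI ≈ 91 < 95, hence `novel_species`).

**What the generator does not emulate:** codon usage and amino-acid
composition of real proteomes, rate heterogeneity across sites, indels,
rearrangements, HGT and paralogy. Consequences worth knowing: with
neutral i.i.d. substitutions, amino-acid divergence per unit of nucleotide
divergence is much steeper than in real purifying-selected genomes, so the
planted inter-genus ANI (~78%) sits *above* the 69–74% band real congeneric
pairs of this order show at comparable AAI separation. The simulation
therefore validates the machinery (filters, RBH logic, threshold
inference, cluster/tree consensus) and the closed-form expectations — it
does not calibrate real-data thresholds, which come from the published
cut-offs instead.

## Numerical and design choices

* **G+C** excludes ambiguous bases from numerator and denominator
  (insensitive to N padding); `size_bp` counts all bases. Published table
  values computed under an unknown N convention may differ by ±0.1.
* **Coordinates** are 0-based half-open internally, 1-based inclusive in
  all reports.
* **Identity denominators**: global mode uses aligned columns excluding
  terminal gaps; local mode uses alignment length. Both conventions are in
  circulation for 16S services, which is why reproducing a published 16S
  percentage can differ by ±0.2–0.3.
* **Tie-breaks** are fixed everywhere so outputs are bit-reproducible:
  best hits by score then lexicographic id; `hclust`'s deterministic
  merge order; NJ via `ape::nj` with negative branch estimates clamped
  to 0 (count flagged on the tree).
* **Monophyly on unrooted trees** is decided by bipartitions, so verdicts
  are invariant under re-rooting; a family-transfer proposal additionally
  requires that (other family ∪ genus) forms a clade while (own family −
  genus) does — identifiable only when a third lineage is present, which
  mirrors how such transfers are argued from real trees.
* **ORF calling** (six frames, longest ORF per stop segment, bacterial
  table 11) is a deliberate stand-in so synthetic genomes are
  self-contained; real analyses should supply annotator proteomes.
* **Percentages** are written with one decimal in TSV reports (matching
  the precision such tables are published at); JSON keeps full precision.

## Problem sizes used by the test-suite and acceptance script

Unit tests run toy constructions through the pure-R DP backend; the
simulation-recovery checks and `scripts/acceptance.R` run the default
3 × 3 × 200 kb conditions through the BLAST backend (a full AAI matrix
over 9 genomes plus two held-out classifications), sizes chosen so a
complete run stays in the minutes range on a single CPU. The
accession-gated reproduction checks (genome statistics and index maxima
of the deposited assemblies) run only when the corresponding NCBI FASTA
files are placed under `data-raw/accessions/`; they are not shipped.

## Known limitations

* The BLAST backend requires the BLAST+ executables on `PATH`; the DP
  backend is quadratic and intended for small inputs and tests.
* Threshold inference with very few genera (several singleton genera, few
  intra-genus pairs) is statistically fragile — quote `n_violations` and
  the pair counts, not just the threshold.
* `consensus_reassignment` names conflicts rather than resolving multi-way
  disagreements (e.g. MLSA and phylogenomic trees placing a species
  differently); resolution is left to the investigator.
* No bootstrap support, no ML/parsimony trees: externally built trees are
  consumed as newick.
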
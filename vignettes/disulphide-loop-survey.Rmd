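---
title: "Surveying short disulphide-bonded protein loops"
author: "dsloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying short disulphide-bonded protein loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsloop)
```

## The objects of study

A short disulphide-bonded loop is a protein segment of roughly four to
eleven residues whose two terminal cysteines form an S--S bond, pinning the
interior residues into a ring on the protein surface. Because the bond
constrains the interior conformation largely independently of the rest of
the protein, such loops are candidate templates for cyclic peptides that
retain the parent protein's binding activity -- for instance at
protein--protein interfaces, where a loop that contributes most of the
interface is a natural self-inhibitory peptide candidate. `dsloop`
implements the three computational stages of such a survey -- structural,
evolutionary and host--virus mimicry -- together with a synthetic-data
module that generates inputs with known planted signal so that each stage
can be validated end to end without external databases.

## Structure survey

### Loop detection

`detectDisulphideLoops()` tests every same-chain cysteine pair. A pair is
a disulphide-bonded loop when

* the S$\gamma$--S$\gamma$ distance lies in the bond window, default
  $[1.6, 2.5]$ Å around the canonical $\approx 2.05$ Å bond length. The
  window is deliberately generous: crystallographic coordinate error moves
  observed S--S distances by several tenths of an Ångström;
* the interior length $j - i - 1$ lies in the configured range, default
  2--9 in structure mode, with a maximum total span of 11 residues. Two
  defensible definitions circulate ("2--9 interior residues" versus "pairs
  spaced up to 11 residues apart"); the defaults reconcile them as a total
  length cap of 11, and both bounds are configuration keys;
* the pair is not knot-like. Interleaved spans $i_1 < i_2 < j_1 < j_2$
  exclude both bonds, bonds sharing a cysteine exclude each other, and a
  loop whose interior contains a cysteine engaged in another detected bond
  is excluded (so in a nested pair the outer loop is dropped and the inner
  kept). Cysteine-knot motifs are a different structural class and would
  contaminate the loop statistics.

Cysteines without an S$\gamma$ atom cannot be tested and are skipped with
a warning rather than an error: incomplete side chains are routine in
crystal structures.

### Surface and interface classification

Solvent-accessible surface area is computed with a Shrake--Rupley
estimator (`computeSasa()`): each atom is expanded by the probe radius
(default 1.4 Å, a water molecule) and sampled with a deterministic
Fibonacci sphere lattice, default 960 points per atom. Rather than a
binary in/out count, each sample point contributes a weight that ramps
linearly from 1 to 0 as its signed clearance from the nearest occluding
sphere crosses zero, with a ramp width of one lattice spacing. This
smoothed boundary test converges substantially faster in the point budget
than binary counting while preserving two exact properties the survey
relies on: an isolated atom scores exactly $4\pi(r + r_\mathrm{probe})^2$,
and adding atoms can only decrease per-atom area -- so per-residue
$\Delta\mathrm{SASA} = \mathrm{monomer} - \mathrm{complex}$ is
non-negative by construction, not merely within tolerance. Van der Waals
radii are Bondi values (C 1.70, N 1.55, O 1.52, S 1.80 Å); an element
without a tabulated radius is a hard error naming the atom. Hydrogens,
waters and HETATM records are excluded at parse time, and alternate
locations resolve to the highest-occupancy record (ties to altloc A).

A residue is a *surface* residue when its area strictly exceeds 2.5 Å²
("over" is read as a strict inequality), and an *interface* residue when
any heavy atom lies within 3 Å -- inclusive, reading "within" -- of a
heavy atom of another chain (`classifySurface()`,
`findInterfaceResidues()`).

Surface classification defaults to the assembled-complex context; whether
a historical survey would have used monomer or assembly context is not
decidable from the criteria alone, so `computeSasa(chains =)` exposes
both.

### Interface coverage

`loopInterfaceCoverage()` reports the fraction of a chain's interface
that falls inside a loop span in two modes, because "fraction of the
interface" is ambiguous between residue counting and buried area:

* `residue_count`: $|\mathrm{span} \cap \mathrm{interface}| /
  |\mathrm{interface}|$;
* `buried_area` (default): the ratio of summed per-residue buried area
  $\max(0, A_\mathrm{monomer} - A_\mathrm{complex})$ over loop interface
  residues to that over all of the chain's interface residues.

The two agree exactly when all interface residues bury equal area. A
share strictly above 0.5 flags the loop as occupying the majority of the
interface. A chain with no interface residues yields share 0 with an
explicit `noInterface` flag rather than `NaN`.

### Superposition

`superposeCalpha()` returns the C$\alpha$ RMSD after least-squares
optimal rigid-body superposition (Kabsch, via bio3d's fitting engine).
Atoms are paired by rank order within each fragment, not by author
numbering, because de novo models rarely share numbering with crystal
structures. Fewer than three C$\alpha$ pairs is an error.

## Conservation survey

### Column scoring

`jsConservation()` scores each alignment column by the Jensen--Shannon
divergence between the column's amino-acid distribution $p_c$ and a
background distribution $q$:

$$\mathrm{JS}_\lambda(p_c, q) = H(\lambda p_c + (1-\lambda) q)
  - \lambda H(p_c) - (1-\lambda) H(q)$$

with $\lambda = 0.5$, logarithms base 2, normalized to $[0,1]$ by the
divergence maximum (the binary entropy of $\lambda$, i.e. 1 bit at
$\lambda = 0.5$), and scaled by $(1 - \text{gap fraction})$ so gappy
columns score low; an all-gap column scores 0. The default background is
the marginal amino-acid frequency vector underlying BLOSUM62
(`blosum62Background()`). No pseudocounts are added: the survey compares
interior and flank columns of the *same* alignment, so the small-sample
bias of the plug-in estimate cancels from the difference statistic.
Window averaging is available (`window` columns each side) but off by
default, since the loop-versus-flank statistic already pools columns.

One consequence worth knowing: a fully conserved rare residue scores
higher than a fully conserved common one, because the divergence is taken
against the background. Under a uniform background all fully conserved
columns score identically.

### The loop-versus-juxtapeptide statistic

For each loop, `loopFlankDifference()` computes

* the interior mean over the loop's interior columns only -- terminal
  cysteine columns are excluded, since bond-forming cysteines are
  conserved for structural reasons and would inflate every loop equally;
* the flank ("juxtapeptide") mean over up to 4 reference positions on
  each side of the loop, skipping positions off the sequence or inside
  any other annotated loop (those are not "outside" any loop). The width
  of 4 matches the positional profile below; it is a configuration key;
* their difference, in $[-1, 1]$.

Loops are only scored when their terminal cysteines align to cysteines in
at least one homolog (`mapLoopColumns()`; both terminals in the same
homolog row, a gap disqualifies). The singular phrasing of the
requirement is read as "at least one homolog", with a flag to include all
loops. A loop with no usable flank position is flagged and excluded from
distributions. Records with difference strictly above 0.30 form the
preferentially conserved subset (`preferentiallyConserved()`), tallied by
family with unlabelled records pooled as "Other".

`positionalProfile()` compares, for each distance $d = 1..4$ from a
terminal cysteine, the scores of residues $d$ positions inside the loop
with residues $d$ positions outside, pooled over loops, using a
single-tailed Mann--Whitney U test (alternative: inside more conserved).
Distances with fewer than two contributing loops on either side are
reported as missing rather than tested.

`mannWhitneyU()` uses midrank tie handling; the p-value is exact (the
exact null distribution of U, equivalent to enumerating all orderings)
when both samples have at most 20 observations and no ties, and a normal
approximation with tie correction and continuity correction otherwise.
Full permutation enumeration with ties at $n = 20$ per side would require
$\binom{40}{20} \approx 1.4\times10^{11}$ rearrangements, so tied samples
use the corrected approximation at any size; when the tie-corrected
variance is zero (all observations identical) the one-sided p is 0.5 by
symmetry. Raw p-values are reported; no multiplicity correction is
applied by default, keeping the per-distance profile interpretable as
reported, with correction available downstream.

## Mimicry

### Sequence-level loop prediction

`predictSequenceLoops()` applies four rules to every Cys...Cys window of
total length at most 10 ("under 11 residues"): terminal cysteines, no
internal cysteine, no interior position predicted helix or sheet, and a
predicted-exposure majority. "More exposed than buried" is implemented as
a strict majority of exposed labels over the whole window; an exact tie
fails the rule. Overlapping candidates are all reported -- downstream
similarity filtering, not the predictor, decides relevance. Note the
deliberate asymmetry with the structural definition: the sequence
predictor caps total length at 10 where the structural survey allows 11;
both are parameters.

### Self-normalized similarity

`loopSimilarity()` aligns two loop *interiors* (flanking cysteines
stripped) by optimal pairwise dynamic programming under BLOSUM62 with a
linear gap penalty of $-12$ per gap position (opening = extension; three
times the most negative BLOSUM62 entry, which all but forbids gaps
between peptides this short) and normalizes by the target interior's
self-alignment score:

$$\mathrm{similarity}(q, t) = \frac{S(q, t)}{S(t, t)} \le 1 .$$

The source description of this normalization is truncated mid-sentence in
the literature this survey follows; dividing the raw score by the viral
(target) self-score is the only reading consistent with the surrounding
text ("the maximum possible alignment score was calculated by aligning
the viral loop to itself"), and is adopted here as the package's
definition rather than asserted as the original authors'. The measure is
asymmetric -- the viral side normalizes. Global alignment is the default;
a local (Smith--Waterman) variant is available via `type = "local"`
because the original description does not specify the regime. The
bundled verified score examples take the same value under both.

### Networks and triangles

`readMitab()` parses PSI-MITAB 2.5 files: accessions from the two
interactor columns (preferring `uniprotkb:` identifiers, isoform
suffixes collapsed to the parent accession so interactions match at
protein level), taxa from columns 10--11 (taxid 9606 is human; a
configurable taxid list or the literal word "virus" marks viral
entries). Unparsable lines are counted and skipped, duplicate edges merge
with the union of their source tags, and the result is an undirected
igraph graph. `findMimicryCandidates()` emits a hit for every human/viral
loop pair with similarity strictly above 0.50 that is supported by at
least one shared interactor $X$ (edges $H$--$X$ and $V$--$X$) -- the
triangle suggesting the viral loop co-opts the host loop's partner. The
shared-interactor set is listed exhaustively and hits are sorted by
descending similarity.

## The synthetic-data module

The generators produce inputs whose planted signal the pipeline should
recover exactly, under a fixed seed and byte-identical on regeneration.

**Structures** (`makeLoopStructure()`): chains are parallel extended
strands with 3.8 Å C$\alpha$ spacing and fixed intra-residue atom
offsets, so the minimum heavy-atom distance between chains is exactly the
configured gap; planted S$\gamma$ pairs are placed symmetrically about
the plant midpoint at exactly the requested distance, each plant on its
own z-shelf so plants cannot contact each other. The geometry is
schematic, not stereochemically valid -- every criterion the survey tests
(bond distance, contact distance, exposure) is purely metric, so metric
correctness is the only requirement. Consequently the structures say
nothing about detection performance on real side-chain packing,
alternate conformers, or crowded interfaces; they validate the decision
logic, not crystallographic robustness.

**Alignments** (`makeConservationMsa()`): row 1 is the ungapped reference
(the column consensus itself); every other row copies the column
consensus with probability `baseConservation`, plus `loopBoost` strictly
inside loop regions, and otherwise draws from the background
distribution; cys-flanked loop terminals are invariant cysteines in every
row. The default `baseConservation` of 0.6 is a calibration choice: the
normalized JS column score is a nonlinear function of the consensus-copy
probability, and 0.6 places the flanks at the operating point where the
score responds to a copy-probability increment with approximately unit
gain, so a planted boost of 0.3 is recovered as a score difference of
about 0.3 -- the parameter-recovery tests verify recovery within
$\pm 0.05$ at 200 loops, and monotonicity of the recovered mean in the
planted boost. Real orthologous alignments differ in ways the generator
does not emulate: gaps, phylogenetic correlation between rows (rows here
are i.i.d. given the consensus), rate variation along the sequence and
alignment error; passing recovery tests therefore demonstrates the
scorer and statistic are correctly wired, not that real alignments carry
this much signal.

**Networks** (`makeInteractionNetwork()`): planted (H, V, X) triangles
contribute the edges H--X and V--X; noise edges are rejection-sampled so
that no planted (H, V) pair gains an interactor that was not planted,
with an attempt cap of 10 times the requested count (exceeding the cap is
an error rather than a silently violated guarantee).

**Prediction profiles** (`makePredictionProfile()`): listed spans are
coil/exposed, everything else helix/buried; a position covered by both a
coil and a sheet span is a contradiction error.

## Problem sizes and numerical choices

The test suites run at sizes chosen to make the statistical assertions
sharp while keeping the default check fast: 100 seeded complexes (two
chains of 10--14 residues) for planted-loop recovery, interface
brute-force equality and $\Delta$SASA monotonicity; sphere-point
convergence compared at 960 versus 1920 points; 200 planted loops across
10 alignments of 50 rows for boost recovery, and 200 null seeds for the
false-positive calibration at $\alpha = 0.001$; 50 seeded networks of up
to ~50 nodes for brute-force triangle equality; exhaustive alignment
oracle over all interior pairs of length $\le 3$ on a six-letter
alphabet.

Determinism: all generators accept a seed and restore the caller's RNG
state; detection sorts output by (chain, position); deduplication picks
the lexicographically smallest structure id; pipeline outputs are
byte-identical under identical config and inputs (the manifest records
input checksums, not timestamps).

## Limitations

* No physically realistic structure modelling; the structural stage's
  correctness on real PDB assemblies is validated only through its
  metric definitions, not against curated disulphide annotations.
* Ortholog search and alignment construction are out of scope:
  alignments are inputs.
* Secondary-structure and accessibility prediction are out of scope:
  per-residue state files are inputs.
* The similarity normalization follows the package's documented reading
  of a truncated source description (see above); the local-alignment
  variant is provided because the regime is not pinned down.
* Sequence-mode conservation treats rows as independent; no phylogenetic
  weighting is applied.
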
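---
title: "Discovering conserved signature indels: methods and design notes"
author: "csindel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conserved signature indels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csindel)
```

## The problem

A conserved signature indel (CSI) is an insertion or deletion of a fixed
number of amino acids, at a fixed position in a protein, that is shared by
every member of a monophyletic group and absent outside it.  Because a
multi-residue indel inside an otherwise conserved region is a rare,
discrete genetic event, a clade-fixed indel is strong evidence of a single
change in the clade's common ancestor — a synapomorphy that can demarcate
taxa independently of phylogenetic tree topology.  `csindel` automates the
classic discovery procedure: scan a protein multiple sequence alignment
for gap patterns that split the rows into a bearer set and a non-bearer
set, require conserved flanking sequence on both sides, map the bearer set
onto a named-clade taxonomy, polarize the indel with outgroups, screen
homolog hit sets for exceptions, and emit signature reports.

## The candidate-indel model

The scanner works on alignment columns.  A column is *mixed* when it
contains at least one residue and at least one gap; a **candidate indel**
is a maximal run of consecutive mixed columns.  Within the run:

* rows carrying residues at every column are the residue side
  (`bearers`);
* rows gapped at every column are the gap side;
* rows gapped over only part of the run make the candidate
  **non-uniform** — it is kept and reported, but it can never become a
  CSI, because a signature indel must have one specific length.  We
  deliberately do not split such runs into smaller clean blocks: the
  sub-blocks would have lengths that differ between rows, which is
  exactly the situation the uniform-length rule exists to reject.

Two degenerate situations are handled explicitly.  Rows containing no
residues at all are dropped before scanning and surface later as missing
data: a single all-gap row would otherwise make *every* column mixed and
fuse the whole alignment into one useless run.  Runs closer than
`max_edge_distance` (default 20) columns to either alignment terminus are
excluded: terminal extensions routinely produce ragged gap patterns that
mimic indels.  Candidates whose residue or gap side is a single row are
flagged `"singleton"` because single-sequence indels are frequently
annotation or alignment artifacts.

## The flank-conservation rule

A candidate only becomes a signature when it sits inside conserved
sequence.  `flank_params()` encodes the rule:

| parameter | default | meaning |
|---|---|---|
| `window` | 45 columns | columns examined on each side (valid 40–50) |
| `min_conserved` | 4 | conserved columns required per side |
| `conservation_fraction` | 0.8 | share of non-gap rows that must carry the modal residue |
| `max_edge_distance` | 20 columns | exclusion zone at the alignment termini |

The discovery literature phrases the rule as "at least four to five
conserved residues on both sides within the neighboring 40–50 residues";
we take the weaker printed bound (4) as the default and the midpoint (45)
for the window, with both configurable inside the printed ranges.  A
column counts as conserved when the modal *non-ambiguous* residue is
shared by at least `conservation_fraction` of the column's non-gap rows
and fewer than half of the rows are gapped; `X`/`B`/`Z` never match
anything.  "Conserved" is not defined precisely in the source procedure,
which inspected alignments by eye; modal-residue identity at 0.8 is a
conservative, reproducible stand-in that recovers the visually obvious
flank blocks.  Conservation is counted over alignment columns (not
reference residues), skipping majority-gap columns so that unrelated gaps
in distant rows do not consume the window.

## Specificity, exceptions, and polarity

The taxonomy is supplied by the user — a newick tree with labelled
internal nodes or a lineage table (`species` → ordered clade path); the
package never infers a tree.  Outgroup species are declared with the
reserved lineage token `outgroup` instead of being grafted into the tree.

`evaluate_specificity()` finds the smallest named clade containing all
bearer species (the deepest common element of their lineage paths) and
succeeds when no species outside that clade carries the indel state and
at most `tolerance` clade members lack it (default 0: strict uniqueness).
Known exceptions can be allow-listed by name so that, for example, a
class-level signature absent from one deep-branching species can still be
reported with its exception recorded.  Because polarity is unknown at
detection time, both character states are tried: the residue side first,
then the gap side — a deletion-type signature is exactly the case where
the *gapped* rows form the clean clade.  Rows entirely gapped across the
signature window are reported as missing data and count neither as
bearers nor as exceptions, matching the convention that specificity
claims extend only to species whose homologs were actually observed.

Evaluation is per homolog group.  When a species contributes multiple
paralogs, only the focal group is scored, and the call is flagged
`paralog-restricted` when another group of a bearer species lacks the
state — the signature then dates to a duplication-then-change history
rather than a simple ancestral gain.  If group labels are absent,
`partition_homolog_groups()` assigns them by single-linkage clustering on
global pairwise identity (threshold 0.5), computed with the package's own
aligner.

`polarize_indel()` reads the outgroup rows: if every scorable outgroup
lacks residues in the block the indel is an **insertion** gained on the
bearer stem; if every outgroup carries residues it is a **deletion** in
the gapped rows; anything else — including zero scorable outgroups — is
ambiguous.  No minimum outgroup count beyond one is enforced, but the
support count is reported.

## The homolog screen

The second-pass screen takes a BLAST tabular hit list (outfmt 6) plus hit
sequences, keeps hits with E-value strictly below `1e-20`, sorts by
E-value with a stable id tie-break, and truncates to the top 250 (hard
cap 500).  E-values are taken from the input, never recomputed.

Each retained hit is aligned to the ungapped signature window with a
semi-global affine-gap dynamic-programming aligner written for this
purpose: the window must align end to end while leading and trailing hit
residues are free, the geometry of a ~100-residue window against a
full-length protein.  Scoring is BLOSUM62 with BLAST-style gap costs — a
gap of length $k$ costs $-11 - k$ ($\text{open} = -11$,
$\text{extend} = -1$ per residue).  Ties are broken deterministically:
substitutions beat gap openings, and gaps extend leftward, so identical
inputs always give identical alignments.  `classify_hit()` then calls the
hit's state: residues across the whole block, or one contiguous gap of
exactly the block length positioned within `slack = 3` columns of it;
partial or mis-sized gaps, straddling gap runs, or flank identity below
30% yield `ambiguous` rather than a guess.  `screen_hits()` aggregates
the calls into a verdict: *uniquely shared* when every in-clade hit with
a definite call has the indel and no out-of-clade hit does.

## The simulator

`simulate_family()` is the package's testbed: it generates families whose
statistical regime matches what the detector assumes, with ground truth
emitted alongside.  A uniform-random root sequence (default 400 residues)
evolves down a 17-taxon tree whose named clades mirror a nested nematode
phylogeny (six *Caenorhabditis* species plus *Diploscapter* forming
Rhabditoidea within Chromadorea, two Enoplea species, four apicomplexan
outgroups).  Branch lengths are read directly as per-site substitution
probabilities; a default 25% of sites are frozen (invariant), plus a
10-residue frozen zone on each side of every planted indel so the flank
rule is satisfiable by construction.  The planted CSI — clade, length,
type, position — is applied once on the stem branch of its target clade.
Background indel noise (length 1–3, Poisson with mean 0.03 per terminal
branch) is placed on terminal branches outside frozen zones.  Confining
noise to terminal branches is a deliberate property of the generator, not
a convenience: an internal-branch indel fixed in a named clade *is* a
clade-specific signature, which no detector could or should distinguish
from a planted one.  What the null families test is therefore the
rejection of lineage-specific gap noise, which is also the dominant form
of spurious gap structure in real alignments.

The true alignment is emitted from the simulator's own column registry,
so pipeline tests do not depend on an external MSA program; sequences can
also be written unaligned for integration tests with a real aligner.
Generation is a pure function of the seed, restores the caller's RNG
state, and self-checks the emitted truth against the alignment before
returning.

What the simulator does **not** emulate: realistic substitution matrices
or rate heterogeneity (replacement is uniform over the 19 alternatives),
within-species polymorphism, alignment error (the true alignment is
exact), compositional bias, and long terminal extensions.  Consequently a
perfect score on the closed-loop benchmark shows that the pipeline's
logic is correct under its own assumptions — clean gap blocks, conserved
flanks, clade-fixed states — not that real proteomes will yield
error-free calls; on real data, alignment quality is the binding
constraint, which is why the flank rule and the ambiguity-first hit
classification exist.

## Benchmark and test sizes

The closed-loop benchmark (`run_benchmark()`) uses 100 families of which
20 carry one planted CSI with randomized clade, length (1–6), type and
position, the configuration also recomputed by `scripts/acceptance.R`.
The scanner is checked against a brute-force interval-and-bipartition
enumerator on 500 random alignments (up to 8 rows × 120 columns); the
aligner against exhaustive alignment enumeration on 300 random pairs
(window 2–5 residues, hit up to 12 — sizes at which full enumeration is
tractable).  These problem sizes keep the whole suite under a minute on
one core while exercising every code path the larger regime uses.

## Known limitations

* The mixed-column run model cannot rescue a real indel whose block is
  fused to unrelated gap structure in another row (the candidate is
  reported, but as non-uniform); curating the input alignment remains the
  user's job.
* Specificity calls are combinatorial, not statistical: the package
  assigns no significance to an indel's presence/absence pattern, mirroring
  the discovery procedure it automates.
* Positions in reports are relative to the chosen reference row's ungapped
  sequence; different reference isoforms shift the printed ranges.
* The supermatrix trimmer is a documented gap-fraction rule, not a
  re-implementation of heuristic trimming tools, and tree inference is
  explicitly delegated to external programs via the PHYLIP/partition
  writers.
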
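# csindel

Discovery and validation of **conserved signature indels (CSIs)** in
protein multiple sequence alignments.

A CSI is an insertion or deletion of a fixed length, at a fixed position
in a protein, flanked by conserved sequence, and uniquely shared by all
members of a monophyletic group. Because such an indel records a single
rare genetic event in the group's common ancestor, CSIs are used as
synapomorphies: molecular markers that demarcate genera, families,
classes or phyla independently of tree topology. `csindel` automates the
classic discovery workflow for anyone mining proteomes for
clade-specific markers:

1. **Scan** an alignment for candidate indels — maximal runs of columns
   whose rows split into a residue-bearing set and a gap set
   (`scan_candidate_indels()`).
2. **Filter** by the flank-conservation rule: at least `min_conserved`
   (default 4) conserved columns on *both* sides within the neighboring
   `window` (default 45, valid 40–50) columns (`assess_flanks()`).
3. **Call specificity**: the smallest named clade containing all bearer
   species, with exceptions, intruders and missing homologs reported
   against a user-supplied taxonomy (`evaluate_specificity()`).
4. **Polarize** insertion vs deletion with outgroups
   (`polarize_indel()`).
5. **Screen** BLAST homolog hit lists (E < 1e−20, top 250–500) against
   the signature window with a semi-global affine-gap aligner (BLOSUM62,
   gap −11/−1) and call per-hit presence/absence (`screen_hits()`).
6. **Report**: dash-identity alignment blocks, signature tables, and
   per-CSI bundle files (`format_signature()`, `export_csi_table()`,
   `write_signature_file()`).

A clade-structured sequence simulator with planted indels
(`simulate_family()`, `make_benchmark_suite()`) provides ground-truthed
families so the whole pipeline is testable end to end without any
downloads, and a small supermatrix utility (`select_families()`,
`concatenate_alignments()`, `trim_columns()`) covers single-copy-family
concatenation for external tree building.

## Worked example

Simulate a family with a 5-residue insertion planted on the stem of the
genus *Caenorhabditis*, then rediscover it:

```r
library(csindel)

spec <- sim_spec(planted_csis = list(list(clade = "Caenorhabditis",
                                          length = 5, type = "ins",
                                          position = 200)),
                 seed = 42)
fam <- simulate_family(spec)
tax <- default_taxonomy()

res <- discover_csis(fam$alignment, tax,
                     meta = list(protein_name = "demo protein",
                                 gene_name = "demo-1"))
res$records[[1]]
#> CSI: 5 aa ins at 156-250, specific for Caenorhabditis
```

The record says: a 5-amino-acid insertion, shared by all six
*Caenorhabditis* species and nobody else, polarized as an insertion
because every outgroup lacks it; `156-250` is the signature window on
the ungapped reference sequence (1-based inclusive). Render the window
in dash-identity notation (dashes = identity with the top row, spaces =
gaps, the indel boxed):

```r
cand <- res$candidates[[1]]
ext <- extract_signature_region(fam$alignment, cand, flank_residues = 20)
format_signature(ext$window, box = ext$indel_cols)
#> C_elegans      181 YSAGMLYPFMRCGAQSTMVC|LLCWD|LEYRHTFYVKMGLKWKMWEL 225
#> C_briggsae     181 --------------------|-----|-------------------- 225
#> C_remanei      181 --------------------|-----|-------------------- 225
#> C_brenneri     181 -----I--------------|-----|-------------------- 225
#> C_japonica     181 --------E-----------|-----|-----------M-------- 225
#> C_sinica       181 --------E-----------|-----|-----------M-------- 225
#> D_pachys       181 --F--T--------------|     |-------------------- 220
#> S_ratti        181 K----K--A-----------|     |---------------V---- 220
#> A_ceylanicum   181 -----K--------------|     |------------QG---D-- 220
#> B_malayi       181 --Y--I--------------|     |-----------------D-- 220
#> A_suum         181 -----K--------------|     |-----------------D-- 220
#> T_spiralis     181 -----K--------------|     |-------------------- 220
#> T_muris        181 -----K--------------|     |-------------------- 220
#> C_muris        181 -----K--------------|     |-------------------- 220
#> P_falciparum   181 C----K--K-----------|     |----------------N--- 220
#> B_xinjiang     181 --P--K--------------|     |------------F---N--- 220
#> E_necatrix     181 --M--K--------------|     |------------F--AN--- 220
```

All six *Caenorhabditis* rows carry residues in the box; every other
nematode and the four apicomplexan outgroups show the gap. Export the
table row (ordering: most specific clade first, then gene):

```r
export_csi_table(res$records)
#>   protein_name gene_name accession    indel position    specificity exceptions flags
#> 1 demo protein    demo-1      <NA> 5 aa ins  156-250 Caenorhabditis
```

Real alignments enter through `read_alignment()` (aligned FASTA or
Clustal, `id|species|homolog_group` headers or a sidecar TSV), and
taxonomies through `read_lineage_table()` /`taxonomy_from_newick()`; see
`inst/extdata/nematode_lineages.tsv` for the lineage format and the
vignette (`vignettes/csi-discovery.Rmd`) for the full method
description.

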
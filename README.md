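# metaspec

De novo protein sequencing by spectral-network assembly, in R.

`metaspec` is for proteomics of organisms without a reference genome —
venoms are the motivating case — where peptide-spectrum matching has
nothing to match against and single-spectrum de novo sequencing yields
only short, error-prone tags. It implements the multi-protease,
multi-dissociation assembly strategy end to end:

* **PRM conversion** — each MS/MS scan becomes a *prefix residue mass*
  spectrum: scored hypotheses for the cumulative N-terminal masses
  $p_k = \sum_{i\le k} m_i$ of its peptide, read from b/y (CID, HCD),
  a (HCD) and c/z• (ETD) ions.
* **Triple merging** — the CID/HCD/ETD spectra acquired from the same
  precursor are merged by adding scores of matching masses; only true
  prefix masses are corroborated by all three chemistries, which is how
  N/C mirror-image ambiguity is broken.
* **Spectral networks** — merged PRM spectra of overlapping peptides
  (different proteases, missed cleavages) are aligned by a mass shift
  with an exact monotone-matching dynamic program, with decoy-calibrated
  significance and an overlap-completeness filter against chance
  compositional collisions.
* **A-Bruijn assembly** — matched peaks glue into vertices; the heaviest
  consensus path is the contig and its consensus spectrum the
  *meta-contig*, which can span far more residues than any one peptide.
* **Gapped de novo readout** — consensus mass differences become residue
  letters or bracketed gap masses (`GVIIHE[291.835][227.31]GFY`-style
  notation, with a verbatim-round-tripping parser/formatter).
* **Homology mapping and parsimony** — gapped strings are placed on
  database proteins (I ≡ L, gaps consume mass-matched substrings) and a
  greedy maximum-parsimony step reports the minimal protein set.

A synthetic-acquisition module reproduces the emulated experimental
design — 10 kDa fractionation, four digests (trypsin 4 h partial,
trypsin 18 h, chymotrypsin 18 h, pepsin 18 h), top-3 DDA with 60 s
dynamic exclusion, m/z 350–1800, carbamidomethyl-C — with complete
ground truth, so the whole pipeline is testable without any downloads.

## Worked example

Two overlapping peptides, aligned, glued, and read out:

```r
library(metaspec)
a  <- ideal_prm("GASP"); b <- ideal_prm("ASPK")
al <- align_pair(a, b, min_matches = 2)
al
#> <PairwiseAlignment> GASP ~ ASPK shift 57.0215, 2 matches, score 4.000
mc <- to_meta_contig(consensus_path(glue(list(a, b), list(al)), "demo"))
mc
#> <MetaContig demo> 4 consensus masses, 2 spectra, span 255.12 Da
format_denovo_string(sequence_consensus(mc))
#> [1] "GASPK"
```

The shift 57.0215 Da is the mass of the glycine by which `ASPK` is
offset inside `GASP`'s frame; the two internal matches (128.059 and
215.091 Da) are the shared prefix masses, and the assembled meta-contig
reads back the five-residue union.

The full pipeline on the default synthetic design (10 proteins, two
mass fractions, four digests, noiseless triples):

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "runs/demo"))
res$summary
#>               category above10k below10k together
#> 1    spectral_triplets      205       48      253
#> 2              contigs       48        9       57
#> 3     denovo_sequences       48        9       57
#> 4 homologous_sequences       48        9       57
#> 5             proteins        7        3       10
#> 6            raw_files        4        4        8
```

253 precursor triples assemble into 57 meta-contigs; every one maps
best to its true source protein, and cross-fraction parsimony recovers
exactly the 10 simulated proteins (the per-fraction counts 7 + 3 merge
to 10 because the fractions share no proteins here). A typical
meta-contig readout spans a whole tryptic-peptide neighbourhood, e.g.
`QFADHMDYNTSSIQMNWCDIMCDFSYIR` (28 residues, I/L reported as I).

`ground_truth_recovery(res)` joins any simulated run against its ground
truth and reports the mapping rate, residue-call accuracy and whether
parsimony recovered the true protein set. A thin command-line wrapper
for simulate / pipeline / summarize lives at `inst/cli/metaspec.R`.

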
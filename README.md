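# chimeraMSA

Windowed multiple sequence alignments for chimeric fusion proteins.

## The problem

MSA-based structure predictors (AlphaFold-2/3 and relatives) extract
coevolution signal from an alignment of homologs. A chimeric protein — a
scaffold such as SUMO, GST, GFP or MBP with a structured peptide tag fused
to one terminus through a flexible Gly-Ser linker — exists nowhere in
nature, so a single MSA search over the fused sequence typically recovers
homologs for the scaffold only. The peptide region loses its coverage, and
with it its prediction accuracy, even when the same peptide is predicted
accurately in isolation.

The windowed-MSA remedy is to search the scaffold (carrying the linker) and
the peptide **independently**, then merge the two sub-alignments into one
block-diagonal alignment over the chimeric query:

```
query:    [ scaffold ][GS][ peptide ]
scaffold  [ homolog i ][--][---------]   <- gaps across the peptide window
homologs  [ homolog j ][--][---------]
peptide   [-----------][--][ hom k   ]   <- gaps across scaffold + linker
homologs  [-----------][--][ hom l   ]
```

Gap characters fill every non-homologous position, so each region keeps its
own homology signal, alignment lengths are preserved, and no spurious
residue pairing across the fusion point can arise. The merged A3M is then
handed to the structure predictor; running the predictor itself is out of
scope for this package.

## What the package provides

- **A3M / aligned-FASTA I/O** in the MMseqs2/ColabFold dialect
  (`read_a3m()`, `write_a3m()`; lowercase insertions stripped so the merge
  operates in query-column space), with `hit_count()`,
  `identity_to_query()` and `coverage_profile()` for interrogation.
- **Fusion construction** (`make_fusion()`, `enumerate_constructs()`):
  scaffold + Gly-Ser linker + peptide at either terminus, with exact
  residue windows; 4 scaffolds x 51 peptides x both termini yields the
  canonical 408-construct dataset.
- **Redundancy clustering** (`greedy_cluster()`): greedy centroid
  clustering under global-alignment identity and bidirectional coverage
  thresholds (canonically 50 % / 80 %), plus a depth filter that removes
  peptides with fewer than 2 MSA hits (`filter_by_depth()`).
- **The windowed merge** (`build_windowed_msa()`, `incorporate_linker()`,
  `validate_windowed()`, `export_for_predictor()`).
- **Per-region evaluation** (`read_structure()` for PDB/mmCIF including
  multi-model NMR ensembles, `kabsch_superpose()`, `region_rmsd()`,
  `region_plddt()`, `rmsd_ratio_report()`): peptide-window CA RMSD after
  local Kabsch superposition against the first NMR model, and window mean
  pLDDT read from the B-factor column.
- **Synthetic fixtures** (`synth_msa()`, `synth_coords()`,
  `planted_families()`) so everything is testable offline, and a CLI
  dispatcher (`chimera_run()`, wrapped by `inst/cli/chimera.R`).

## Worked example

```r
library(chimeraMSA)

scaf <- synth_msa(60, depth = 8, substitution_rate = 0.25, gap_rate = 0.05,
                  seed = 42, query_id = "scaffold_demo")
pep  <- synth_msa(12, depth = 5, substitution_rate = 0.15, gap_rate = 0.05,
                  seed = 43, query_id = "peptide_demo")
fc <- make_fusion(scaf$query_seq, pep$query_seq, terminus = "C", linker = "GS",
                  scaffold_id = "scaffold_demo", peptide_id = "peptide_demo")
fc
#> FusionConstruct 'scaffold_demo_peptide_demo_C' (C-terminal): 74 aa =
#>   scaffold[0,60) + linker[60,62) + peptide[62,74)

w <- build_windowed_msa(scaf, pep, fc)
w
#> WindowedAlignment 'scaffold_demo_peptide_demo_C': 74 columns, depth 12
#>   (1 query + 7 scaffold + 4 peptide)
validate_windowed(w)
#> Windowed alignment clean (depth 12)

# the mechanism: merged coverage over the peptide window equals the
# peptide alignment's own coverage — the signal the fused-sequence search
# would have lost is restored
pw <- fusion_window_resno(fc, "peptide")
coverage_profile(w$merged)[pw[1]:pw[2]]
#> [1] 5 5 5 5 5 4 5 5 5 5 5 5
coverage_profile(pep)
#> [1] 5 5 5 5 5 4 5 5 5 5 5 5

export_for_predictor(w, "windowed.a3m")   # ColabFold-dialect A3M

# evaluating a (here synthetic) prediction against its reference
ref  <- synth_coords(12, "ideal_helix", seed = 44, sequence = pep$query_seq)
pred <- synth_coords(12, "ideal_helix", noise_sigma = 0.4, seed = 45,
                     sequence = pep$query_seq, plddt = 85)
region_rmsd(pred, ref, c(1, 12))   # 0.593 A (CA, local superposition)
region_plddt(pred, c(1, 12))       # 85.0
```

The same workflow is available from a shell:

```sh
Rscript inst/cli/chimera.R demo --out demo_dir
Rscript inst/cli/chimera.R window-msa --scaffold-a3m demo_dir/scaffold.a3m \
    --peptide-a3m demo_dir/peptide.a3m --terminus C --linker GS --out merged.a3m
```

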
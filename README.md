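# pamprospector

Tools for discovering and characterizing the protospacer adjacent motif
(PAM) specificity of Cas9 nucleases, aimed at computational biologists
who mine Cas9 orthologs for non-canonical PAMs (for example the
adenine-dinucleotide 5'-NAAN-3' preference found in SpyCas9 relatives
whose PAM-contacting arginines have diverged to glutamines) and at
bench scientists quantifying the validation experiments.

The package covers five stages as composable functions, plus a seeded
synthetic-data module with planted truth for all of them:

| Stage | Functions | What it computes |
|---|---|---|
| Ortholog mining | `global_align`, `filter_orthologs`, `map_reference_positions`, `build_residue_logo`, `design_hybrid` | BLOSUM62 percent-score filtering (`100·S(ref,q)/S(ref,ref)`, keep ≥ 70), residue logos (`IC = log2 20 − H`) around PAM-contact positions, PID-graft hybrid bookkeeping with verified point mutations |
| PAM inference | `find_protospacers`, `extract_pam_flank`, `build_pam_matrix`, `information_content`, `call_consensus`, `infer_pam` | spacer→genome Hamming mapping on both strands, 3'-flank position frequency matrix, `IC = 2 − H` bits, IUPAC consensus |
| Reporter enrichment | `normalize_trace`, `compute_enrichment`, `call_pam_preference` | per-position `log2((post+ε)/(pre+ε))` of a sorted vs pre-sort randomized PAM library, IUPAC calls at ≥ 2-fold |
| Cleavage quantification | `cleaved_fraction`, `assemble_naan_matrix`, `fit_first_order`, `summarize_replicates`, `quantify_lanes` | cleaved fraction = products / all bands, 4×4 NAAN matrices with duplicate mean ± sd, first-order fits `f(t) = A(1 − e^{−kt})` |
| PAM landscape | `scan_pam_sites`, `dinucleotide_frequencies`, `pam_density` | IUPAC motif sites with protospacer coordinates on both strands, genome-wide motif density over N-free windows |
| Synthetic data | `gen_ortholog_family`, `gen_phage_cohort`, `gen_trace_pair`, `gen_gel_data`, `gen_timecourse` | seeded inputs with truth records for every stage |

A thin command-line interface wraps the same functions
(`inst/cli/pamprospector`, subcommands `mine-orthologs`, `infer-pam`,
`enrich`, `quantify-gel`, `scan-pam`, `simulate`).

## Worked example

Simulate a phage cohort whose planted protospacers carry flanks drawn
from (N, A:0.9, A:0.9, N), then infer the PAM from the spacers alone:

```r
library(pamprospector)

cohort <- gen_phage_cohort(3, 10000, 30,
                           pam_profile = list("N", c(A = 0.9), c(A = 0.9), "N"),
                           mismatch_rate = 0.02, seed = 42)
res <- infer_pam(cohort$spacers, cohort$genomes)
res$consensus$iupac
#> [1] "NAANNNNN"
round(res$consensus$ic_bits, 2)
#> [1] 0.04 1.65 1.58 0.11 0.09 0.07 0.13 0.02
```

All 30 spacers map back to their planted protospacers, and the
consensus over the 8-nt flank is 5'-NAAN(NNNN)-3': the planted adenine
dinucleotide carries ~1.6 bits of information per position while the
unconstrained positions stay near 0 bits, exactly the logo shape
expected when the only selective pressure on the flank is the PAM.

Fitting a simulated digestion time course recovers its kinetics:

```r
tc <- gen_timecourse(0.3, 0.9, c(1, 2, 4, 6, 8, 12, 16, 24),
                     noise_sd = 0.02, seed = 42)
fit <- fit_first_order(tc$time, tc$fraction)
sprintf("k = %.3f /min, plateau = %.3f", fit$k, fit$plateau)
#> [1] "k = 0.302 /min, plateau = 0.909"
```

And the landscape convention is easy to check by hand: in `AATT` the
three dinucleotide windows are `AA` (forward match), `AT` (no match on
either strand) and `TT` (reverse-strand match), so

```r
pam_density("AATT", "AA")$density
#> [1] 0.6666667
```

See `vignette("pam-discovery-workflow")` for the models, parameter
conventions and limitations.

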
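# tcrep — TCR repertoire comparison for sorted T-cell populations

`tcrep` is an R package for asking whether sorted T-cell populations carry
the *same* T-cell receptor (TCR) repertoire or *different*, clonally
expanded ones — the analysis used to show that, after immunization,
T follicular helper (Tfh) cells are oligoclonally expanded while
T follicular regulatory (Tfr) cells share their repertoire with regulatory
T (Treg) cells. It implements two complementary tracks:

**Spectratype track** (fluorescence peak tables, per TRBV segment):
normalized CDR3-length profiles; deviation from a reference profile; a
bounded perturbation score per sample × segment,

    P = 100 · ½ Σ_ℓ | f_sample(ℓ) − f_ref(ℓ) |      (total-variation distance, %)

plus Euclidean/UPGMA clustering, PCA, and one-way ANOVA with Holm-adjusted
pairwise Welch tests on the overall scores.

**Repertoire track** (clonotype count tables): depth normalization by
random downsampling without replacement; resampled pairwise clonotype
sharing (mean ± s.d. over iterations); clonality

    clonality = 1 − J,   J = H / log2(S),   H = −Σ p_i log2 p_i

(1 − Pielou evenness, 0 = maximally even, 1 = monoclonal); Morisita–Horn
overlap

    MH = 2 Σ x_i y_i / ((λ_x + λ_y) · X · Y),   λ = Σ x_i² / X²

with 1 − MH as clustering distance; top-k predominant-clonotype tables; and
average-linkage dendrograms annotated with multiscale-bootstrap AU/BP
cluster support (features resampled with replacement at scales 0.5–1.4,
probit fit `qnorm(1 − BP_r) = v√r + c/√r`, `AU = 1 − Φ(v − c)`).

A synthetic-data module generates both input dialects with planted ground
truth (expanded clones shared across replicate mice, a Tfr pool nested in
the Treg pool, single-length spectratype spikes), so the entire pipeline is
testable without access to any sequencing archive.

## Worked example

```r
library(tcrep)

dir <- tempfile()
paths  <- write_simulated_repertoires(repertoire_sim_config(seed = 3), dir)
report <- run_repertoire_pipeline(paths$table, file.path(dir, "out"),
                                  n_boot = 200, seed = 11)
round(unlist(report$clonality), 3)
#>   Tfr_m1   Tfr_m2   Tfr_m3   Tfh_m1   Tfh_m2   Tfh_m3  Treg_m1  Treg_m2
#>    0.349    0.300    0.341    0.422    0.385    0.411    0.116    0.115
#>  Treg_m3  Treg_m4  Tact_m1  Tact_m2  Tact_m3  Tact_m4 Tconv_m1 Tconv_m2
#>    0.129    0.114    0.349    0.340    0.357    0.380    0.116    0.107
#> Tconv_m3 Tconv_m4
#>    0.114    0.123
```

Clonality separates the expanded populations (Tfh highest, then Tact and
Tfr) from the polyclonal ones (Treg, Tconv ≈ 0.11). The Morisita–Horn
dendrogram in `out/mh_dendrogram.nwk` carries AU/BP labels; the cluster
containing exactly the Tfr and Treg samples is recovered with AU = 1 — its
counterpart in the motivating analysis is the key evidence that Tfr cells
recirculate from the Treg repertoire rather than arising from the same
specificities as Tfh cells.

The spectratype track runs the same way:

```r
paths <- write_simulated_spectratypes(spectratype_sim_config(seed = 7), dir)
rep   <- run_spectratype_pipeline(paths$peaks, file.path(dir, "spec_out"),
                                  reference_group = "Tfr", seed = 7)
round(sort(unlist(rep$overall_perturbation)), 2)
#>   Tfr_m1   Tfr_m2   Tfr_m3  Treg_m1 Tconv_m1 Tconv_m3  Treg_m2 Tconv_m2
#>     1.27     1.31     1.33     1.88     1.92     2.00     2.00     2.00
#>  Treg_m3   Tfh_m1   Tfh_m3   Tfh_m2
#>     2.28     7.63     8.10     8.24
```

Tfh samples stand apart (planted single-length expansions, δ = 0.3 in five
segments), everything else sits at the noise floor; the accompanying ANOVA
on these scores gives F ≈ 798, p ≈ 3e-10.

Every run writes TSV matrices, Newick trees and a JSON report listing each
artifact with its md5 hash; rerunning with the same input and seed
reproduces the hashes byte for byte. A thin command-line wrapper with
`simulate-spectratype` / `simulate-repertoire` / `spectratype` /
`repertoire` subcommands is installed at `inst/scripts/tcrep-cli.R`.

See the vignette (`vignettes/tcr-repertoire-comparison.Rmd`) for the model
assumptions, parameter defaults and their rationale, and the limits of what
the synthetic validation shows.

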
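# paralogdiv

Functional divergence analysis between two paralog clades of an
aligned protein family, motivated by the vertebrate paralogs GAS6 and
PROS1 — homologous vitamin-K-dependent proteins separated by the
whole-genome duplications at the base of vertebrate evolution, which
retained structural similarity while diverging in function.

Given a two-clade protein alignment, the package answers four
questions:

1. **Which sites diverged functionally?** Every column gets entropy-based
   scores for the three classic patterns — with per-clade conservation
   `c = 1 − H/ln 20` and modal residues `m`:

   * Type Ia — conserved in the second clade, variable in the first:
     `S_Ia = c₂ (1 − c₁)`
   * Type Ib — the mirror image: `S_Ib = c₁ (1 − c₂)`
   * Type II — conserved in both clades for different residues:
     `S_II = c₁ c₂ [m₁ ≠ m₂]`

   Detection cutoffs are **calibrated on simulated null alignments**
   (single-class exchangeable substitution process, gamma rate
   variation) as the 99th percentile of null scores — a tolerated
   false-positive rate of about 1% per score type — and detection runs
   over the full alignment plus all leave-one-out jackknife replicates,
   retaining every detection. External per-site method results
   (FunDi-style posteriors, branch-site positive-selection tables) are
   merged in at their posterior thresholds.

2. **Do divergent sites matter structurally?** From a per-position
   ΔΔG substitution matrix (ΔΔG = ΔG_mut − ΔG_wt, kcal/mol; e.g. a
   FoldX position scan, or the bundled surrogate generator), each
   clade's median stability effect per column and the absolute
   between-clade difference |Δ|, with a Wilcoxon rank-sum comparison of
   divergent vs non-divergent sites and effect binning at 0.5/1/2
   kcal/mol.

3. **When did the paralogs split?** A clock rate from taxon-pair time
   calibrations (`r = d / 2T`, median over pairs) converts node heights
   of a near-ultrametric tree into ages in Ma.

4. **Where do divergent sites sit on the structure?** Interface
   residues and ligand-proximal residues at a strict <6 Å heavy-atom
   cutoff, N-glycosylation sequon (N-X-S/T) scanning, and alignment-based
   mapping of sites onto chain residues.

A seeded synthetic-data module generates every input the pipeline
consumes (null and planted-site alignments, trees, surrogate ΔΔG
matrices, toy structures), so the whole chain is exercisable without
any external data. The bundled table
`inst/extdata/gas6_pros1_divergent_sites.tsv` carries the 78
GAS6/PROS1 sites under functional divergence with dual-isoform
numbering and method tags.

## Worked example

```r
library(paralogdiv)

# the bundled GAS6/PROS1 divergent-site table
sites <- gas6_pros1_sites()
nrow(sites)
#> [1] 78
head(sites, 3)
#>   aln_col gas6_pos1 gas6_pos2 gas6_aa pros1_pos pros1_aa methods
#> 1      NA        37        37       E        31        Q    B_Ib
#> 2      NA       384       341       Q       345        D    B_Ia
#> 3      NA        51        51       Q        44        S      PS

# calibrate Ia/Ib/II cutoffs on a 5,000-column null alignment
null_msa <- simulate_null_alignment(sim_spec(n_columns = 5000, seed = 1))
th <- calibrate_thresholds(null_msa)
th$II
#> calibrated_threshold [II]: 99th percentile of 5000 null scores = 0.843165

# plant 60 divergent sites into a fresh alignment and detect them
base    <- simulate_null_alignment(sim_spec(n_columns = 1000, seed = 2))
planted <- plant_divergent_sites(base, c(Ia = 20, Ib = 20, II = 20),
                                 eps = 0.05, seed = 3)
det <- detect_sites(planted$msa, th)          # jackknife union
mean(planted$truth$column %in% det$aln_col)   # sensitivity
#> [1] 0.95

# stability divergence of the planted sites (surrogate ddG matrix)
ref  <- planted$msa$ids[1]
ddg  <- surrogate_ddg(unname(planted$msa$seqs[ref]), seed = 4)
nmap <- build_numbering_map(planted$msa, ref)
stability_analysis(planted$msa, ddg, nmap, planted$truth$column)$comparison
#> stability_comparison (Wilcoxon rank-sum, two-sided)
#>   divergent sites:     n=60  mean=1.429  median=1.354 kcal/mol
#>   non-divergent sites: n=940  mean=0.379  median=0.000 kcal/mol
#>   W = 48612.0, p = 4.729e-26

# clock-date a strict-clock tree from two calibrated pairs
tr  <- ape::read.tree(text = "((a:0.16,b:0.16):0.44,(c:0.24,d:0.24):0.36);")
cal <- data.frame(taxon_a = c("a", "c"), taxon_b = c("b", "d"),
                  time_ma = c(80, 120))
clock_calibration(tr, cal)
#> time_calibrated_tree: 4 tips, 2 calibrations
#>   median clock rate: 0.002 substitutions/site/Myr
#>   root age: 300.0 Ma
```

The sensitivity of 0.95 means 57 of the 60 planted sites were
recovered at a within-clade error rate of 5%; the stability comparison
shows planted divergent columns carrying a mean |Δ median ΔΔG| about
1 kcal/mol above the background, and the clock example recovers the
generating rate and a 300 Ma root exactly.

A command-line wrapper (`exec/paralogdiv`) exposes the stages as
subcommands (`simulate`, `calibrate`, `detect`, `stability`, `clock`,
`structmap`, `report`); machine outputs are TSV/JSON with embedded
version, seed and parameter echo.

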
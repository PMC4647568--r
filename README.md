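# vertvar

Analysis of meristic variation in the vertebral column of *Triturus* newts
(and similar salamanders), for researchers working on axial-skeleton
evolution and homeotic transformations.

Newt vertebral columns are scored per specimen as a vertebral formula —
one cervical vertebra (the atlas), `T` complete rib-bearing thoracic
vertebrae, one sacral vertebra. Incomplete homeotic transformations at the
thoraco-sacral boundary produce *transitional* sacral vertebrae (thoracic
rib on one side, sacral rib on the other), scored as a half vertebra:

    s = T + 0.5 · 1[transitional sacral vertebra]

From a species sample the package derives the four statistics used
throughout this literature — the modal count **T_n**, the percentage of
non-modal individuals **T_var** (half-score specimens excluded from the
numerator), the integer-count span **T_range**, and the transitional-sacrum
prevalence **S_tr** — and tests the classic prediction of Geoffroy St.
Hilaire's rule that series with more serially homologous elements vary
more, via tie-corrected Spearman rank correlations (r_s from midranks),
G-tests of independence for central-vs-fringe and hybrid-vs-parent
comparisons, and phylogenetic comparative procedures: Felsenstein
independent contrasts with through-origin contrast regression, and a
tip-permutation phylogenetic-signal test whose statistic is the minimal
sum of squared changes under squared-change parsimony.

A seeded synthetic-data module (`simulate_records()`, `simulate_bm()`)
generates specimen tables and Brownian-motion traits with the statistical
structure the analysis assumes, so every stage can be exercised and
calibrated without museum material. The published species tables ship as
plain-text fixtures and flow through the same code paths as user data.

## Worked example

```r
library(vertvar)
rec <- rbind(table1_records(),
             table3_records()[is_hybrid(table3_records()$species), ])
report <- vertebral_report(rec, triturus_tree(),
                           iterations = 10000, seed = 1)
print(report)
```

```
Species summaries (central populations):
      species   n T_n T_var T_range S_tr
   marmoratus  58  12  13.8       1  6.9
     pygmaeus  55  12   3.6       1  1.8
 ivanbureschi 175  13  10.3       2  4.0
    karelinii  43  13   4.7       1  2.3
     carnifex  66  14  12.1       3  7.6
  macedonicus  67  14  14.9       2  9.0
    cristatus 122  15  14.8       3  4.9
   dobrogicus  57  17  24.6       3  1.8

Spearman correlations:
  Tn_Tvar     r_s =  0.75  (p_t = 0.032)
  Tn_Trange   r_s =  0.90  (p_t = 0.002)
  Str_Tvar    r_s =  0.24  (p_t = 0.570)
  Str_Trange  r_s =  0.13  (p_t = 0.766)

Phylogenetic signal (tip-permutation, 10000 iterations):
  T_n      p = 0.0017
  T_var    p = 0.1862
  T_range  p = 0.0281
  S_tr     p = 0.2974

Contrast regressions (through origin):
  Tvar_on_Tn    slope =   3.811  t =   2.65  p = 0.0383
  Trange_on_Tn  slope =   0.362  t =   2.14  p = 0.0762
  Tvar_on_Str   slope =   0.559  t =   0.65  p = 0.5371
  Trange_on_Str slope =   0.022  t =   0.23  p = 0.8246
```

Reading the output: species with more thoracic vertebrae are more variable
in their count (r_s = 0.75 between T_n and T_var; positive contrast
regression after removing phylogenetic structure), the modal count itself
is strongly clade-structured (signal p = 0.0017), while the prevalence of
transitional sacra tracks neither the count nor its variability. The
phylogenetic p-values depend on the branch lengths of the packaged tree,
which is a clearly-labelled synthetic approximation of the calibrated
species tree (topology exact, node ages approximate) — substitute your own
Newick via `read_newick()` for calibrated inference.

The methods vignette (`vignettes/vertebral-variation.Rmd`) documents the
scoring rules, the exclusion rule behind T_var, the permutation-test and
contrast algebra, the generator's scope, and all numerical choices.

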
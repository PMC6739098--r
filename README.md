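# cytotaxa

Links 16S rRNA gene taxon abundances to flow-cytometry functional groups —
the high-nucleic-acid (HNA) and low-nucleic-acid (LNA) cell pools of
aquatic bacterioplankton — with stability selection, blocked
cross-validation, and independent validation layers. It is written for
microbial ecologists who have paired OTU tables and cytometry event data
from structured surveys (multiple sites and years) and want to know which
taxa's dynamics predict the dynamics of each functional group.

## The method in brief

Relative abundances $x_{ij}$ are mapped to the centred log-ratio scale,
$z_{ij} = \log\!\big(x_{ij} / (\prod_k x_{ik})^{1/p}\big)$, with zeros
replaced by $\delta = 1/p^2$. For a target $y$ (log HNAcc or log LNAcc,
cells/ml, from fixed-gate cytometry averaged over replicates), the
Randomized Lasso fits

$$\hat\beta_\lambda=\arg\min_\beta \lVert y'-X'\beta\rVert_2^2+\lambda\sum_j w_j\,\lvert\beta_j\rvert$$

on `B` half-subsamples with random per-variable weakness
$w_j \in \{\alpha, 1\}$, over 100 penalties in $[10^{-3}, 10^{3}]$. A
taxon's RL score is its maximum selection frequency along that path.
Recursive elimination then drops low-scoring taxa and tracks RCV² — the
pooled out-of-group $R^2$ under leave-one-group-out cross-validation over
site-by-year blocks — to find the smallest subset with maximal predictive
performance; a fully nested variant (RNCV²) re-runs selection inside every
outer fold. Associations are cross-validated three ways: Boruta
(all-relevant Random-Forest selection against permuted shadow features),
Kendall tau-b with Benjamini–Hochberg control, and a 128×128
kernel-density fingerprint of the cytometry plane whose per-bin tau-b maps
show *where* in fluorescence space each taxon's dynamics are mirrored.

A synthetic-data generator (`sim_config()`, `simulate_dataset()`) plants
known driver taxa in a blocked compositional community with matching
two-cloud event data, so every stage is testable against ground truth.

## Worked example

```r
library(cytotaxa)

sim <- simulate_dataset(sim_config(n_samples = 24, p_taxa = 50,
                                   n_groups = 4, depth = 2000,
                                   n_drivers = 3, events_per_sample = 400,
                                   seed = 9), fcm = TRUE)
res <- run_pipeline(sim, out_dir = tempfile(), gate = sim_gate_config(),
                    stability = stability_config(B = 30, seed = 5),
                    boruta = boruta_config(n_iterations = 20, seed = 5),
                    min_count = 2, step = 10, grid = 64, seed = 5)

res$select
#> <stability_result> 45 taxa, B = 30, alpha = 0.5
#> scores > 0.5: 3; top taxon: OTU030 (0.633)

res$elimination
#> <elimination_trace> 6 steps; optimum: 1 taxa, RCV2 = 0.2951

head(tidy(res$select), 3)
#> # A tibble: 3 × 3
#>   taxon_id rl_score  rank
#>   <chr>       <dbl> <int>
#> 1 OTU001      0.4       9
#> 2 OTU002      0.133    44
#> 3 OTU003      0.467     5

sim$truth$s_hna
#> [1] "OTU030" "OTU027" "OTU033"
```

The RL puts a planted driver on top (`OTU030`, score 0.633, one of the
three taxa above the 0.5 false-selection-control threshold); the
elimination trace says that on this tiny noisy fixture a single top-ranked
taxon already predicts held-out site-by-year groups (RCV² ≈ 0.30) better
than the full 45-taxon model. `autoplot()` methods exist for
stability paths, elimination traces, nested-CV predictions, fingerprints
and bin-correlation maps; `tidy()`/`glance()` return tibbles for every
result type.

Real data enter through `read_taxon_table()` (mothur shared-style TSV or
wide CSV), `read_sample_metadata()`, `read_targets()`, and
`read_fcm_events()` (CSV or FCS 3.0/3.1), aligned with `align_samples()`.

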
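# mmdbatch

Batch correction for single-cell RNA-seq by **cluster-pair MMD transfer
learning**. The package is for analysts who need to merge scRNA-seq batches
whose *cell-type compositions differ* — including the hard case where some
populations exist in only one batch — without erasing that batch-specific
biology.

## The method

1. **Preprocess** each batch: counts-per-million, `log2(x+1)`, highly
   variable genes (dispersion z-scored within 20 mean-expression bins,
   ranked across batches), per-batch gene standardization, then a pooled
   linear rescaling of every gene to [0, 1].
2. **Cluster each batch independently** (PCA, shared-nearest-neighbor graph,
   Louvain modularity).
3. **Match clusters across batches** with a neighbor-voting AUROC on a
   rank-normalized Spearman correlation network. The raw score tensor
   `M[(a, j_a), (b, j_b)]` is reduced by: best hit per other batch →
   symmetrize with `max` → binarize at `S_thr` (default 0.90; clusters
   scoring below the threshold everywhere are aligned to nothing). One
   cluster may legitimately match several clusters of another batch.
4. **Train an autoencoder** on all cells with the loss

   `L = L1 + lambda_p * L2`,

   where `L1` is the reconstruction error, `L2` is the sum of biased squared
   maximum mean discrepancies `MMD²(Z_{a,j_a}, Z_{b,j_b})` between the
   bottleneck codes of every aligned cluster pair in the mini-batch
   (multi-bandwidth Gaussian kernels, median heuristic), and
   `lambda_p = 2/(1+e^{-10p/np}) - 1` ramps the transfer loss in over
   training. The bottleneck code is the batch-corrected embedding.
5. **Evaluate** with three label-aware metrics on 2D coordinates:
   `divergence_score` (kNN KL divergence between shared populations; lower
   is better mixing), `entropy_score` (local batch entropy around
   batch-specific populations; lower means they stayed pure), and
   `silhouette_score` (cell-type silhouette; higher is better separation).

Two simulators — a projected 2D-Gaussian-mixture generator with additive
gene-specific batch noise, and a gamma-Poisson count simulator with
lognormal batch/DE factors and 0.4/0.3/0.2/0.1 group composition — make the
whole pipeline testable with no external data, including "removal" designs
where named cell types are deleted from single batches.

## Worked example

```r
library(mmdbatch)

# two simulated batches, four cell types; make the compositions differ by
# removing one type from each batch ("removal2" design)
ds <- simulate_gaussian(gaussian_sim_config(
  cells_per_batch = 500, composition_mode = "fixed",
  proportions = rep(0.25, 4), seed = 1))
ds <- remove_cell_type(ds, "Batch1", "Type1")
ds <- remove_cell_type(ds, "Batch2", "Type4")

run <- run_pipeline(
  ds, s_thr = 0.90,
  preprocess = preprocess_config(n_hvg = 100),
  model = ae_config(hidden_sizes = c(20, 2, 20), epochs = 500,
                    recon_mean = TRUE, learning_rate = 2e-3, lr_decay = TRUE),
  seed = 1)

run$report
#> # A tibble: 1 x 5
#>   divergence_score entropy_score silhouette_score n_div n_ent
#>              <dbl>         <dbl>            <dbl> <int> <int>
#> 1            1.12          0.269            0.714     2     2

tidy(run$mask)[tidy(run$mask)$aligned, ]   # which cluster pairs were aligned
plot_embedding(run, colour = "cell_type")  # 2D code, types and batches
autoplot(run$model)                        # loss history
```

`divergence_score` is computed over the `n_div = 2` ordered batch pairs that
share cell types (smaller = the shared Type2/Type3 populations mix);
`entropy_score` over the `n_ent = 2` ordered pairs with batch-specific types
(smaller = the private Type1/Type4 populations remain pure);
`silhouette_score` measures how cleanly the four types separate in the
corrected code. For comparison, evaluating the *uncorrected* scaled input
with `evaluate_correction()` on the same labels gives a divergence several
times larger and a lower silhouette.

Everything is driven by one master seed: rerunning `run_pipeline()` with the
same inputs and seed reproduces the embedding and report bit-for-bit, and
`out_dir =` writes the similarity table, embedding, labels, JSON report and
a YAML manifest of every parameter and derived seed.

A thin command-line front end is installed at
`system.file("cli", "mmdbatch.R", package = "mmdbatch")` with subcommands
`simulate`, `preprocess`, `evaluate` and `run`.

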
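# spatchwork

Multi-slice spatial transcriptomics integration in R: a masked variational
graph autoencoder over per-slice spatial kNN graphs, refined by deep
embedded clustering and corrected for batch effects with a
mutual-nearest-neighbor triplet loss.

## Who this is for

Labs with several spatial transcriptomics sections — consecutive slices of
one tissue, multiple donors, or mixed platforms (Visium, Stereo-seq,
MERFISH-like) — who want one consistent set of spatial domains across all
sections, a batch-corrected joint embedding, denoised expression, and a
center-aligned 3D view. Everything runs on a single CPU; no deep-learning
framework is required (forward pass, backpropagation and Adam are
implemented on top of base matrix algebra and `Matrix`).

## The model in brief

Per-slice spot×gene counts are filtered, library-normalized,
log-transformed, reduced to highly variable genes and PCA scores
`X ∈ R^{n×m}`. Per-slice kNN graphs (default k = 8) are joined
block-diagonally into `A` and normalized as `Â = D^{-1/2}(A+I)D^{-1/2}`.
A random 20% of spots is replaced by a learnable mask token. The encoder

    Z_f = FC₂(ReLU(FC₁(X_mask)))            (64 → 16 units)
    H   = ReLU(BN(Â Z_f W₀))                 (64 units)
    μ, log σ² = ReLU(BN(Â H W_{μ,σ}))        (16 units each)
    Z  = Z_f + μ + exp(½ log σ²) ⊙ ε

feeds two decoders: `sigmoid(Z Zᵀ)` reconstructs the adjacency and a linear
graph convolution reconstructs `X`. Training minimizes

    L = λ₁(L_graph + w·L_KL + L_sce) + λ₂ L_DEC + λ₃ L_Tri

with a mean-squared adjacency loss, a Gaussian KL to N(0, I) (weighted
`w = 1/n` as in the reference VGAE implementation), a scaled cosine error
on masked spots (γ = 2), a Student-t deep-embedded-clustering refinement
(target refreshed every 20 epochs), and a margin triplet loss (τ = 1) over
cross-slice mutual nearest neighbors whose positives/negatives are
readout-averaged over α = 2 spots (anchors refreshed every 500 epochs).
Adam, lr 5e-4, weight decay 1e-4; 500 pretraining + 1000 fine-tuning
epochs by default. Domains come from an in-package EM Gaussian mixture
(shared full covariance); evaluation covers ARI, NMI/AMI/ACC, V-measure
and perplexity-calibrated iLISI/cLISI.

## Worked example

```r
library(spatchwork)

res <- run_pipeline(default_config(
  simulate   = list(n_slices = 3, spots_per_slice = 600, n_genes = 300,
                    n_domains = 5, batch_strength = 0.5),
  preprocess = list(n_components = 50),
  training   = list(epochs_pretrain = 200, epochs_finetune = 300),
  clustering = list(n_domains = 5),
  seed = 1L))
res$metrics
```

On this synthetic three-slice dataset (1800 spots, 5 shared band domains,
strong per-slice batch effects) the run above prints:

```
ari             0.9549
ari_paper_form  0.9549
nmi             0.9417
ami             0.9416
acc             0.9416
hom             0.9417
com             0.9417
v_measure       0.9417
ilisi_mean      1.7479
clisi_mean      1.0412
```

Read: the recovered domains agree with the generating labels at ARI 0.95;
each spot's embedding neighborhood contains on average 1.75 effective
slices out of 3 (raw PCA: 1.35 — batches are measurably better mixed) and
1.04 effective domains (close to the ideal 1, i.e. domain-pure
neighborhoods). Downstream, `denoise_expression()` maps decoder output
back to gene space, `rank_markers()` ranks per-domain markers
(Wilcoxon + BH), and `center_align_stack()` builds 3D coordinates.

A command-line surface with `simulate`, `run`, `evaluate` and `ablate`
subcommands lives at `inst/cli/spatchwork.R`; configs are YAML or JSON
(`read_config()`).

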
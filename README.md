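# paratopeR

Chain-aware, sequence-only prediction of antibody paratopes — the residues
of a heavy or light variable domain that contact the antigen — at
single-residue resolution.

## Who this is for and what it does

In early-stage antibody discovery there are usually thousands of candidate
sequences and no structures. paratopeR predicts, for every residue of a
VH/VL domain (~110–130 residues), the probability that it is a binding
residue, using nothing but the amino-acid sequence. The package contains
the full experimental workbench around the model: dataset I/O and
validation, complex-level blind splitting and stratified grouped
cross-validation, masked class-weighted training, an imbalance-robust
evaluation panel, a 30-configuration sweep (2 encodings × 3 chain regimes
× 5 kernel sizes), a synthetic paired-chain data generator with planted
binding motifs so everything is testable offline, and a scriptable CLI.

## The model

Residues are encoded as 21-dimensional one-hot vectors or learnable
embeddings (20 amino acids + `X`), zero-padded to L = 130 with a mask
*m<sub>t</sub>*. A single bidirectional LSTM (hidden size 64 per
direction) produces contextual vectors
*h<sub>t</sub>* = *h⃗<sub>t</sub>* ⊕ *h⃖<sub>t</sub>* ∈ ℝ¹²⁸; a
length-preserving ("same"-padded) 1D convolution with kernel size
k ∈ {7, 15, 31, 71, 130} and 64 channels extracts local motif features
*z<sub>t</sub>* = ReLU(Σᵢ wᵢ·h<sub>t+i</sub> + b) without pooling; a
per-position dense layer and sigmoid yield binding probabilities
*p<sub>t</sub>*. Dropout (p = 0.3) is applied after the embedding, the
BiLSTM and the convolution during training.

Because binding residues are only ~10% of positions, training minimizes a
masked, class-weighted binary cross-entropy

> L = −Σₜ mₜ [w⁺ y*ₜ log pₜ + w⁻ (1−y*ₜ) log(1−pₜ)] / Σₜ mₜ,

with w⁺ = N<sub>neg</sub>/N<sub>pos</sub> recomputed from each training
split and w⁻ = 1, optimized with Adam (lr = 0.001) and MCC-based early
stopping (patience 5). The forward and backward passes (BiLSTM, conv,
dense, dropout, Adam) are implemented in R on BLAS matrix operations and
are verified in the test suite against finite-difference gradients and
nested-loop oracles. All splits are grouped at the antibody-complex level
so paired H and L chains can never leak across a training/validation or
blind boundary.

## Worked example

Simulate a paired-chain dataset with planted binding motifs, hold out a
blind set, train a heavy-chain model, and evaluate:

```r
library(paratopeR)

ds <- generate_dataset(generator_spec(n_complexes = 60, seed = 7))
dataset_summary(ds)
#> 60 complexes, 120 chains, 14400 residues, 1501 binding (10.42%)
#>  chain_type n_chains n_residues n_binding binding_fraction
#>           H       60       7192       748        0.1040044
#>           L       60       7208       753        0.1044673

sp <- split_blind(ds, blind_fraction = 0.2, seed = 7)
fit <- train_model(
  model_config(encoding = "onehot", kernel_sizes = 31L, seed = 7),
  train_config(max_epochs = 12L, seed = 7),
  select_chain_regime(sp$modeling, "H"),
  select_chain_regime(sp$blind, "H"))
fit$best_epoch            # 11
fit$loss_spec$w_plus      # 8.65  (negative/positive residue ratio)

evaluate_blind(fit$state, select_chain_regime(sp$blind, "H"),
               train_ids = complex_ids(sp$modeling))
#> <metrics_report> 12 chains, 1450 residues, threshold 0.50
#>       AUC    PR AUC  Accuracy Precision    Recall        F1       BAC       MCC
#>     0.953     0.705     0.902     0.522     0.856     0.649     0.882     0.620
```

The summary line shows the generator hitting its ~10.4% positive-residue
target; `w_plus` is the resulting class weight; the report is the pooled
(micro-averaged) panel over all real residues of the blind heavy chains.
At this deliberately small scale the model already ranks residues well
(AUC 0.95, PR AUC 0.71); with the 200-complex default protocol the blind
MCC rises above 0.8 (see below). Larger runs, the 30-configuration sweep
and per-residue prediction files are available through the CLI:

```sh
inst/exec/paratope simulate --n 200 --seed 1 --out data.tsv
inst/exec/paratope split    --data data.tsv --seed 1 --out plan.tsv
inst/exec/paratope train    --data data.tsv --plan plan.tsv --regime H --kernel 31 --outdir run/
inst/exec/paratope predict  --checkpoint run/checkpoint.rds --data data.tsv --out pred.tsv
```

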
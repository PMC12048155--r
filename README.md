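# structvep

Structure-informed, zero-shot prediction of protein variant effects in R.

## What it is for

Protein engineers need to rank candidate substitutions — "is A24G more likely
to keep this enzyme folded and active than T56W?" — usually with no labelled
data for the protein at hand. `structvep` implements a self-supervised
sequence-plus-structure encoder for this zero-shot setting: a protein backbone
becomes a k-nearest-neighbour residue graph with geometric edge features, a
roto-translation **equivariant graph neural network** (EGNN) is pre-trained to
**recover wild-type residues from randomly perturbed observations**, and a
mutant is scored by the **log-odds ratio** under the trained model's per-site
token distribution:

```
F_x = Σ_{t ∈ T}  log p(y_t) − log p(v_t)
```

where `T` is the set of mutated sites, `y_t` the mutant residue and `v_t` the
wild-type residue. One forward pass on the wild type serves every mutant of a
protein, and scores are additive over disjoint site sets. Per layer, the EGNN
updates features and coordinates as

```
m_ij = φ_e(w_i, w_j, ‖x_i − x_j‖², a_ij)
x_i  ← x_i + (1/n) Σ_j (x_i − x_j) φ_x(m_ij)
w_i  ← φ_v(w_i, Σ_j m_ij)
```

so node features are invariant, and coordinates equivariant, under rigid
motions of the input structure.

The package also provides the surrounding tooling: PDB backbone parsing with
virtual C-beta construction, the 33-token sequence vocabulary and perturbation
strategies (multinomial replacement, BERT-style 15%/80-10-10 masking, Gaussian
embedding noise of variance 0.5, embedding recoding), token-budget batching
(8192 residues) with a 2000-residue corpus filter, deep-mutational-scanning
assay curation for thermostability benchmarks (ΔTm / ΔΔG conventions),
Spearman-ρ evaluation with an assay-level bootstrap summary, and a synthetic
fixture generator (ideal α-helical backbones, planted-signal assays) so the
entire pipeline runs and is tested fully offline. Gradients for the EGNN are
derived by hand and verified against finite differences.

## Worked example

The end-to-end pipeline generates a three-helix corpus, trains a desk-scale
denoiser, creates noise-free planted-signal assays, scores them both with the
planted (known-answer) model and the trained model, and summarises per-assay
rank correlations with a 50%/10-run bootstrap:

```r
library(structvep)
res <- run_planted_pipeline(tempfile("demo"), seed = 7, epochs = 200)

glance(res$model)
#> # A tibble: 1 × 6
#>   layers hidden     k n_parameters epochs final_loss
#>    <int>  <int> <int>        <dbl>  <int>      <dbl>
#> 1      6     32    10        64391    200      0.961

res$planted
#> <vep_eval> 3 assay(s); macro-mean Spearman rho = 1.000
#>   bootstrap (frac 0.5, 10 runs): mean 1.000, sd 0.000

res$trained
#> <vep_eval> 3 assay(s); macro-mean Spearman rho = -0.054
#>   bootstrap (frac 0.5, 10 runs): mean -0.062, sd 0.009
```

Reading the numbers: the planted scorer recovers the assay ranking exactly
(ρ = 1 on every assay, zero bootstrap spread) — the evaluation machinery is
exact end to end. The trained toy model's correlation against this *random*
planted table is ~0 by construction (the planted scores share nothing with
the denoising task); its training is measured instead by the loss trace
(`autoplot(res$model)`) falling from the uniform-guess level ln 33 ≈ 3.50 and
by wild-type recovery, e.g. at 600 epochs on the default corpus:

```r
corpus <- make_corpus(fixture_spec(n_proteins = 3, length_range = c(30, 30), seed = 1))
model  <- train_denoiser(corpus,
                         graph_conf = graph_config(k = 10),
                         egnn_conf  = egnn_config(layers = 6, hidden = 64,
                                                  input_dim = 33, message_dim = 64),
                         train_conf = train_config(lr = 2e-3, epochs = 600, seed = 1))
mean(tail(model$trace$loss, 20))   # 0.238  (per-token cross-entropy)
recovery_rate(model, corpus)       # 0.989  (argmax residue recovery)
```

Scoring real-style inputs follows the tidy data-frame-first pattern:

```r
scored <- assay_tbl |>                      # columns: protein_id, mutant, score, ph
  curate_assays(mode = "dtm") |>
  score_variants(model, structure = wt_structure)
evaluate_assays(scored) |> add_bootstrap(seed = 1) |> glance()
```

A command-line wrapper is installed with the package
(`system.file("cli", "structvep.R", package = "structvep")`) with subcommands
`make-fixtures`, `train`, `score`, `eval` and `pipeline`.

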
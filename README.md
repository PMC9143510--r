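# phenodnn

Deep feedforward classification of host phenotype from taxonomic
abundance profiles.

Microbiome composition carries a strong signature of its host's state:
gut metagenomes separate cirrhosis patients from healthy controls,
type-2-diabetes cohorts from non-diabetic ones, obese animals from lean
ones. `phenodnn` is for researchers who already have taxonomic profiles —
from Kraken2, MetaPhlAn, or any pipeline that can emit an OTU table — and
want to train a classifier that predicts a sample's phenotype from its
profile, tune it without hand-picking architectures, and apply the saved
model to new, unlabeled samples.

## What it does

1. **Ingest** profiles in three dialects — generic TSV OTU tables
   (lineage rows × sample columns), per-sample Kraken2 report files
   (lineages reconstructed from indentation and rank codes), and
   MetaPhlAn-style merged percent tables — and join them with a
   `sample_id → label` metadata TSV.
2. **Preprocess** with a fixed pipeline: restrict to one taxonomic rank
   (default species), convert to relative abundance (percent), drop taxa
   whose maximum abundance over the training samples is below a threshold
   (default 0.03%), and normalize by cumulative sum scaling (CSS): for
   sample *j*, the factor is
   s_j = Σ_i v_ij · [v_ij ≤ q_l(j)], the sum of the sample's values at or
   below the *l*-th quantile of its positive values (default l = 0.5),
   and normalized values are v′_ij = v_ij / s_j × median(s). Data are
   split 15% test / 15% validation, stratified by class.
3. **Train** a deep feedforward network: `n_layers` hidden linear layers
   (default 10) of `n_neurons` units (default 25), each followed by an
   ELU activation and an optional dropout layer (default rate 0.5), then
   a linear output layer with a prediction-time softmax giving an M×N
   matrix of class probabilities. Optimization is mini-batch Adam
   (default batch 50, 20 epochs) on the cross-entropy loss, default
   learning rate 3e-5 and weight decay 0, with best-epoch checkpointing
   on validation accuracy.
4. **Tune** with a randomized grid search over layers 5–75, neurons 5–75,
   dropout on/off with rate 0.1–0.9, learning rate 5e-6–5e-4
   (log-uniform) and weight decay 0–0.1, stopping once 10 consecutive
   trials fail to improve the best validation accuracy.
5. **Evaluate** with accuracy, precision, recall, F1, ROC/AUC and a
   confusion matrix, plus stratified k-fold cross-validation, and
   **persist** models as a single archive that reloads to bit-identical
   predictions.

A seeded synthetic generator (`synth_config()` / `synth_generate()`)
produces labeled case/control tables — log-normal abundances,
compositional closure, sparsity, a multiplicative effect on a set of
informative taxa — so the whole pipeline is testable without downloading
any cohort.

## Worked example

```r
library(phenodnn)

gen <- synth_generate(synth_config(n_per_class = c(60L, 60L), n_taxa = 120L,
                                   n_informative = 15L, seed = 42))
model <- fit_phenodnn(gen$table, gen$meta,
                      preprocess_config(seed = 42),
                      network_config(n_layers = 2L, n_neurons = 32L,
                                     dropout_enabled = FALSE,
                                     learning_rate = 1e-3, epochs = 100L,
                                     seed = 42))
model
#> <phenodnn_model> 120 taxa -> class_0/class_1
#>   layers: 2 x 32, dropout off, 4994 parameters
#>   normalization: CSS(q = 0.5, ref = 11.33)

feats <- preprocess_apply(gen$table, model$retained_taxa, model$pre_config,
                          model$normalization)
te <- model$split$test_ids
truth <- unname(model$labels$label_index[gen$meta$mapping[te]])
evaluate_model(model, feats[te, , drop = FALSE], truth)
#> <evaluation_report> accuracy 1.000  precision 1.000  recall 1.000  f1 1.000  auc 1.000
#> confusion (rows = true):
#>      [,1] [,2]
#> [1,]    9    0
#> [2,]    0    9
```

All 120 taxa pass the default abundance filter here; the 18 held-out
samples (15% of 120, stratified 9 + 9) are classified perfectly because
15 informative taxa carry a 3-log-unit fold change — an easy benchmark
whose point is to verify signal recovery end to end. `predict_table()`
applies the saved preprocessing to raw profiles of unknown samples and
returns a label and per-class probabilities per row.

The same pipeline is scriptable from a shell:

```sh
phenodnn simulate --out fixture --seed 1
phenodnn train  --profile fixture/otu_table.tsv --metadata fixture/metadata.tsv --out run --seed 1
phenodnn tune   --profile fixture/otu_table.tsv --metadata fixture/metadata.tsv --out tuned --max-iter 10 --seed 1
phenodnn predict --model run/model.tar.gz --profile fixture/otu_table.tsv --out run
```

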
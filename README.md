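# StructDTA

Structure-aware drug–target binding affinity prediction in R.

## What this is for

Estimating how tightly a small molecule binds a protein — the
drug–target affinity (DTA), expressed as pKd = −log10 Kd — is a routine
question in early drug discovery. Sequence-only predictors ignore the
3D context in which binding happens; StructDTA is for computational
chemists and method developers who have protein structures (PDB), a
designated binding pocket (a PDB subset) and ligand files (SDF/MOL2)
and want an end-to-end, fully inspectable regression pipeline that
fuses sequence and structural knowledge.

## The model

Each complex contributes three graphs:

* **target**: residues as vertices (C-alpha positions), an edge whenever
  two C-alphas lie within 8 Å (Euclidean, closed cutoff);
* **pocket**: the same construction over the pocket residues only;
* **drug**: heavy atoms as vertices, covalent bonds from the ligand file
  as edges.

Per stream the model computes

    one-hot sequence ──1D-CNN (kernel 5 target / 3 pocket, 128 ch)──┐
                                                                    ├─► 3-layer GNN (32→64→128) ─► mean readout ─► linear →256
    27-dim one-hot atom features (drug stream, no CNN) ─────────────┘

and the three projected 256-vectors concatenate to 768, pass through a
fully connected head (768→256, LeakyReLU, dropout 0.4, 256→1) to the
predicted pKd. The default GNN layer is GraphSAGE (mean neighbor
aggregation + self term); GCN, single-head GAT and GIN are selectable,
as are LSTM/BiLSTM/CNN+LSTM sequence encoders and a `none` ablation
that feeds one-hot features straight to the GNN. Training minimizes the
MSE with Adam (defaults: lr 1e-4, batch 128, 300 epochs, dropout 0.4).
Evaluation reports MAE, RMSE, Pearson, Spearman, concordance index and
R². For interpretability, unparameterized scaled dot-product attention
between pre-pooling drug and target vertex embeddings yields
row-stochastic atoms→residues and residues→atoms score matrices, from
which top-k pocket-hit and atom-coverage statistics are derived.

The entire network — convolution, LSTM, all four GNN families,
attention, backpropagation, Adam — is implemented in R with explicit
analytic backward passes (verified against finite differences in the
test suite); sparse block-diagonal batching comes from the `Matrix`
package, file parsing from `bio3d` (PDB, MOL2) and `ChemmineR` (SDF).

## Worked example

The package ships a seeded generator of synthetic complexes whose
affinity follows a planted law on pocket residue composition, so the
whole pipeline runs without external data:

```r
library(StructDTA)

dataDir  <- file.path(tempdir(), "demo")
manifest <- generateDataset(synthSpec(nComplexes = 60, noiseSd = 0.2,
                                      seed = 42), dataDir)
cfg     <- modelConfig()
samples <- featurizeDataset(manifest, cfg)
samples[[1]]
#> ComplexSample 'cplx_0001': 46 residues (pocket 12), 6 heavy atoms, pKd 8.266

fit   <- trainModel(samples[1:50], cfg,
                    trainConfig(epochs = 80, learningRate = 1e-3,
                                batchSize = 16, valFraction = 0.1, seed = 42))
preds <- predictAffinity(fit, samples[51:60])
head(preds, 3)
#>           complex_id   y_true   y_pred
#> cplx_0051  cplx_0051 6.545400 7.055299
#> cplx_0052  cplx_0052 7.348178 6.989493
#> cplx_0053  cplx_0053 8.638031 8.406621

computeMetrics(preds$y_true, preds$y_pred)
#> MetricsReport (n=10): MAE 0.4785  RMSE 0.5591  PCC 0.7893  Spearman 0.6606  CI 0.7556  R2 0.5983
```

Ten held-out complexes are predicted with a Pearson correlation of 0.79
and a concordance index of 0.76 against label noise of 0.2 pKd units —
the model has recovered most of the planted pocket-composition signal
from fifty training complexes. Attention statistics for one complex:

```r
ir <- interpretComplex(samples[[51]], fit$params, cfg)
ir$residueHits           # fraction of per-atom top-k residues in the pocket
#>  top5 top10 top20
#>  0.46  0.49  0.34
ir$atomCoverage          # fraction of heavy atoms picked by any residue's top-k
#> top3 top5 top8
#>  0.4  0.7  0.9
```

With 12 of 46 residues in the pocket, a random ranking would hit about
0.26 — the trained model's top-5/top-10 attention residues land in the
pocket roughly twice as often.

A command-line interface wraps the same functions
(`simulate`, `featurize`, `train`, `evaluate`, `predict`, `explain`):

```sh
Rscript inst/cli/structdta simulate --spec spec.yaml --out data/
Rscript inst/cli/structdta train --manifest data/manifest.csv --config run.yaml --out run/
Rscript inst/cli/structdta evaluate --manifest data/manifest.csv \
        --checkpoint run/checkpoint.rds --out metrics.json
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/structio.R` | PDB / SDF / MOL2 / PSSM / HHM / manifest readers, prediction tables |
| `R/encoders.R` | label, one-hot, physico-chemical encoders; fixed-length padding |
| `R/graphs.R` | contact and molecular graph construction, batching, archives |
| `R/nn-layers.R`, `R/network.R` | layers with analytic backward passes; the heterogeneous model |
| `R/trainer.R` | seeded Adam training, validation, checkpoints |
| `R/metrics.R` | the six evaluation metrics |
| `R/interpret.R` | attention top-k statistics and selection exports |
| `R/synthdata.R` | synthetic complex generator with planted affinity law |
| `R/cli.R`, `inst/cli/structdta` | command-line interface |
| `vignettes/structdta-methods.Rmd` | model, assumptions, design choices, limitations |
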
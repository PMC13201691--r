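# squeezevit

Multi-label classification of chest radiographs needs models small enough
for modest clinical hardware. `squeezevit` implements **SqueezeViT**, a
lightweight hybrid CNN/vision-transformer classifier, in pure R (with a
small C++ kernel layer): parameter-efficient **Fire modules** (1×1 squeeze
to `C_s = max(1, ⌊C_in/2⌋)` channels, then parallel 1×1/3×3 excitations
concatenated to the target width) learn local structure, and a
**Translution Block** — Fire expansion 128→256, Fire squeeze 256→64 tokens,
order-preserving 4×4 patch tokenization, a pre-norm transformer encoder with
scaled dot-product attention

```
Attention(Q, K, V) = softmax(Q Kᵀ / √d_k) V
```

(no positional embeddings), 1×1-conv projection, channel-doubling fusion
(`C_out = 2C`) and Fire reduction back to 128 — supplies global context at
constant spatial resolution. The full network is

```
224×224×1 → stem (3×3 conv s2 → 3 ch; 3×3 maxpool s2)
          → Stage 1: Fire Block 3→32→64→64→128, 3×3 maxpool   (56→28)
          → Stage 2: Translution Block (shape-preserving, 28×28×128)
          → Stage 3: Fire 128→256, 3×3 maxpool, 1×1 conv 256→256,
                     global average pooling, FC → L logits
```

The package also provides analytic parameter/MAC accounting with reduction
percentages against published baseline budgets, the reference training
recipe (sigmoid BCE, Adam, lr 1e-4, batch 64, from scratch), class-wise and
average AUROC (Mann–Whitney midranks), macro F1, percentile-bootstrap
confidence intervals, an NIH ChestX-ray14-style CSV manifest reader, and a
seed-deterministic synthetic multi-label image generator with planted
class-specific patterns, so the entire pipeline runs without external data.

## Worked example

```r
library(squeezevit)

## the model and its complexity budget
model <- build_squeezevit()           # default: 14-class head, 224×224×1
report <- complexity_report(model)
report$params                         # 539136  (= 0.54 × 10^6)
round(report$macs / 1e9, 2)           # 0.48    (MACs per image, × 10^9)

refs <- reference_budgets()           # published baseline budgets
reduction_percent(report$params / 1e6,
                  refs$params_millions[refs$model == "MobileViT"])  # 43.2
reduction_percent(report$params / 1e6,
                  refs$params_millions[refs$model == "ResNet"])     # 95.4

## a fully synthetic study: 200 images, 14 planted finding patterns
dir <- tempfile()
man <- generate_synthetic(synthetic_spec(n_images = 200, seed = 1), dir)
imgs <- load_images(man)
y <- label_matrix(man)

## fixture sanity check: a matched-filter oracle must separate the classes
oracle <- classwise_auroc(matched_filter_scores(imgs, 14), y)
round(oracle$average, 3)              # 0.998

## the reference recipe, scaled to desk size (15 epochs on one CPU)
fit <- train(model, imgs, y,
             train_spec(epochs = 15, micro_batch = 25, seed = 1))
fit$history$loss[c(1, 15)]            # 0.782 0.483  (train loss falls)
ev <- evaluate(fit$model, imgs, y)
round(ev$average, 3)                  # 0.734  (mean training AUROC)
autoplot(fit$history)                 # loss curve
```

The interpretation: `0.54 × 10⁶` trainable parameters is the architecture's
printed budget, and the two percentages are its headline parameter
reductions against the MobileViT and ResNet reference budgets. The
matched-filter AUROC near 1 certifies that the synthetic classes are
separable *before* any training, so the training AUROC measures the
optimiser and architecture, not the fixture. Fifteen epochs on 200 images
give only 60 optimiser updates at learning rate 1e-4 — enough for a clear
descent and well-above-chance ranking, far short of convergence (the same
run continued to the recipe's full 100 epochs reaches a mean training AUROC
of 0.80, still improving when the schedule ends; with a freer optimiser
budget the network fits such data essentially perfectly).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/squeezevit.R synth --n 200 --seed 7 --out data/
Rscript inst/cli/squeezevit.R train --data data/ --epochs 5 --out run/
Rscript inst/cli/squeezevit.R eval  --data data/ --checkpoint run/model.rds --out eval/
Rscript inst/cli/squeezevit.R profile --report-json --out prof/
Rscript inst/cli/squeezevit.R ablate --which no_translution --data data/ --out abl/
```

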
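# mtpaunet

Retinal vessel segmentation with **MTPA_Unet**, a serial Transformer + CNN
encoder–decoder, implemented natively in R.

## The problem and who this is for

Automatic segmentation of blood vessels in fundus photographs underpins
screening for hypertensive and diabetic retinopathy: vessel calibre,
tortuosity and density are clinical markers, and the hard part is the
one-to-two-pixel capillaries rather than the main trunks. This package is
for researchers in retinal image analysis who want a fully inspectable,
dependency-light R implementation of a modern hybrid
Transformer–convolutional segmentation network — including training — plus
a seeded synthetic fundus generator so the whole pipeline runs and is
tested without downloading any clinical dataset.

## The model

MTPA_Unet processes 64×64 patches as a multi-scale pyramid (64/32/16/8)
through four Transformer stages (channels 32/64/128/256) whose core is the
**TPA block**:

* **TMSA** — multi-head self-attention with queries at full resolution and
  keys/values from a spatially reduced map (strided convolution, factors
  8/4/2/1 per stage). Per-head logits `Q·Kᵀ/√d_k` are mixed across the
  head axis by a learned 1×1 convolution *before* the softmax over keys,
  then a residual feed-forward network follows.
* **Criss-cross position attention, applied twice** — each pixel attends
  to the `H+W−1` positions in its row and column; two shared-weight passes
  connect every pixel pair at a fraction of full-attention cost.

Stage outputs feed a convolutional encoder (feature-extraction blocks with
parallel conv/transposed-conv branches; adaptive-pooling downsampling),
all encoder levels are fused into a pyramid-pooling bottom
(shallow-information fusion), and a decoder with *additive* residual skips
restores resolution to a sigmoid vessel-probability head. Training
minimizes the soft Dice loss `1 − (2Σpg + w)/(Σp + Σg + w)`; evaluation
reports Dice, Accuracy, Sensitivity `TP/(TP+FN)`, Specificity
`TN/(TN+FP)`, Precision `TP/(TP+FP)` and trapezoidal AUCs of the ROC and
precision–recall sweeps, inside the circular field of view.

The network, and the reverse-mode automatic-differentiation engine it
runs on, are implemented in this package (R arrays + C++ kernels for
convolution, batched matrix products, softmax and the fused criss-cross
attention). Preprocessing follows the published chain: weighted RGB fusion
(R 0.299 / G 0.587 / B 0.114), per-image standardization, CLAHE
(via EBImage), gamma correction.

## Worked example

Train the desk-scale profile (the same architecture at width 8/16/32/64,
~264 k parameters) on synthetic fundus images and evaluate on held-out
ones:

```r
library(mtpaunet)

samples <- make_dataset(8, synth_config(size = 128, target_density = 0.10,
                                        seed = 501))
ctl <- train_control(epochs = 20, patches_per_image = 10, batch_size = 8,
                     seed = 1)
fit <- mtpa_fit(samples[1:5], model = mtpa_config("desk"), control = ctl)
print(fit)
#> MTPA_Unet fit (desk profile): 264,064 parameters
#>   trained 120 steps (20 epochs); best validation Dice 0.8831 at epoch 14

ev <- evaluate(fit, samples[6:8])
round(unlist(ev$aggregate), 4)
#>        dice    accuracy sensitivity specificity   precision     auc_roc
#>      0.9035      0.9802      0.9286      0.9860      0.8800      0.9960
#>      auc_pr
#>      0.9684
```

A Dice of ~0.90 on unseen synthetic images after two minutes of CPU
training says the implementation learns vessel geometry; it is not a claim
about clinical images. `predict(fit, sample)` returns a
`segmentation_result` with the stitched probability map and the
thresholded mask; `plot(fit)` shows the loss/validation trace; `coef(fit)`
the learned weights.

The full-size reference model is available as `mtpa_config("paper")`:

```r
count_parameters(mtpa_config("paper"))
#> [1] 11782624      # 11.8 M trainable parameters
```

A thin command-line interface wraps the same functions
(`inst/cli/mtpa_cli.R`; subcommands `simulate`, `preprocess`, `train`,
`predict`, `eval`, `loo`).

## Package layout

* `R/autograd.R`, `R/ops.R`, `src/kernels.cpp` — the autodiff engine.
* `R/attention.R` — patch embedding, positional encoding, TMSA,
  criss-cross position attention, TPA block.
* `R/backbone.R` — FE/DS blocks, SCI fusion, pyramid-pooling bottom,
  decoder, model assembly, parameter counting.
* `R/preprocess.R` — enhancement chain, patch pyramids, stitching.
* `R/synthetic.R` — seeded synthetic fundus generator and DRIVE-style IO.
* `R/metrics.R` — Dice, confusion metrics, ROC/PR areas.
* `R/train.R`, `R/fit.R` — Adam training, evaluation, leave-one-out,
  checkpoints, and the `mtpa_fit` S3 interface.
* `vignettes/mtpa-unet-methods.Rmd` — model, assumptions, design choices.
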
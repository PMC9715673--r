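# saliret — saliency-guided content-based medical image retrieval

Radiologists looking for reference cases need the catalogue image that is
most similar to their query *in terms of disease and disease severity* —
which is rarely the image that is most similar overall, because global
appearance is dominated by anatomy, positioning and exposure rather than by
the small image region that carries the pathology. `saliret` implements a
disease-targeted retrieval pipeline built on model interpretability:

1. train a binary disease classifier (a dense-block CNN) on labelled
   grayscale images;
2. derive per-pixel **Deep Taylor** relevance maps `S(θ_CNN, I)` from the
   trained classifier (z⁺ rule in hidden layers, bounded rule at the pixels,
   non-negative and conservation-checked);
3. retrain the same architecture **on the saliency maps** and retrieve by
   Euclidean distance between penultimate-layer embeddings:

   `d_IG(I_t, I_c) = || F(θ_IG, S(θ_CNN, I_t)) − F(θ_IG, S(θ_CNN, I_c)) ||₂`

Baselines for comparison: SSIM on raw images, plain CNN features
(`d_CNN = ||F(θ_CNN, I_t) − F(θ_CNN, I_c)||₂`), the ablation CNN(IG)
(saliency maps fed to the raw-image network), and an attention-driven
comparator ATT (per-tap self-attention + softmax-gated multi-level fusion).
Rankings are scored against a severity ground truth with the normalised
discounted cumulative gain,

`nDCG_p = DCG_p / IDCG_p`, `DCG_p = Σ_{i=1..p} (2^{rel_i} − 1) / log2(i+1)`,

with relevance linear in ground-truth rank: 5.5 for the most similar down to
1 for the least similar of a 10-image catalogue (step 0.5).

Because clinical ranking ground truth requires expert annotation, the
package ships a synthetic **phantom radiograph** generator with a known
continuous severity: elliptical thorax archetypes create dominant,
disease-irrelevant appearance variation, and a severity-scaled basal wedge
(or blob) lesion creates the disease signal — so "globally similar" and
"disease-similar" are decoupled by construction and every component can be
tested end-to-end on a laptop CPU. The neural-network engine (convolutions,
dense blocks, backprop, Adadelta/Adam) is implemented in R with C++ kernels;
no external deep-learning framework is required.

## Worked example

```r
library(saliret)

cfg <- run_config(seed = 1)        # defaults: 600/100/100 phantoms at 96x96,
                                   # 10 epochs/model, 10 splits of 10 images
dir <- tempfile("saliret-run-")
ev <- run_benchmark(cfg, dir)      # generate -> train cnn, ig, att ->
                                   # rank 5 methods -> score with nDCG
aggregate(ndcg ~ method + p_eval, ev$per_split, mean)
```

During the run each trained model reports its selected epoch:

```
generated 800 phantoms (400 positive), 10 splits
cnn: selected epoch 10, validation F1 0.891
ig: selected epoch 1, validation F1 0.891
att: selected epoch 7, validation F1 0.949
```

and the final table gives the mean nDCG per method at both truncations
(Top-10 over the full catalogue, Top-3 over the first three retrieved
images); with `seed = 1` this prints:

```
   method p_eval      ndcg
1     att      3 0.7557492
2     cnn      3 0.5247526
3  cnn_ig      3 0.6386582
4      ig      3 0.7025536
5    ssim      3 0.4482257
6     att     10 0.8739956
7     cnn     10 0.7551272
8  cnn_ig     10 0.8305184
9      ig     10 0.8628929
10   ssim     10 0.7168113
```

Higher is better; 1.0 means the method reproduced the severity ground-truth
ranking exactly. The pattern is the method's mechanism at work: whole-image
similarity (`ssim`) is the floor, plain classifier features (`cnn`) improve
on it, feeding Deep Taylor saliency maps to the same network (`cnn_ig`)
improves it further, and retraining on the maps (`ig`) is better still —
disease-focused inputs beat whole-image inputs for severity ranking. The interpretability-guided method (`ig`) is the package's
main subject; `ssim` is the floor set by whole-image similarity. Per-split
values, five-number summaries, retrieval CSVs, checkpoints and training
logs are written into `dir`.

Individual pieces are available as plain functions: `generate_dataset()`,
`make_splits()`, `build_backbone()`, `train()`, `deep_taylor()`,
`conservation_report()`, `build_attention_model()`, `ssim()`,
`rank_catalogue()`, `ndcg()`, `evaluate_methods()`, `interrater()`. A thin
command-line front-end lives at `inst/cli/saliret.R`
(`generate | train | saliency | retrieve | evaluate | benchmark`).

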
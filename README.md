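# seizenet

Seizure recognition from fixed-length single-channel EEG segments with an
adaptive spectral-selection, multi-scale attention, and phase-aware fusion
network — implemented entirely in base R matrix algebra, including the
backward pass, so the model trains without any deep-learning framework.

## The problem and who this is for

Automated seizure detection classifies short EEG windows as seizure or
non-seizure. Three properties of epileptic EEG make fixed feature pipelines
brittle: the discriminative frequency bands vary across patients; discharges
mix slow macro-rhythms with fast micro-transients; and multi-branch networks
fuse features whose waveforms are not phase-aligned. This package is for
researchers who want a transparent, fully inspectable reference
implementation of a network that addresses all three — every forward and
backward computation is plain R, unit-tested against closed forms, naive
loop oracles, and finite differences — together with a synthetic EEG
benchmark that makes each mechanism measurable without access to clinical
data.

## The model

For a segment batch $X \in \mathbb{R}^{B\times L}$ (default $L=1228$ at
256 Hz):

1. **Dynamic frequency selection.** One-sided FFT
   $F \in \mathbb{C}^{B\times N}$, $N = \lfloor L/2\rfloor + 1$; a two-layer
   ReLU perceptron scores each bin from the amplitude spectrum $|F|$; a
   Gumbel-SoftMax at temperature $\tau$ turns scores into a per-segment
   probabilistic mask $W$ (rows sum to 1, differentiable); the spectrum is
   filtered $\tilde F = F \otimes W$ and inverted back to the time domain.
2. **Multi-scale extraction.** Window-mean pooling to scales
   $[1228, 614, 307]$, scalar-to-$D$ embedding per scale, and multi-head
   self-attention with shared QKV and per-head learnable temperature
   $\tau_h = e^{\lambda_h}$, $\lambda_h$ initialized to $\ln(D/H)$.
3. **Phase-aware fusion.** A learnable waveform template (mixed with a fixed
   impulse prior, softmax-normalized) slides over the signal; time-softmax
   attention enhances matching regions; per scale, a small network estimates
   a signed phase offset between attended features and the aligned enhanced
   signal, and a sigmoid gate $\Gamma$ blends them convexly:
   $F_i = \Gamma A_i + (1-\Gamma)\tilde X_i$. Temporal means are
   concatenated into a two-class softmax head.

Evaluation uses accuracy, sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, and $F1 = 2TP/(2TP+FP+FN)$, plus paired t-tests over repeated
runs, a repeated mixed-split generalization protocol, AB1/AB2/AB3 ablation
variants, and control-variable hyperparameter sweeps.

## Worked example

```r
library(seizenet)

# a small synthetic study: 1 s segments at 128 Hz, 10% seizure prevalence,
# 3-8 Hz discharges over high-passed pink noise
ds  <- make_dataset(benchmark_synth_config(n_samples = 1000))  # ~10% seizure
res <- evaluate_on_split(benchmark_model_config(seed = 1), ds, seed = 1)
res$metrics
#> # A tibble: 1 x 9
#>      tp    tn    fp    fn   acc  sens  spec    f1 positive_class
#>   <int> <int> <int> <int> <dbl> <dbl> <dbl> <dbl>          <int>
#> 1    19   180     0     1 0.995  0.95     1 0.974              1
```

Of the 20 held-out seizure segments, 19 are recovered (sensitivity 0.95)
with no false alarms among the 180 background segments (specificity 1).
The learned spectral mask can be inspected directly — on seizure segments
its mean weight concentrates inside the planted 3-8 Hz band:

```r
band_mask_ratio(res$fit, ds$segments[ds$labels == 1, ], c(3, 8))$ratio
#> [1] 1211.534   # in-band mean weight vs out-of-band mean weight
```

A command-line surface wraps the same functions
(`inst/cli/seizenet simulate|train|evaluate|ablate|sweep|ttest|export-mask`);
every run logs its configuration hash and seed, so results are reproducible
from the log line.

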
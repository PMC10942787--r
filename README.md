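# spikemux

Bayesian classification of trial-to-trial multiplexing in neural
spike-count data.

## The problem

When two stimuli, A and B, both drive a neuron — two adjacent gratings or
dot patches in an MT receptive field, two faces in an IT face patch's
field — what does the neuron's response to the pair (AB) look like? Four
answers are possible, and they correspond to four models of the per-trial
AB spike-count distribution, each built from Poisson models anchored to
the single-stimulus responses:

- **mixture** — each AB trial follows the A rate with probability α and
  the B rate otherwise: the AB histogram is a bimodal mixture of the A
  and B distributions. This is the signature of *multiplexing*: the
  neuron alternates between representing the two stimuli across trials.
- **intermediate** — every AB trial shares one rate
  `α·λ_A + (1−α)·λ_B` strictly between the single-stimulus rates
  (averaging, or switching faster than the counting window).
- **single** — the AB rate matches exactly one of λ_A or λ_B
  (winner-take-all with a constant winner).
- **outside** — the AB rate lies above both or below both
  single-stimulus rates (summation or strong suppression).

spikemux screens matched A/B/AB count samples ("triplets") for adequacy,
computes the marginal likelihood of the AB counts under each of the four
hypotheses — integrating λ_A and λ_B over their conjugate Gamma
posteriors and α over Uniform(0,1) with deterministic Gauss quadrature —
and combines them with equal 25% priors. A triplet is called
*fluctuating* when mixture wins with posterior probability above 0.67,
i.e. when the mixture model is at least twice as likely as the other
three combined.

Triplets enter the analysis only if they pass three screens:

1. at least 5 trials in each of the A, B and AB conditions;
2. mean variance-to-mean ratio (Fano factor) of the A and B counts no
   greater than 3 (Poisson adequacy; a stricter variant uses 2);
3. A and B counts separable: the log intrinsic Bayes factor for distinct
   Poisson means must exceed 3, which at even prior odds means at least
   a 95% likelihood that the two distributions differ.

Population summaries tally the categories per stimulus regime and
contrast mixture prevalence between regimes with Pearson chi-squared
tests.

## Worked example

```r
library(spikemux)

# a synthetic triplet: rates 20 vs 5 counts per 200 ms window,
# AB trials flip a fair coin between the two rates
tr  <- simulate_triplet(regime_spec("mixture", alpha = 0.5, seed = 7))
scr <- screen_triplet(tr)
scr
#> <screening_report> INCLUDED
#>   trials A/B/AB: 15/15/15   mean Fano: 1   log IBF: 91.4

fit <- classify_triplet(tr)
fit
#> <triplet_fit> winner: mixture (posterior 1.000)  [fluctuating]
#>      mixture intermediate       single      outside
#>            1            0            0            0

round(coef(fit), 3)
#>      mixture intermediate       single      outside        alpha
#>        1.000        0.000        0.000        0.000        0.396
#>     lambda_A     lambda_B
#>       23.500        5.100
```

The posterior concentrates on the mixture hypothesis, the triplet is
flagged fluctuating, and the posterior mean of the mixing weight α
(0.40) is close to the generating 0.5: about 40% of the AB trials in
this draw followed the A rate. `plot(fit)` shows the AB count histogram
with the display smoothing (1/4–1/2–1/4 kernel plus cubic spline) and
the two single-stimulus rates; counts per 200 ms window convert to Hz
by multiplying by 5.

The same analysis runs end to end from a trial table on disk, or from a
synthetic preset, via the pipeline:

```r
run_pipeline(list(input = list(n_per_regime = 5), seed = 1),
             output_dir = "demo_out")
# -> trials.csv, screening.csv, classifications.csv, tallies.csv,
#    comparisons.csv, manifest.json
```

A thin command-line wrapper is installed at
`system.file("cli", "spikemux", package = "spikemux")`.

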
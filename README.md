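# SpliceJudge

SpliceJudge decides whether a candidate RNA splice junction is real using
only the genomic sequence around it. It is aimed at transcriptomics
workflows (bulk or single-cell) that need to triage junction lists
produced by spliced aligners — collections in which genuine junctions are
vastly outnumbered by alignment noise — without leaning on read support,
which penalises lowly expressed but real junctions.

## What it does

* **Classification.** A junction at donor position $J_d$ / acceptor
  position $J_a$ is represented by four 30-nt windows read in transcript
  orientation (donor exon | donor intron | acceptor intron | acceptor
  exon; `GT`/`AG` at the boundaries for canonical junctions), one-hot
  encoded (`A=[0,0,0,1]`, `C=[0,0,1,0]`, `G=[0,1,0,0]`, `T=[1,0,0,0]`,
  `N=[0.25,0.25,0.25,0.25]`) and scored by a small convolutional network:
  conv(8 maps, 3×1) → conv(16 maps, 3×1) → fully connected (32, dropout)
  → softmax, trained with Adam + L2. Junctions can be scored jointly
  (120-nt *junction mode*) or as the product of independent donor-site and
  acceptor-site probabilities (*site-pair mode*),
  $p = p_\text{donor} \cdot p_\text{acceptor}$.
* **Explanation.** Deep Taylor decomposition (z⁺ rule on hidden rectifier
  layers, bounded-box rule on the $[0,1]$ input) redistributes the
  positive-class score onto every nucleotide, yielding nonnegative,
  conservation-checked contribution profiles annotated by exon/intron
  window.
* **Artifact filtering.** Junctions fabricated by spliced alignment over
  repetitive sequence are flagged by two anchor edit distances
  ($E_d$ between the donor exonic anchor and the window just before the
  acceptor; $E_a$ symmetric) and dropped when
  $\min(E_d, E_a) \le$ a configurable threshold — independent of read
  coverage. A sample-support filter (keep junctions seen in ≥ 2 samples)
  is separate.
* **Evaluation.** Sensitivity, specificity, accuracy, F1,
  $Q9 = (1+q9)/2$ with
  $q9 = 1-\sqrt{2}\sqrt{(FN/(TP{+}FN))^2+(FP/(TN{+}FP))^2}$, auROC,
  auPRC, binomial error confidence intervals, stratified k-fold
  cross-validation.
* **Synthetic benchmarks.** A generator plants PWM-shaped donor/acceptor
  motifs, GT..AG-anchored decoys and repeat artifacts in random genomes
  with known truth, and provides the exact Bayes log-odds scorer of its
  own generative model as a reference classifier.

## Worked example

```r
library(SpliceJudge)

bench <- makeBenchmark(generatorConfig(nTrue = 800, nFalse = 800, seed = 42))
model <- trainSpliceModel(buildSpliceModel(spliceModelConfig(seed = 1)),
                          bench$train$sequences, bench$train$labels,
                          bench$valid$sequences, bench$valid$labels)
model
#> SpliceModel (junction mode, trained)
#>   input width: 120 nt x 4 channels (TGCA)
#>   conv 8 -> conv 16 (filters 3x1) -> fc 32 -> 2
#>   parameters: 62042
#>   best epoch 16: valid loss 0.1435, valid accuracy 0.96

p <- predict(model, bench$test$sequences)
cm <- confusionCounts(p, bench$test$labels)
str(c(rateMetrics(cm), curveMetrics(p, bench$test$labels),
      list(Q9 = q9Score(cm))))
#> List of 7
#>  $ sensitivity: num 0.975
#>  $ specificity: num 0.965
#>  $ accuracy   : num 0.97
#>  $ F1         : num 0.97
#>  $ auROC      : num 0.995
#>  $ auPRC      : num 0.995
#>  $ Q9         : num 0.97
```

The held-out auROC of 0.995 sits just under the Bayes bound of the
generator (`pwmBayesScore()` scores 0.999 on the same split): the network
has recovered nearly all of the signal that exists. Explanation and
filtering:

```r
prof <- explainPredictions(model, bench$test$sequences,
                           labels = bench$test$labels)
aggregate(mean ~ window, prof, mean)
#>            window       mean
#> 1   acceptor_exon 0.01960710
#> 2 acceptor_intron 0.02644817
#> 3      donor_exon 0.02346684
#> 4    donor_intron 0.02392557

sim <- generateGenome(generatorConfig(nTrue = 100, nFalse = 100,
                                      repeatFraction = 0.3, seed = 7))
res <- filterRepetitive(sim$genome, sim$junctions)
table(dropped = sim$junctions$id %in% res$dropped$id,
      truth = sim$junctions$class)
#>        truth
#> dropped artifact decoy true
#>   FALSE        0    70  100
#>   TRUE        30     0    0
```

Intronic windows out-contribute exonic ones (most splice-defining
sequence is intronic), and the repeat filter recovers exactly the 30
planted artifacts while touching no genuine junction. Per-position
profiles (`exportProfile()`, `plotProfile()`) peak at the planted motifs.

A command-line interface wrapping the same functions ships as
`inst/scripts/splicejudge` with subcommands `simulate`, `train`,
`predict`, `explain`, `filter`, `evaluate`, `crossval`; every run writes
a `manifest.json` recording resolved options, seeds and input digests.

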
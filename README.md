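# fsklr — beta-turn prediction with fixed-size kernel logistic regression

Beta-turns are four-residue chain-reversal motifs covering roughly 25% of
the residues of globular proteins.  `fsklr` predicts, for every residue of
a protein chain, whether it lies in a beta-turn, from two kinds of
per-residue evidence: a PSSM (L x 20 log-odds profile) and three-state
secondary-structure predictions (H/E/C plus a 0–9 confidence digit) from
four sources.

The classifier is a **kernel logistic regression** with an RBF kernel
K(x, x′) = exp(−γ‖x − x′‖²), fitted by minimising the penalized negative
log-likelihood

```
min_{w,b}  (1/2) wᵀw + (λ/2) Σᵢ log(1 + exp(−yᵢ f(xᵢ))),   f(x) = wᵀφ(x) + b
```

so that P(turn | x) = 1/(1 + e^(−f(x))).  To scale beyond small data the
package uses the **fixed-size** construction: m prototype vectors chosen
by k-means define a Nyström low-rank feature map
Φ = K_{n,m} U_p Λ_p^(−1/2), and the model is fitted in that explicit
space with a trust-region Newton solver (truncated-CG inner steps).  An
exact dual-form KLR (IRLS on the dense kernel matrix) is included for
small problems and serves as the correctness reference: at m = n the two
agree to numerical precision.

Around the model sit the full pipeline stages:

* a 216-feature per-residue encoding (140 windowed logistic-scaled PSSM
  values + 76 secondary-structure indicators/confidences/ratios), reduced
  to 90 features by information-gain / chi-squared ranking;
* a 0.45 probability threshold and four ordered state-changing rules
  (tnt→ttt, ntn→nnn, nttn→tttt, ntttn→ttttn/ntttt) that enforce the
  four-residue minimum run length of turns;
* MCC, Q_total, Q_predicted, Q_observed, specificity, ROC/AUC, and
  chain-level sevenfold cross-validation with hyperparameter tuning and an
  incremental prototype-count search;
* readers/writers for FASTA chains, PSI-BLAST ASCII PSSM profiles,
  columnar secondary-structure and label TSVs, and a seeded synthetic-data
  generator so everything runs without external downloads.

## Worked example

```r
library(fsklr)

ds  <- simulate_dataset(sim_config(n_chains = 20, seed = 42))
enc <- encode_dataset(ds)                      # 1170 residues x 216 features
sel <- rank_features(enc$X, enc$y)
X   <- select_features(sel, enc$X, 90)

model <- fs_klr_train(X, enc$y, hyperparams(lambda = 1, gamma = 0.05),
                      m = 50, seed = 42)

cv <- cross_validate(ds, hyperparams(1, 0.05), m = 50, k = 7, seed = 42)
round(cv$average[, c("auc", "mcc_raw", "mcc_smoothed",
                     "q_total_raw", "q_total_smoothed")], 4)
#>      auc mcc_raw mcc_smoothed q_total_raw q_total_smoothed
#> 1 0.9757  0.8215       0.8232     92.1226          91.8211
```

Mean AUC 0.976 says the raw probabilities rank turn residues far above
non-turn residues across the seven held-out folds; the Matthews
correlation rises from 0.8215 to 0.8232 after rule smoothing, the same
qualitative effect the rules are designed for.  On a single chain the
smoothing is visible directly — the rules flip an isolated `n` inside a
run and complete a three-residue run to four:

```r
chain1 <- enc$provenance$chain_id == ds$chains$chain_id[1]
pred   <- fs_klr_predict(model, X[chain1, ])
cat(ds$labels[[1]], "\n")                          # truth
cat(paste(pred$label, collapse = ""), "\n")        # raw
cat(apply_state_rules(pred$label, pred$prob), "\n")# smoothed
#> ntttttnnnnnnnnntttttnnnntttttttnnnnnttttnnnnnnnnntttttnnnnnnnnnnnnnnnnnnnnnn
#> ntttttnnnnnnnnntttnnnnnnnttttttnnntnttttnnnnnnnnnttttnnnnnnnnnnnnnnnnnnnnnnn
#> ntttttnnnnnnnnnttttnnnnnnttttttnnnttttttnnnnnnnnnttttnnnnnnnnnnnnnnnnnnnnnnn
```

A command-line wrapper over the same functions lives at
`inst/scripts/fsklr.R` (`simulate`, `encode`, `train`, `predict`,
`evaluate`, `cv`, `tune`).

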
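# ibvs — integrative Bayesian selection of genes and pathways

`ibvs` identifies genes *and* the regulatory pathways containing them,
jointly, from gene expression measured against a binary phenotype (disease
vs. control).  It is aimed at analysts who have an expression matrix, a
gene-set collection (GMT) and optionally a gene–gene network, and who want
posterior probabilities — not just ranked p-values — for both genes and
pathways.

## The model

For outcomes `y ∈ {0,1}^n` and a standardized `n × p` expression matrix `X`,
a probit model with Albert–Chib latent utilities is combined with two layers
of selection indicators: `θ_k ∈ {0,1}` per pathway and `γ_j ∈ {0,1}` per
gene,

    y_i = 1{Z_i > 0},      Z = α·1 + T_(θ,γ) b + ε,   ε ~ N(0, I_n),

where `T_(θ,γ)` holds one column per selected pathway — the first partial
least squares (PLS) component of that pathway's selected genes against the
centered phenotype.  Priors:

* **PLS g-prior** on pathway effects: `b ~ N(0, c (T'T)⁺)` with the
  Moore–Penrose generalized inverse, well defined for any design;
* independent **Bernoulli(π)** on pathway indicators;
* a **Markov random field (Ising)** prior on gene indicators restricted to
  selected pathways, `log P(γ) = d Σ γ_j + f Σ_{j~l} γ_j γ_l + C`, which
  rewards the joint selection of network-adjacent genes;
* zero prior mass for invalid configurations (an empty selected pathway, a
  selected gene outside all selected pathways, or two selected pathways
  with identical selected-gene sets).

With `α` and `b` integrated out, `Z ~ N(0, h·11' + I + c·P_T)` where `P_T`
projects onto the design's column space; a hybrid sampler alternates
truncated-normal Gibbs sweeps of `Z` with constrained Metropolis–Hastings
moves on `(θ, γ)` (add/remove pathway, toggle/swap genes), implemented in
compiled code.  Marginal inclusion frequencies of the kept draws are the
Bayesian-model-averaged selection probabilities.

The package also provides the robust two-test screening step (t-test with
Wilcoxon rescue, pathway expansion, exact hypergeometric enrichment), a
pathway-structured expression simulator (DAG gene sets, structural-equation
generation with unit variances, SNR-calibrated probit outcomes), a
gene-only Bayesian variable selection baseline, ROC/AUC evaluation and
cross-validated marker-count selection.

## Worked example

Simulate one replicate of the sparse-causal study design (315 genes in 9
partially overlapping pathways, 8 causal genes, SNR 54.5) and fit it:

```r
library(ibvs)

sim <- build_scenario(1, seed = 7)
sim
#> ibvs_sim scenario 1: 100 samples x 315 genes, 9 pathways, 8 causal genes, SNR 54.5

draws <- run_chain(sim$X, sim$y, sim$structure,
                   config = sampler_config(burn_in = 2000, kept = 8000,
                                           chains = 2, seed = 11))
draws
#> ibvs_draws (ibvs): 2 chain(s) x 8000 kept iterations
#> acceptance by move type: 0.14 0.14 0.09 0.25
#> top genes: g171=0.99 g97=0.92 g95=0.82 g96=0.61 g120=0.50

probs <- marginal_selection_probs(draws)
round(sort(probs$pathway, decreasing = TRUE), 2)
#>  pw5  pw7  pw6  pw9  pw8  pw3  pw4  pw1  pw2
#> 1.00 1.00 0.77 0.61 0.56 0.43 0.41 0.08 0.02

labels <- as.integer(seq_len(315) %in% sim$causal)
roc_auc(probs$gene, labels)$auc
#> [1] 0.9508929
gelman_rubin(draws$logpost)
#> [1] 1.000876
```

The causal set here is `g58 g95 g96 g97 g130 g131 g170 g171`.  Four causal
genes top the gene ranking outright; `g120` at probability 0.50 is a
*marker*, not a cause — it is the hub regulator of the strongly correlated
causal pair `g130`/`g131`, and the posterior honestly splits mass between
the correlated candidates.  The gene-selection AUC on this single replicate
is 0.95; averaging selection probabilities over ten replicates drives it to
≈ 1.  The two pathways holding most causal genes (`pw5`, `pw7`) are
selected with probability 1.

A thin command-line front end over the same functions ships in
`inst/cli/ibvs.R` (subcommands `simulate`, `screen`, `run`, `evaluate`,
`cvsize`, `pipeline`).

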
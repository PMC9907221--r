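---
title: "PepPPO: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PepPPO: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(PepPPO)
```

## Problem setting

MHC Class I molecules present short peptides (8-15 residues, most often
9-mers) on the cell surface; which peptides a given allele presents is
governed by a sequence motif dominated by a few anchor positions. PepPPO
learns, by reinforcement learning, a *mutation policy*: starting from a
uniform-random peptide, it repeatedly substitutes one residue at a time
until a presentation scorer judges the peptide qualified, or a step
horizon is reached. Running many episodes yields a per-allele peptide
repertoire from which a position weight matrix (PWM) binding motif is
estimated, and those motifs drive rapid neoantigen screening of
point-mutated proteins.

## Markov decision process

* **State**: the current peptide plus the target allele, represented by
  its 34-residue pseudo sequence (the polymorphic contact positions of
  the MHC binding groove).
* **Action**: a pair (position, replacement residue). The replacement
  must differ from the current residue - the policy's residue
  distribution masks the current residue to probability zero, so no-op
  actions are impossible by construction.
* **Reward**: sparse. Intermediate steps earn 0; the episode ends when
  the presentation score of the mutated peptide strictly exceeds the
  qualification threshold `sigma` (default 0.75), or after `maxSteps`
  substitutions (default 8), and the terminal reward is the final
  presentation score. Rewards-to-go are therefore the closed form
  `gamma^(T-t) * r_T`, which `rewardsToGo()` implements and validates.

## Policy network

Residues are encoded as the concatenation of a scaled BLOSUM62 row
(scale 0.1), a one-hot vector, and a learned 16-dimensional embedding
(56 features total; each block can be disabled in `encodingConfig()`).
The peptide is embedded by a one-layer bidirectional LSTM; each
position's representation concatenates the two directions' hidden
states, and the peptide vector concatenates the two end states. The
pseudo sequence is embedded by a two-layer perceptron over its
residue-major flattened encoding. A position head scores every peptide
position (softmax), a residue head produces the masked 20-way residue
distribution at the chosen position, and a value head estimates the
state value for PPO from the peptide and MHC vectors.

All layers are implemented directly in R with analytic backpropagation
(`R/backprop.R`); the test suite verifies the gradients of both the
imitation loss and the exact PPO minibatch loss against central finite
differences. The LSTM boundary vectors are drawn once at initialization
and frozen, so a checkpoint fully determines behavior given a seed.

## Training

Training follows standard PPO with clipped surrogate
`min(phi * A, clip(phi, 1 - eps, 1 + eps) * A)`, generalized advantage
estimation, and the combined loss
`L = -L_CLIP + alpha1 * L_V + alpha2 * L_B - alpha3 * H`, where `L_B` is
an imitation cross-entropy on samples from a diversity-promoting
experience buffer and `H` the action entropy. Defaults in `ppoConfig()`:
`gamma = 0.99`, `lam = 0.95`, `epsClip = 0.2`,
`alpha = (0.5, 0.1, 0.01)`, `K = 4` epochs over `N = 2048` transitions
in minibatches of 256.

Two mechanisms stabilize early learning:

1. **Expert policy.** From a binding dataset, every allele with at least
   `minCount` qualified peptides per length receives Laplace-smoothed
   per-position residue frequencies. The expert mutates the position
   with the largest gap between the most popular and the current
   residue, sampling the replacement from the profile (current residue
   excluded). Alleles without data fall back to the most
   BLOSUM62-similar allele with data. The policy is pretrained by
   behavior cloning against expert actions on random states, and a
   decaying fraction of PPO rollout episodes is expert-driven.
2. **Experience buffer.** State-action pairs from qualified
   trajectories are stored with eviction from the currently most
   frequent action key (oldest first), and sampled with
   inverse-frequency weights, so rare residue substitutions are never
   crowded out by a dominant one.

```{r train, eval = FALSE}
oracle <- makeHiddenOracle(seed = 7L)
pseudo <- oraclePseudoSequences(oracle)
binding <- synthBindingDataset(oracle, nPerAllele = 200L, seed = 7L)
expert <- buildExpertPolicy(binding, pseudo)
pre <- pretrainPolicy(initPolicy(), expert, pseudo)
fit <- trainPepPPO(oracle, pseudo, policy = pre$policy, expert = expert,
                   buffer = experienceBuffer())
```

## Motif characterization

`buildPWM()` estimates a PWM from qualified generated peptides (the
reporting default uses no pseudocount, so the motif reflects the
repertoire exactly). Motifs are compared by `motifDistance()`, the mean
over positions of the column-wise Hellinger distance
`sqrt(sum((sqrt(p) - sqrt(q))^2) / 2)`; `motifSimilarity()` is one minus
that distance. `robustnessProtocol()` repeats generation across seeds
and flags alleles whose pairwise motif similarity falls below a bound.

## Neoantigen screening

`windowPeptides()` enumerates every mutant k-mer window containing a
point mutation (reference windows are never emitted; windows truncated
by protein ends are dropped). `matchingScore()` scores a window against
an allele PWM by summing per-position probabilities, min-max normalized
by the PWM's analytic score bounds. `screenNeoantigens()` labels each
(peptide, allele) pair with the reference scorer and evaluates
discrimination by rank-statistic AUC and a two-sided Wilcoxon rank-sum
test.

## Synthetic fixtures and their realism

No external presentation predictor ships with the package, so all
analyses run against `makeHiddenOracle()`: per allele, a hidden PWM with
a small number of anchor columns carrying concentration `kappa` on one
consensus residue, all other columns exactly uniform. A peptide's score
is its PWM match, min-max normalized by the PWM's attainable bounds and
squashed through a fixed logistic calibrated so that uniform-random
peptides score near 0, any peptide missing an anchor stays below the
qualification threshold, and the full anchor set scores 1. This mirrors
the anchor-dominated structure of real Class I motifs while making
ground truth (anchors, consensus, qualification) exactly known.

Because the non-anchor columns are uniform, a peptide matching `k` of
the 4 anchors scores exactly `k/4` before squashing - qualification is
equivalent to matching the complete anchor set, which is what makes the
motif-recovery criteria sharp rather than threshold-sensitive.

`synthBindingDataset()` rejection-samples balanced positive/negative
binding records; positives are proposed from the hidden PWM (a
qualified peptide is a ~6e-6 event under a uniform proposal) but
accepted, and labeled, only by thresholding the oracle score.
`synthCohort()` builds random proteins with planted consensus windows
hidden behind a reference substitution, keeping planted windows disjoint
so every record's reference residue matches the final protein.

## Numerical choices

* Gradients: analytic, verified against central finite differences at
  tolerances of about 1e-4 per probed entry (relative errors observed
  near 1e-7).
* Optimizer: Adam with global gradient-norm clipping.
* Softmax: computed with per-row max subtraction; masked entries use
  `-Inf` logits.
* GAE: backward recursion, tested against the brute-force double sum at
  1e-10.
* AUC: Mann-Whitney rank statistic with averaged tie ranks; p-values
  from the normal approximation with continuity correction.
* All randomness flows through R's RNG; every workflow takes explicit
  seeds and the CLI writes the resolved configuration next to outputs.

## Limitations

* The presentation oracle is synthetic; absolute performance numbers on
  it do not transfer to real predictors, though the pipeline accepts
  any `RewardScorer` (including the subprocess adapter for an external
  predictor).
* The policy treats each allele independently through its pseudo
  sequence; no cross-allele generalization claim is tested beyond
  nearest-allele fallback of the expert.
* Training is CPU-bound single-threaded R; the shipped configuration
  targets minutes-scale runs on one core, not large-scale sweeps.
* PWM motifs are position-independent by construction and cannot
  express residue covariation.
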
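# PepPPO

Reinforcement learning of MHC Class I binding peptides and binding
motifs in pure R.

MHC Class I molecules present short peptides (8-15 residues, usually
9-mers) on the cell surface, and which peptides an allele presents is
governed by a sequence motif dominated by a few anchor positions.
PepPPO trains a *mutation policy* with proximal policy optimization
(PPO): starting from a uniform-random peptide, the policy substitutes
one residue at a time until a presentation scorer judges the peptide
qualified (score strictly above 0.75) or a step horizon is reached.
Episodes earn a single terminal reward, the final presentation score.
Running many episodes per allele yields a peptide repertoire; position
weight matrix (PWM) motifs built from the qualified peptides
characterize the allele's binding preferences and drive rapid neoantigen
screening of point-mutated proteins.

The model is a bidirectional LSTM over encoded residues (scaled BLOSUM62
row + one-hot + learned embedding), an MLP over the allele's 34-residue
pseudo sequence, a position head, a masked residue head (the current
residue has probability zero, so actions are never no-ops) and a value
head. Network, analytic backpropagation, Adam and PPO are implemented
directly in R and the gradients are verified against finite differences
in the test suite. Training is stabilized by behavior cloning against an
expert policy derived from binding data, a decaying fraction of
expert-driven rollouts, and a diversity-promoting experience buffer with
inverse-frequency sampling.

Everything runs self-contained against a synthetic hidden-motif
presentation oracle with exactly known ground truth; any external
predictor can be plugged in through the `RewardScorer` contract.

## Worked example

Build the synthetic world: a 3-allele oracle whose hidden 9-mer motifs
have 4 anchor columns, plus a balanced binding dataset and the expert
policy derived from it.

```r
library(PepPPO)
set.seed(42)
oracle  <- makeHiddenOracle(nAlleles = 3L, seed = 7L)
pseudo  <- oraclePseudoSequences(oracle)
hiddenConsensus(oracle, "SYN-01", 9L)
#> [1] "PEALAHAAA"
hiddenAnchors(oracle, "SYN-01", 9L)
#> [1] 1 2 4 6
presentationScores(oracle, c("ACDEFGHIK", hiddenConsensus(oracle, "SYN-01", 9L)),
                   "SYN-01")
#> [1] 0 1

binding <- synthBindingDataset(oracle, nPerAllele = 200L, seed = 7L)
expert  <- buildExpertPolicy(binding, pseudo)
expert
#> ExpertPolicy over 3 allele(s)
#>   SYN-01: lengths 9
#>   SYN-02: lengths 9
#>   SYN-03: lengths 9
```

A PWM built from the qualified binders already recovers the hidden
anchors (positions 1, 2, 4, 6 carry nearly all information):

```r
qual <- binding[binding$allele == "SYN-01" & binding$measurement > 0.75, ]
pwm  <- buildPWM(qual$peptide)
pwm
#> PWM motif of length 9 (200 peptides)
#>   consensus: PEELTHRQY
#>   information content (bits): 4.32 4.32 0.08 4.32 0.09 4.32 0.04 0.07 0.06
round(motifSimilarity(pwm, hiddenPWM(oracle, "SYN-01", 9L)), 3)
#> [1] 0.841
```

Those motifs screen a synthetic mutated-protein cohort for neoantigen
candidates:

```r
cohort <- synthCohort(oracle, seed = 7L)
pwms <- lapply(oracleAlleles(oracle), function(al)
  buildPWM(binding$peptide[binding$allele == al & binding$measurement > 0.75]))
names(pwms) <- oracleAlleles(oracle)
res <- screenNeoantigens(cohort$records, cohort$proteins, pwms, oracle)
res$summary
#>      n nNeoantigen auc   wilcoxonP medianNeo medianNonNeo
#> 1 1434           3   1 0.002742226 0.9660422   0.03157895
```

Training the full policy (behavior-cloning pretraining followed by PPO;
a few minutes on one CPU core):

```r
pre <- pretrainPolicy(initPolicy(), expert, pseudo)
fit <- trainPepPPO(oracle, pseudo,
                   cfg = ppoConfig(N = 1024L, iterations = 30L,
                                   expertFractionInit = 0.3,
                                   expertDecayFrac = 0.5),
                   policy = pre$policy, expert = expert,
                   buffer = experienceBuffer())
gen <- generatePeptides(fit$policy, oracle, "SYN-01", pseudo[["SYN-01"]],
                        n = 1000L)
evaluateGeneration(gen$peptide, "SYN-01", oracle, method = "PepPPO")
```

## Command line

`inst/cli/pepppo.R` dispatches the exported workflow commands:

```sh
Rscript inst/cli/pepppo.R fixtures --out fixtures/
Rscript inst/cli/pepppo.R train    --out run/ --set iterations=30
Rscript inst/cli/pepppo.R generate --checkpoint run/checkpoint.rds --out run/
Rscript inst/cli/pepppo.R motif    --generated run/generated.tsv --out run/
Rscript inst/cli/pepppo.R screen   --proteins fixtures/proteins.fasta \
    --mutations fixtures/mutations.tsv --motifs run/motifs --out run/
Rscript inst/cli/pepppo.R baseline --checkpoint run/checkpoint.rds --out run/
```

All settings live in a flat YAML configuration (`runConfig()`); unknown
keys fail loudly and every command writes the resolved configuration
next to its outputs.

## Package layout

* `R/alphabet.R`, `R/encoding.R` - canonical residue alphabet, encoding
  blocks.
* `R/env.R` - the mutation environment (sparse terminal reward).
* `R/policy.R`, `R/backprop.R` - BiLSTM policy/value network with
  analytic gradients.
* `R/ppo.R` - GAE, clipped surrogate, rollout collection, pretraining,
  PPO training loop.
* `R/expert.R`, `R/buffer.R` - expert mutation policy, diversity
  buffer.
* `R/motif.R` - PWMs, Hellinger motif distance, robustness protocol.
* `R/screen.R` - mutant windows, matching scores, AUC/Wilcoxon
  screening.
* `R/generate.R` - repertoire generation and baselines.
* `R/fixtures.R` - hidden-motif oracle and synthetic datasets.
* `R/io.R`, `R/cli.R` - file formats and command-line workflows.

See the vignette `vignettes/pepppo-methods.Rmd` for the model,
assumptions, numerical choices and limitations.
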
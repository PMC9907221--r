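Package: PepPPO
Title: Reinforcement Learning of MHC Class I Binding Peptides and Motifs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns a peptide mutation policy with proximal policy
    optimization (PPO) that converts random peptides into peptides
    presented by a given MHC Class I allele, represented by its 34-residue
    pseudo sequence. The trained policy generates per-allele peptide
    repertoires from which position weight matrix (PWM) binding motifs are
    characterized and compared by mean column-wise Hellinger distance.
    Includes an expert mutation policy derived from binding data with
    BLOSUM62 nearest-allele fallback, imitation pretraining, a
    diversity-promoting experience buffer, sPWM and random generation
    baselines, and rapid neoantigen screening of point-mutated proteins by
    PWM matching scores with Wilcoxon and AUC evaluation. A self-contained
    hidden-motif presentation oracle and synthetic cohort generators make
    the whole pipeline runnable without external predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'alphabet.R'
    'encoding.R'
    'scorer.R'
    'motif.R'
    'io.R'
    'fixtures.R'
    'screen.R'
    'env.R'
    'expert.R'
    'buffer.R'
    'policy.R'
    'backprop.R'
    'ppo.R'
    'generate.R'
    'cli.R'
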
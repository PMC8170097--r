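# shared fixtures: all built in code at test time

# the worked-example response used throughout the semantic-feature tests
worked_example_chat <- function() {
  paste0("@Begin\n@Participants:\tPAR Participant\n",
         "*PAR:\tthere is a boy .\n",
         "*PAR:\tthe boy is a brother .\n",
         "*PAR:\the is stealing a cookie .\n",
         "*PAR:\tthe sister is watching .\n",
         "@End\n")
}

worked_example_transcript <- function() parse_chat(worked_example_chat())

# expand confusion-matrix counts into prediction/label vectors
preds_from_counts <- function(tp, fp, tn, fn) {
  list(pred = c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn)),
       label = c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn)))
}

# a small Gaussian feature table with a separable signal column
toy_features <- function(n = 20, p = 5, effect = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[, 1] <- x[, 1] + effect * y
  list(x = as.data.frame(x), y = y)
}

effect_free_params <- function(n = 50, seed = 1) {
  synth_params(
    n_per_group_per_language = n,
    iu_mention_prob = c(HC = 0.55, AD = 0.55),
    specific_keyword_prob = c(HC = 0.35, AD = 0.35),
    pronoun_substitution_prob = c(HC = 0.2, AD = 0.2),
    filler_rate = c(HC = 0.2, AD = 0.2),
    duration_lognormal = list(HC = c(meanlog = log(60), sdlog = 0.45),
                              AD = c(meanlog = log(60), sdlog = 0.45)),
    paralinguistic_effects = default_paralinguistic_effects()[0, ],
    seed = seed)
}
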
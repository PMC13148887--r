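# Shared fixtures and independent oracles, built in code.

# Brute-force Welch heteroscedastic one-way ANOVA from the textbook formula
# (weights w_i = n_i / s_i^2). Independent of the package implementation.
welch_oracle <- function(groups) {
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  s2 <- vapply(groups, stats::var, numeric(1))
  k <- length(groups)
  w <- n / s2
  W <- sum(w)
  xw <- sum(w * m) / W
  num <- sum(w * (m - xw)^2) / (k - 1)
  lam <- sum((1 - w / W)^2 / (n - 1))
  den <- 1 + (2 * (k - 2) / (k^2 - 1)) * lam
  Fst <- num / den
  df2 <- (k^2 - 1) / (3 * lam)
  list(F = Fst, df1 = k - 1, df2 = df2,
       p = stats::pf(Fst, k - 1, df2, lower.tail = FALSE))
}

# A minimal 8-cell lexicon (one word per subdimension x valence) for
# construction-level tests.
tiny_lexicon <- function() {
  scm_lexicon(tibble::tibble(
    word = c("kind", "cold", "honest", "selfish",
             "capable", "clumsy", "confident", "timid"),
    dimension = rep(c("warmth", "warmth", "competence", "competence"),
                    each = 2),
    subdimension = rep(c("sociability", "morality", "ability",
                         "assertiveness"), each = 2),
    valence = rep(c(1L, -1L), times = 4)))
}

# Noise-free synthetic backend over the seed lexicon (axes only).
noise_free_backend <- function(lexicon = scm_seed_lexicon(), dim = 64L) {
  synthetic_backend(synthetic_embedding_spec(dim = dim, noise_sd = 0),
                    lexicon)
}

# Small deterministic generator configuration for fast end-to-end tests.
small_generator <- function(seed = 11L, responses_per_age = 5L, ...) {
  generator_config(responses_per_age = responses_per_age, seed = seed, ...)
}

# The five-sentence worked response: boilerplate opener, list header, two
# substantive sentences, boilerplate closer.
worked_response <- function() {
  paste("Sure!",
        "Here are some common characteristics:",
        "They are kind and generous to everyone.",
        "They love learning new things every day.",
        "I hope this helps you.",
        sep = "\n")
}
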
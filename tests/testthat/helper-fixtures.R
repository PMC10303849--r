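# Shared fixtures: everything is generated in code at test time.

random_dna <- function(n, L, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, random_dna(n, L)))
  }
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

tiny_model <- function(U = 2, L = 40, T_ = 1, seed = 1, ...) {
  build_model(seqnam_config(U, L, T_, ...), seed = seed)
}

# A small binary planted-motif dataset plus splits, shared across tests.
toy_planted <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_dataset(plant_spec(
        demo_motifs("GATA_SYN"), n = 600, length = 60,
        rule = "presence_binary", seed = 7
      ))
      cache <<- c(gen, list(
        splits = split_dataset(gen$data, split_spec(stratify = TRUE),
                               seed = 3)
      ))
    }
    cache
  }
})

# Naive single-unit forward recomputation (independent of both engines):
# valid convolution, eval-mode batch norm with stored stats, exponential.
naive_unit_activation <- function(model, sequence, unit = 1) {
  cfg <- model$config
  W <- cfg$filter_width
  f <- matrix(model$params$filters[, unit], nrow = 4L) # rows A,C,G,T
  code <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  conv_len <- length(code) - W + 1L
  vapply(seq_len(conv_len), function(w) {
    s <- sum(f[cbind(code[w:(w + W - 1L)], seq_len(W))])
    z <- (s - model$stats$bn1_mean[unit]) /
      sqrt(model$stats$bn1_var[unit] + 1e-5)
    z <- z * model$params$bn1_gamma[unit] + model$params$bn1_beta[unit]
    exp(min(z, 20))
  }, numeric(1))
}
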
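# Shared helpers: tiny deterministic fixtures built in code.

# brute-force CRF oracle: enumerate all m^n paths
enumerate_paths <- function(n, m) {
  as.matrix(expand.grid(rep(list(seq_len(m)), n)))
}

brute_scores <- function(emissions, trans) {
  paths <- enumerate_paths(nrow(emissions), ncol(emissions))
  apply(paths, 1L, function(y) {
    crf_path_score(emissions, trans, as.integer(y))
  })
}

random_crf_instance <- function(n, m, lim = 2) {
  list(P = matrix(stats::runif(n * m, -lim, lim), n, m),
       T = matrix(stats::runif((m + 1L) * m, -lim, lim), m + 1L, m))
}

# a 3-sentence annotated toy corpus over the default scheme
toy_corpus <- function() {
  list(
    annotated_sentence(c("a", "X", "Y", "b"),
                       c("O", "B-HyC", "I-HyC", "O")),
    annotated_sentence(c("Z", "W", "c"),
                       c("B-DiD", "I-DiD", "O")),
    annotated_sentence(c("d", "e"), c("O", "O"))
  )
}

# small reduced-size synthetic corpus for fast training tests
small_synth <- function(n = 40L, seed = 13L) {
  generate_corpus(synth_config(n_docs = n, seed = seed))
}
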
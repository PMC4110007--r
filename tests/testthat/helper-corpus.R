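# Shared heavyweight artifacts, computed once per test run and reused by the
# acceptance suite: a 100-reach synthetic participant under the default
# recording conditions, its decomposition, the training tables, and the
# cross-validated networks with closed-loop simulations of every test reach.

.corpus_env <- new.env(parent = emptyenv())

corpus_seed <- 73L
corpus_n <- 100L

shared_corpus <- function() {
  if (is.null(.corpus_env$corpus)) {
    co <- synth_corpus(corpus_n, seed = corpus_seed)
    ds <- preprocess_dataset(co$dataset)
    .corpus_env$corpus <- list(truth = co$truth, dataset = ds)
  }
  .corpus_env$corpus
}

shared_decomposition <- function() {
  if (is.null(.corpus_env$decomp)) {
    cp <- shared_corpus()
    .corpus_env$decomp <- decompose_dataset(
      cp$dataset,
      decomposition_config(n_restarts = 1, seed = corpus_seed))
  }
  .corpus_env$decomp
}

shared_crossval <- function() {
  if (is.null(.corpus_env$cv)) {
    cp <- shared_corpus()
    tb <- build_training_tables(cp$dataset, shared_decomposition())
    .corpus_env$cv <- crossval_evaluate(
      cp$dataset, tb, training_config(seed = corpus_seed),
      sim_cfg = simulation_config())
  }
  .corpus_env$cv
}
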
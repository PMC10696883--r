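# Shared fixtures: everything is generated in code at test time.

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

write_temp_fasta <- function(records) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  write_fasta(records, f)
  f
}

# small configuration used by unit tests that need to train quickly
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(conv_kernels = 8L, kernel_len = 6L, rnn_units = 8L,
         dense_units = 16L, batch_size = 64L, max_epochs = 15L,
         patience = 5L, learning_rate = 3e-3, seed = 42L),
    list(...)
  )
  do.call(crnn_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

# a small trained model on planted-motif reads, shared across test files
tiny_trained_model <- function() {
  if (is.null(.fixture_cache$tiny_model)) {
    cfg <- synth_config(n_reads = 600L, seed = 99L)
    sim <- simulate_reads(cfg)
    ds <- build_balanced_dataset(sim$reads, seed = 7L)
    parts <- split_dataset(ds, seed = 7L)
    .fixture_cache$tiny_model <- train(build_model(tiny_config()),
                                       parts$train, parts$validation)
    .fixture_cache$tiny_parts <- parts
  }
  .fixture_cache$tiny_model
}

tiny_split <- function() {
  tiny_trained_model()
  .fixture_cache$tiny_parts
}

# full-scale study conditions: ~10,000 training / ~2,100 validation reads,
# planted-motif softness 0.05, default architecture, fixed seed
acceptance_sim_config <- function() synth_config(n_reads = 7150L, seed = 1L)

acceptance_model <- function() {
  if (is.null(.fixture_cache$acc_model)) {
    sim <- simulate_reads(acceptance_sim_config())
    ds <- build_balanced_dataset(sim$reads, seed = 1L)
    parts <- split_dataset(ds, seed = 1L)
    .fixture_cache$acc_parts <- parts
    .fixture_cache$acc_model <- train(build_model(crnn_config(seed = 1L)),
                                      parts$train, parts$validation)
  }
  .fixture_cache$acc_model
}

acceptance_split <- function() {
  acceptance_model()
  .fixture_cache$acc_parts
}

itc_fixture_path <- function() {
  system.file("extdata", "grhl1_itc_affinities.tsv", package = "crnntfbs")
}
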
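# small shared synthetic worlds, built once per test run
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(simulation_spec(seed = 8, n_genes = 100))
    cache
  }
})

# a tiny trained CNN for structural tests (41-nt input, one block)
tiny_cnn <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(5)
      n <- 120
      seqs <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 41, TRUE), collapse = ""), "")
      substr(seqs[1:60], 19, 23) <- "GGACT"
      spec <- cnn_spec(input_len = 41, conv_filters = 8L, kernel_sizes = 8L,
                       pool_sizes = 2L, dense_units = 8, epochs = 4,
                       batch_size = 16, seed = 5)
      cache <<- list(model = cnn_train(seqs, rep(1:0, each = 60), spec),
                     seqs = seqs, labels = rep(1:0, each = 60))
    }
    cache
  }
})
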
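# Shared fixtures, all generated in code.

# Minimal recording constructor for tests that need full control of the
# signal matrix (the simulator is exercised separately).
new_test_recording <- function(semg, fs, grid = grid_layout(2L, 2L, 1L),
                               force_values = rep(0.5, ncol(semg)),
                               subject = "T01", gesture = "G1",
                               repetition = 1L, group = "HC") {
  force <- structure(list(values = force_values, fs = fs,
                          mode = "constant", params = list(amp = 0.5)),
                     class = "force_trace")
  structure(
    list(semg = semg, force = force, fs = fs, grid = grid,
         gesture = gesture, subject_id = subject,
         repetition = as.integer(repetition), group = group,
         channel_ids = seq_len(nrow(semg))),
    class = "recording"
  )
}

# Small sample set of smooth random windows; target = window mean.
toy_sample_set <- function(n, L = 500L, seed = 1L, subject = "S1") {
  withr::with_seed(seed, {
    W <- matrix(0, n, L)
    for (i in seq_len(n)) {
      W[i, ] <- generate_force_profile("random", L / 1000, 1000,
                                       list(amp = 0.9),
                                       seed = seed * 1000L + i)$values
    }
    structure(
      list(windows = W, targets = rowMeans(W), L = as.integer(L),
           step = as.integer(L),
           provenance = data.frame(subject = subject, gesture = "G1",
                                   repetition = 1L, group = "HC",
                                   window = seq_len(n))),
      class = "sample_set"
    )
  })
}

# Tiny fast estimator configuration used across training tests.
tiny_config <- function(units = c(8L, 6L), dropout = 0.2, seed = 1L,
                        batch_size = 32L) {
  estimator_config(layer_units = units, dropout = dropout,
                   batch_size = batch_size, input_stride = 10L,
                   seed = seed)
}

# Session-level cache for expensive acceptance fixtures.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- force(expr)
  }
  .fixture_cache[[name]]
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
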
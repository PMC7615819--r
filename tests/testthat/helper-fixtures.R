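# Shared fixtures, built in code.

# rows of a Hadamard matrix: mutually orthogonal +/-1 patterns
hadamard_rows <- function(k) {
  H <- matrix(1)
  for (i in seq_len(k)) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

# fast desk-scale recipes
fast_single <- function() tpc_recipe(n_epochs = 200L, tol = 1e-6)
fast_two <- function(hidden_dim) {
  tpc_two_recipe(hidden_dim = hidden_dim, lr_weights = 3e-3, n_epochs = 100L,
                 tol = 0, n_inference_steps = 100L)
}

train_moving_bar_model <- function(seed = 1L) {
  bar <- generate_moving_bar()
  m <- tpc_two(25L, hidden_dim = 5L, seed = seed, lr_weights = 3e-3)
  tpc_train(m, bar, n_epochs = 2000L, tol = 0, n_starts = 5L)
}
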
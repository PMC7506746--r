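# Shared fixtures, built in code.

# Independent oracle for the window-label assignment rule, written as a
# plain loop so it shares no code with the vectorized implementation.
brute_assign <- function(label_seq, r) {
  distinct <- c()
  for (v in label_seq) if (!(v %in% distinct)) distinct <- c(distinct, v)
  if (length(distinct) >= 3) return(NA_integer_)
  if (length(distinct) == 1) return(distinct[1])
  newest <- label_seq[length(label_seq)]
  run <- 0
  i <- length(label_seq)
  while (i >= 1 && label_seq[i] == newest) {
    run <- run + 1
    i <- i - 1
  }
  if (run >= r) newest else distinct[distinct != newest][1]
}

# random window holding exactly two labels: an initial run of `old`
# followed by arbitrary interleaving that ends in `new`
random_two_label_window <- function(w = 14L) {
  labs <- sample(1:4, 2L)
  k <- sample(seq_len(w - 1L), 1L)           # terminal run of the new label
  head <- sample(labs, w - k, replace = TRUE)
  head[1L] <- labs[1L]
  while (all(head == labs[2L])) head <- sample(labs, w - k, replace = TRUE)
  c(head, rep(labs[2L], k))
}

# small labeled, standardized window dataset for model tests
small_dataset <- function(seed = 1L, duration_s = 20,
                          config = window_config()) {
  rec <- simulate_walk(make_gait_profile(seed, 1.0), duration_s)
  labs <- label_stream(rec)$right
  params <- fit_standardization(rec$features)
  build_window_dataset(apply_standardization(rec$features, params),
                       labs, config)
}
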
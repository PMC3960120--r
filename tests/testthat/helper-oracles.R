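# Independent brute-force oracles, kept free of the package's own code paths.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# pmf of the draw number at which object 1 appears, enumerating every
# equally likely draw order of a sequential no-replacement search
oracle_attempt_pmf <- function(set_size) {
  perms <- all_perms(set_size)
  pos <- apply(perms, 1L, function(p) which(p == 1L))
  as.numeric(table(factor(pos, levels = seq_len(set_size)))) / nrow(perms)
}

# pmf of the sum of n_trials attempt indices by full enumeration of the
# (set_size)^n_trials outcome grid
oracle_sum_pmf <- function(n_trials, set_size) {
  grid <- do.call(expand.grid, rep(list(seq_len(set_size)), n_trials))
  sums <- rowSums(grid)
  support <- seq.int(n_trials, n_trials * set_size)
  as.numeric(table(factor(sums, levels = support))) / set_size^n_trials
}

# binomial tail probabilities by enumerating all 2^n success/failure
# sequences (n <= 12 or so)
oracle_binom_tails <- function(k, n, p0) {
  grid <- do.call(expand.grid, rep(list(c(0L, 1L)), n))
  succ <- rowSums(grid)
  pr <- p0^succ * (1 - p0)^(n - succ)
  list(lower = sum(pr[succ <= k]), upper = sum(pr[succ >= k]))
}

random_trials <- function(n = 24L, set_size = 3L, subject = "s1",
                          experiment = "exp1", seed = 1L) {
  withr::with_seed(seed, {
    first <- sample.int(set_size, n, replace = TRUE)
    attempts <- ifelse(first == 1L, "target", "distracter;target")
    tibble::tibble(
      subject_id = subject, experiment = experiment,
      trial_index = seq_len(n), set_size = set_size, condition = "default",
      requested_label = paste0("lab", seq_len(n)),
      attempts = attempts,
      success_attempt = ifelse(first == 1L, 1L, 2L)
    )
  })
}
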
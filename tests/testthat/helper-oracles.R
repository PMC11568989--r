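# Independent brute-force oracles. These deliberately re-derive each quantity
# from its definition with naive loops, sharing no code with the package
# internals they check.

oracle_sliding_median3 <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    w <- sort(x[lo:hi])
    # shrunken edge window of length 2 would average; the stated convention
    # passes edge samples through untouched
    out[i] <- if (i == 1L || i == n) x[i] else w[2L]
  }
  out
}

oracle_autocorr <- function(x, tau_range) {
  n <- length(x)
  c0 <- sum(x * x) / n
  best <- -Inf
  for (tau in tau_range) {
    s <- 0
    for (t in seq_len(n - tau)) s <- s + x[t] * x[t + tau]
    best <- max(best, (s / (n - tau)) / c0)
  }
  best
}

# Prominence by exhaustive walk-down on the discrete grid.
oracle_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]; j <- i - 1L
  while (j >= 1L && y[j] <= y[i]) { left_min <- min(left_min, y[j]); j <- j - 1L }
  right_min <- y[i]; j <- i + 1L
  while (j <= n && y[j] <= y[i]) { right_min <- min(right_min, y[j]); j <- j + 1L }
  y[i] - max(left_min, right_min)
}

# Exhaustive two-class ReliefF: naive neighbor search and the textbook
# update, one feature at a time; neighbor counts cap at availability.
oracle_relieff <- function(X, y, K) {
  m <- nrow(X); p <- ncol(X)
  y <- as.character(y)
  prior <- table(y) / m
  W <- numeric(p)
  for (i in seq_len(m)) {
    d <- sapply(seq_len(m), function(j) sum(abs(X[i, ] - X[j, ])))
    same <- setdiff(which(y == y[i]), i)
    other <- which(y != y[i])
    kh <- min(K, length(same)); km <- min(K, length(other))
    hits <- same[order(d[same], same)][seq_len(kh)]
    misses <- other[order(d[other], other)][seq_len(km)]
    other_cl <- setdiff(names(prior), y[i])
    wmiss <- prior[[other_cl]] / (1 - prior[[y[i]]])
    for (f in seq_len(p)) {
      W[f] <- W[f] - sum(abs(X[i, f] - X[hits, f])) / (m * kh) +
        wmiss * sum(abs(X[i, f] - X[misses, f])) / (m * km)
    }
  }
  W
}

# quick jitterless or jittered walking subject
walk_subject <- function(seed = 1L, f_step = 2.0, timing_jitter = 0,
                         amp_jitter = 0, noise_sd = 0, duration_s = 60,
                         fs_hz = 100, label = "unknown") {
  generate_subject(
    gait_profile(f_step_hz = f_step, timing_jitter = timing_jitter,
                 amp_jitter = amp_jitter, noise_sd = noise_sd),
    duration_s = duration_s, fs_hz = fs_hz, seed = seed, label = label)
}

# planted-feature cohort: first `n_informative` columns shift with the class,
# the rest are noise; returned as a scaled feature_matrix
planted_matrix <- function(n_per_class = 20L, n_features = 20L,
                           n_informative = 5L, shift = 1.2, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * n_features), n, n_features)
  X[seq_len(n_per_class), seq_len(n_informative)] <-
    X[seq_len(n_per_class), seq_len(n_informative)] + shift
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  labels <- factor(rep(c("faller", "non_faller"), each = n_per_class),
                   levels = c("non_faller", "faller"))
  fm <- structure(list(X = X, subject_ids = sprintf("P%02d", seq_len(n)),
                       labels = labels,
                       excluded = data.frame(subject_id = character(),
                                             reason = character())),
                  class = "feature_matrix")
  minmax_scale(fm)
}
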
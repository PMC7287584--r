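# Independent oracle implementations used to cross-check the package.
# These deliberately use different code paths (plain R, different counting
# styles) from the implementations they validate.

# O(n^2) sample entropy pair counts, direct translation of the definition:
# unordered template pairs i < j over start indices 1..L-m, Chebyshev
# distance, computed with R vector arithmetic (one row of the pair matrix at
# a time) rather than the package's compiled scan.
brute_sampen_counts <- function(x, m, r) {
  n <- length(x) - m
  if (n < 2) return(c(0, 0))
  tmpl <- sapply(0:m, function(u) x[(1:n) + u])  # n x (m+1) template matrix
  B <- 0; A <- 0
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    dmax <- abs(tmpl[js, 1] - tmpl[i, 1])
    for (u in 2:m) dmax <- pmax(dmax, abs(tmpl[js, u] - tmpl[i, u]))
    hit <- dmax <= r
    B <- B + sum(hit)
    A <- A + sum(hit & abs(tmpl[js, m + 1] - tmpl[i, m + 1]) <= r)
  }
  c(B, A)
}

brute_sampen <- function(x, m, r) {
  cnt <- brute_sampen_counts(x, m, r)
  if (cnt[1] == 0 || cnt[2] == 0) return(NA_real_)
  -log(cnt[2] / cnt[1])
}

# Composite sample entropy at one scale: pool counts over all tau offsets of
# the block-mean coarse-graining, coarse means computed per block in R.
brute_composite_sampen <- function(x, m, r, tau) {
  Bsum <- 0; Asum <- 0
  for (off in seq_len(tau)) {
    nb <- (length(x) - off + 1L) %/% tau
    if (nb < m + 2) next
    y <- vapply(seq_len(nb), function(j)
      mean(x[(off + (j - 1) * tau):(off + j * tau - 1)]), numeric(1))
    cnt <- brute_sampen_counts(y, m, r)
    Bsum <- Bsum + cnt[1]; Asum <- Asum + cnt[2]
  }
  if (Bsum == 0 || Asum == 0) return(NA_real_)
  -log(Asum / Bsum)
}

# Permutation entropy via explicit order() patterns tabulated as strings.
brute_perm_entropy <- function(y, m) {
  n <- length(y) - m + 1L
  pats <- vapply(seq_len(n), function(i)
    paste(order(y[i:(i + m - 1)]), collapse = ","), character(1))
  p <- table(pats) / n
  -sum(p * log(p))
}

# ICC(A,1) with mean squares taken from stats::aov on long-format data.
icc_a1_aov <- function(a, b) {
  n <- length(a)
  d <- data.frame(y = c(a, b),
                  subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# Maximum-cardinality one-to-one matching count by exhaustive recursion
# (feasible for <= 8 reference events).
brute_max_matching <- function(ref, cand, tol) {
  best <- 0L
  recurse <- function(i, used, count) {
    if (i > length(ref)) { best <<- max(best, count); return(invisible()) }
    # upper-bound prune
    if (count + (length(ref) - i + 1L) <= best) return(invisible())
    recurse(i + 1L, used, count)  # leave ref[i] unmatched
    for (j in seq_along(cand)) {
      if (!used[j] && abs(ref[i] - cand[j]) <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(cand)), 0L)
  best
}

# Short synthetic session shared by several test files (30 s keeps the
# Madgwick and detection stages fast).
short_session <- function(seed = 5, duration_s = 30, ...) {
  simulate_session(gait_sim_params(seed = seed, duration_s = duration_s, ...))
}
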
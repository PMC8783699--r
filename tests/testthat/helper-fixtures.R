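# Shared fixtures: all inputs are generated in code at test time.

# a small deterministic feature table with plausible physiology
toy_feature_table <- function(n = 20L, seed = 42L, record_id = "toy") {
  set.seed(seed)
  ptt <- runif(n, 0.15, 0.35)
  pir <- runif(n, 1.2, 2.8)
  hr <- runif(n, 55, 110)
  dbp <- 60 + 20 * runif(n)
  data.frame(record_id = record_id, cycle_index = seq_len(n) - 1L,
             ptt_s = ptt, pir_ratio = pir, hr_bpm = hr,
             sbp_mmHg = dbp + 30 + 15 * runif(n), dbp_mmHg = dbp)
}

# a noise-free single-regime spec for closure checks
quiet_regime <- function(n_beats = 30L, regime_id = 1L,
                         hr = 70, ptt = 0.22, pir = 1.8) {
  regime_spec(regime_id, hr_mean_bpm = hr, hr_sd = 0, ptt_mean_s = ptt,
              ptt_sd = 0, pir_mean = pir, pir_sd = 0,
              sbp_coeffs = list(intercept = 160, ptt = -150, pir = 5, hr = 0.1),
              dbp_coeffs = list(intercept = 100, ptt = -90, pir = 2, hr = 0.05),
              noise_sd_mmHg = 0, n_beats = n_beats)
}

# brute-force oracles, written independently of the implementations
oracle_mae <- function(est, ref) {
  tot <- 0
  for (i in seq_along(est)) tot <- tot + abs(ref[i] - est[i])
  tot / length(est)
}

oracle_rmse <- function(est, ref) {
  tot <- 0
  for (i in seq_along(est)) tot <- tot + (ref[i] - est[i])^2
  sqrt(tot / length(est))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# O(n^2) silhouette by explicit loops over points and clusters
oracle_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  lev <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    own <- labels[i]
    n_own <- sum(labels == own)
    if (n_own == 1L) { s[i] <- 0; next }
    a <- sum(d[labels == own & seq_len(n) != i]) / (n_own - 1L)
    b <- Inf
    for (g in lev[lev != own]) b <- min(b, mean(d[labels == g]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
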
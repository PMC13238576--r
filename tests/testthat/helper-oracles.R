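# Independent oracles, deliberately naive and separate from the package code.

# EHF by direct double loop over windows (forward orientation):
# sig_mean(i) = mean(x[i..i+k-1]); accl_mean(i) = mean(x[i-m..i-1])
naive_ehf <- function(x, t95, k = 3L, m = 30L) {
  n <- length(x)
  out <- data.frame(ehi_sig = rep(NA_real_, n), ehi_accl = NA_real_,
                    ehf = NA_real_)
  for (i in seq_len(n)) {
    if (i + k - 1 > n || i - m < 1) next
    sig <- 0; for (j in i:(i + k - 1)) sig <- sig + x[j]
    sig <- sig / k
    acc <- 0; for (j in (i - m):(i - 1)) acc <- acc + x[j]
    acc <- acc / m
    out$ehi_sig[i] <- sig - t95
    out$ehi_accl[i] <- sig - acc
    out$ehf[i] <- (sig - t95) * max(1, sig - acc)
  }
  out
}

# full unconditional Poisson MLE with stratum dummy intercepts (glm), the
# equivalence oracle for the conditional fitter on small instances
glm_dummy_oracle <- function(y, X, stratum) {
  d <- data.frame(y = y, X, stratum = factor(stratum))
  f <- stats::as.formula(paste("y ~", paste(colnames(X), collapse = " + "),
                               "+ stratum"))
  fit <- stats::glm(f, family = stats::poisson(), data = d,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  stats::coef(fit)[colnames(X)]
}

# random small conditional-Poisson instance with within-stratum variation
random_cc_instance <- function(seed, max_strata = 6L, max_days = 8L, p = 4L) {
  set.seed(seed)
  k <- sample(2:max_strata, 1)
  rows <- sample(4:max_days, k, replace = TRUE)
  n <- sum(rows)
  X <- cbind(x1 = rbinom(n, 1, 0.4), x2 = rbinom(n, 1, 0.3),
             x3 = rnorm(n, 0, 0.5), x4 = round(runif(n, 0, 2), 2))
  stratum <- rep(seq_len(k), rows)
  eta <- log(6) + drop(X %*% c(0.3, -0.2, 0.15, 0.1))
  y <- rpois(n, exp(eta))
  list(y = y, X = X, stratum = stratum)
}

make_small_series <- function(tmean, start = "2001-01-01", region = "R1",
                              rh = 50) {
  region_daily_series(region,
                      seq(as.Date(start), by = "day",
                          length.out = length(tmean)),
                      tmean, rh_pct = rep(rh, length(tmean)))
}
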
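# Independent numerical oracles used across the suite. These deliberately
# avoid the code paths they check: F statistics come from explicit
# residual-sum-of-squares comparisons of nested least-squares fits, and
# studentized-range tail probabilities from direct numeric integration.

# RSS of the least-squares fit of y on the columns of X (QR, no lm()).
rss_qr <- function(y, X) {
  fit <- qr(X)
  sum((y - X %*% qr.coef(fit, y))^2)
}

# F test of H0: the extra columns of X_full beyond X_red are zero,
# by nested-model residual-SS comparison.
f_nested <- function(y, X_full, X_red) {
  r_f <- rss_qr(y, X_full)
  r_r <- rss_qr(y, X_red)
  df1 <- qr(X_full)$rank - qr(X_red)$rank
  df2 <- length(y) - qr(X_full)$rank
  F_ <- ((r_r - r_f) / df1) / (r_f / df2)
  list(F = F_, df1 = df1, df2 = df2,
       p = stats::pf(F_, df1, df2, lower.tail = FALSE))
}

# One-way ANOVA F from the group-indicator projection, for the oracle side.
f_oneway_oracle <- function(y, g) {
  g <- factor(g)
  X_full <- stats::model.matrix(~g)
  X_red <- matrix(1, length(y), 1)
  f_nested(y, X_full, X_red)
}

# Upper-tail probability of the studentized range with k means and df error
# degrees of freedom, by direct double numeric integration:
#   P(Q <= q) = int_0^inf f_S(s) * k * int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# where S = sqrt(chisq_df / df) with density f_S(s) = 2 df s dchisq(df s^2, df).
ptukey_oracle <- function(q, k, df, lower.tail = FALSE) {
  inner <- function(s) {
    vapply(s, function(si) {
      g <- function(z) {
        stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * si))^(k - 1)
      }
      k * stats::integrate(g, -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  f_s <- function(s) 2 * df * s * stats::dchisq(df * s^2, df)
  cdf <- stats::integrate(function(s) f_s(s) * inner(s), 0, Inf,
                          rel.tol = 1e-9)$value
  if (lower.tail) cdf else 1 - cdf
}

# Quick generator for a small random one-factor dataset.
random_groups <- function(k = 3, n_per = 10, unbalanced = FALSE) {
  ns <- if (unbalanced) sample(4:12, k, replace = TRUE) else rep(n_per, k)
  g <- factor(rep(seq_len(k), ns))
  y <- stats::rnorm(sum(ns), mean = as.numeric(g) * stats::runif(1, 0, 2))
  list(y = y, g = g)
}
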
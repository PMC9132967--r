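# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain R, template matrices
# materialized explicitly, per-row loops.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# summed match quantities at template lengths m and m+1 (ordered pairs)
naive_pair_sums <- function(x, m, r_abs, fuzzy = TRUE, exponent = 2,
                            convention = "gaussian_ratio", demean = TRUE) {
  N <- length(x)
  Tn <- N - m
  out <- c(0, 0)
  for (li in 1:2) {
    len <- m + li - 1
    M <- matrix(0, Tn, len)
    for (k in seq_len(len)) M[, k] <- x[(seq_len(Tn)) + k - 1]
    if (fuzzy && demean) M <- M - rowMeans(M)
    tot <- 0
    for (i in seq_len(Tn - 1)) {
      d <- rep(0, Tn - i)
      for (k in seq_len(len)) d <- pmax(d, abs(M[i, k] - M[(i + 1):Tn, k]))
      tot <- tot + if (fuzzy) {
        if (convention == "gaussian_ratio") {
          sum(exp(-(d / r_abs)^exponent))
        } else {
          sum(exp(-d^exponent / r_abs))
        }
      } else {
        sum(d <= r_abs)
      }
    }
    out[li] <- tot
  }
  out
}

naive_entropy <- function(x, m = 2, r = 0.2, fuzzy = TRUE, exponent = 2,
                          convention = "gaussian_ratio", demean = TRUE,
                          r_abs = NULL) {
  if (is.null(r_abs)) r_abs <- r * pop_sd(x)
  s <- naive_pair_sums(x, m, r_abs, fuzzy, exponent, convention, demean)
  if (s[2] == 0) NA_real_ else log(s[1] / s[2])
}

naive_grain <- function(x, tau, offset = 0) {
  L <- (length(x) - offset) %/% tau
  vapply(seq_len(L), function(j) mean(x[(offset + (j - 1) * tau + 1):(offset + j * tau)]),
         numeric(1))
}

# multiscale curve that materializes every offset grain explicitly
naive_mse <- function(x, m = 2, r = 0.2, tau_max = 10,
                      method = "rcmse", fuzzy = TRUE) {
  r_abs <- r * pop_sd(x)
  vapply(seq_len(tau_max), function(tau) {
    if (method == "mse") {
      s <- naive_pair_sums(naive_grain(x, tau, 0), m, r_abs, fuzzy)
      return(if (s[2] == 0) NA_real_ else log(s[1] / s[2]))
    }
    sums <- sapply(0:(tau - 1), function(k) {
      naive_pair_sums(naive_grain(x, tau, k), m, r_abs, fuzzy)
    })
    if (method == "cmse") {
      if (any(sums[2, ] == 0)) NA_real_ else mean(log(sums[1, ] / sums[2, ]))
    } else {
      if (sum(sums[2, ]) == 0) NA_real_ else log(sum(sums[1, ]) / sum(sums[2, ]))
    }
  }, numeric(1))
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
enum_mw_p <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  stopifnot(anyDuplicated(pooled) == 0)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  u_all <- apply(idx, 2, function(ii) sum(rk[ii]) - na * (na + 1) / 2)
  mu <- na * nb / 2
  if (u_obs == mu) return(1)
  p <- if (u_obs > mu) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(p, 1)
}
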
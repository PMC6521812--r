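# Independent brute-force oracles for the exact rank-test distributions.
# These enumerate the full permutation / sign-flip null and never call the
# package's test path.

# Mann-Whitney U for group x vs y (no ties assumed)
mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# exact rank-sum p by enumerating all C(n1+n2, n1) group assignments
oracle_rank_sum <- function(x, y, alternative = "two_sided") {
  pool <- c(x, y)
  n1 <- length(x)
  u_obs <- mw_u(x, y)
  combs <- utils::combn(length(pool), n1)
  us <- apply(combs, 2, function(idx) mw_u(pool[idx], pool[-idx]))
  if (alternative == "greater") return(mean(us >= u_obs))
  min(1, 2 * min(mean(us >= u_obs), mean(us <= u_obs)))
}

# exact signed-rank p by enumerating all 2^n sign patterns of |d| ranks
oracle_signed_rank <- function(d, alternative = "two_sided") {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% rk)
  if (alternative == "greater") return(mean(vs >= v_obs))
  min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs)))
}

# tie-free sample generator on a fixed-resolution grid
tie_free_pair <- function(n1, n2) {
  v <- sample(seq(1, 500), n1 + n2, replace = FALSE) / 10
  list(x = v[seq_len(n1)], y = v[-seq_len(n1)])
}

# short synthetic recording around a given diameter vector
make_recording <- function(diameter, fs = 10, valid = NULL, id = "t") {
  t <- (seq_along(diameter) - 1) / fs
  pupil_recording(t, diameter, valid, subject_id = id,
                  sampling_rate_hz = fs)
}
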
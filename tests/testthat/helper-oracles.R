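# full-enumeration oracles for the rank tests

# exact two-sided Mann-Whitney p by enumerating all group assignments
mw_enum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  vals <- c(a, b)
  u_stat <- function(x, y) sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  u_obs <- u_stat(a, b)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) u_stat(vals[idx], vals[-idx]))
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# exact one-sample signed-rank p by enumerating all sign flips
wsr_enum_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  switch(alternative,
         greater = mean(ws >= w_obs - 1e-12),
         less = mean(ws <= w_obs + 1e-12),
         two.sided = {
           mu <- n * (n + 1) / 4
           mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
         })
}
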
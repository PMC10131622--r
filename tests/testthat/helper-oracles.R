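# Independent brute-force oracle for the signed-rank test: enumerate all
# 2^n sign assignments of the absolute-difference ranks directly.
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(ranks[signs])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
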
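# independent enumeration oracle for the one-sided signed-rank p-value
enum_signed_rank_p <- function(x, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(NA_real_)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    wp <- sum(r[bits == 1L])
    hit <- if (alternative == "greater") wp >= w - 1e-9 else wp <= w + 1e-9
    if (hit) count <- count + 1L
  }
  count / 2^n
}
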
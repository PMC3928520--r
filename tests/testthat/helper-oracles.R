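# Independent oracles kept deliberately naive: exhaustive enumeration and
# direct counting, never the code paths they check.

# P(overlap >= k) by enumerating every possible dataset draw of size d from
# a universe of size u in which the first t genes are the targets.
enum_overlap_tail <- function(u, t, d, k) {
  if (d == 0L) return(as.numeric(k <= 0L))
  draws <- utils::combn(u, d)
  mean(colSums(draws <= t) >= k)
}

# finding aggregation by direct counting
count_aggregate <- function(signs) {
  np <- sum(signs == 1); nm <- sum(signs == -1)
  if (np + nm == 0 || np == nm) return(list(sign = 0L, weight = 0))
  if (np > nm) list(sign = 1L, weight = np / (np + nm))
  else list(sign = -1L, weight = nm / (np + nm))
}
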
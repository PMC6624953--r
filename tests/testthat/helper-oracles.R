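# Independent oracles: deliberately naive implementations used to check the
# package's algorithms. They share no code with the package internals.

# Poisson negative log-likelihood cost of one constant-mean segment
# (up to data-only constants), computed naively.
oracle_cost <- function(x) {
  S <- sum(x)
  if (S == 0) 0 else S - S * log(S / length(x))
}

# Exhaustive recursive change-point search: at each level try every split
# position, take the minimum total cost (ties toward the most downstream
# split), accept under the drop and fold rules, recurse. Returns all end
# positions including the extinction end.
oracle_segment <- function(v, min_fold = 0.8, min_len = 100,
                           split_penalty = 1) {
  nz <- which(v > 0)
  if (length(nz) == 0) return(integer(0))
  v <- v[seq_len(max(nz))]
  penalty <- split_penalty * log(length(v))
  rec <- function(l, r) {
    lo <- l + min_len - 1
    hi <- r - min_len
    if (lo > hi) return(integer(0))
    ts <- lo:hi
    costs <- vapply(ts, function(t) {
      oracle_cost(v[l:t]) + oracle_cost(v[(t + 1):r])
    }, numeric(1))
    t <- ts[max(which(costs == min(costs)))]
    up <- mean(v[l:t])
    down <- mean(v[(t + 1):r])
    improvement <- oracle_cost(v[l:r]) - min(costs)
    if (!(up > 0 && down < up && down / up <= min_fold &&
            improvement > penalty)) return(integer(0))
    c(rec(l, t), t, rec(t + 1, r))
  }
  sort(c(rec(1, length(v)), length(v)))
}

# Union-find over the pairwise "< window apart" relation; returns the list
# of clusters (sorted member vectors) in ascending order.
oracle_merge <- function(ends, window = 100) {
  ends <- sort(ends)
  n <- length(ends)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(ends[i] - ends[j]) < window) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(ends, roots), sort))
}

# Noiseless nested-isoform 3'UTR coverage for a planted abundance vector:
# depth at position p is scale times the summed abundance of isoforms whose
# end is at or beyond p.
oracle_nested_coverage <- function(ends, abundances, scale = 1) {
  n <- max(ends)
  vapply(seq_len(n), function(p) scale * sum(abundances[ends >= p]),
         numeric(1))
}

# naive per-base interval sum on a depth vector over 0-based [a, b)
oracle_interval_sum <- function(depth, start0, a, b) {
  idx <- seq.int(a - start0 + 1, b - start0)
  if (length(idx) == 0) 0 else sum(depth[idx])
}
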
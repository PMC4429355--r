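# Independent oracles used to check the package's fast implementations.

# Dense O(n^2) kernel sums, no truncation.
dense_kernel_sums <- function(pos, y, sigma) {
  n <- length(pos)
  w <- exp(-outer(pos, pos, "-")^2 / (2 * sigma^2))
  list(S_KY = as.numeric(w %*% y),
       S_K = rowSums(w),
       S_KK = rowSums(w^2))
}

# Sort-based BH step-up, written directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# O(n^2) transitive-closure merge of positions at gap <= lambda:
# returns a group label per (sorted) position.
merge_oracle <- function(pos, lambda) {
  pos <- sort(pos)
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= lambda
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(adj[i, ])
      g <- min(grp[linked])
      if (any(grp[linked] != g)) {
        grp[linked] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(pos, grp)
}

# small manifest on one chromosome at given positions
toy_manifest <- function(pos, chrom = "chr1", ...) {
  as_manifest(data.frame(
    probe_id = sprintf("p%03d", seq_along(pos)),
    chrom = chrom, pos = pos, ...
  ))
}
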
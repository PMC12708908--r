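# Independent brute-force oracles used to pin down expected values.

# minimum total DTW cost by exhaustive recursion over all warping paths
oracle_dtw_cost <- function(a, b) {
  rec <- function(i, j) {
    c <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    c + best
  }
  rec(length(a), length(b))
}

# O(n^2) Hausdorff on point sets given as two-column matrices
oracle_hausdorff <- function(A, B) {
  dmat <- outer(seq_len(nrow(A)), seq_len(nrow(B)), Vectorize(function(i, j)
    sqrt(sum((A[i, ] - B[j, ])^2))))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

oracle_point_seg <- function(p, s1, s2) {
  v <- s2 - s1
  L2 <- sum(v^2)
  t <- if (L2 > 0) max(0, min(1, sum((p - s1) * v) / L2)) else 0
  sqrt(sum((p - (s1 + t * v))^2))
}

oracle_spd <- function(A, B) {
  mean(vapply(seq_len(nrow(A)), function(i) {
    min(vapply(seq_len(nrow(B) - 1), function(j)
      oracle_point_seg(A[i, ], B[j, ], B[j + 1, ]), numeric(1)))
  }, numeric(1)))
}

# exhaustive scan over all (valley, peak) pairs under the trough-to-peak
# criterion: peak paired with the most recent preceding valley, accepted when
# the rise is >= min_amp and the valley-to-peak latency <= max_rise_s
oracle_scr_scan <- function(x, fs, min_amp = 0.05, max_rise_s = 5) {
  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n], FALSE)
  is_valley <- c(FALSE, x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n], FALSE)
  peaks <- which(is_peak); valleys <- which(is_valley)
  hits <- NULL
  for (pk in peaks) {
    cand <- valleys[valleys < pk]
    if (length(cand) == 0) next
    vl <- max(cand)
    if (x[pk] - x[vl] >= min_amp && (pk - vl) / fs <= max_rise_s)
      hits <- rbind(hits, c(valley = (vl - 1) / fs, peak = (pk - 1) / fs,
                            amp = x[pk] - x[vl]))
  }
  hits
}
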
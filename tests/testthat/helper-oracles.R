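# Independent oracles, deliberately written with naive algorithms and no
# shared code with the implementation under test.

# Character-by-character Hamming distance for two strings.
oracle_hamming <- function(x, y) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  sum(a != b)
}

# Brute-force RSEC fixpoint on one UMI group: repeatedly find the
# lowest-read UMI (ties: lexicographically smallest) that has a
# Hamming-1 neighbour with reads >= 2*child - 1, and merge it into the
# highest-read such neighbour (ties: lexicographically smallest).
oracle_rsec_group <- function(umis, reads) {
  repeat {
    n <- length(umis)
    pick <- NULL
    ord <- order(reads, umis)
    for (i in ord) {
      elig <- integer(0)
      for (j in seq_len(n)) {
        if (i == j) next
        if (oracle_hamming(umis[i], umis[j]) == 1 &&
            reads[j] >= 2 * reads[i] - 1) {
          elig <- c(elig, j)
        }
      }
      if (length(elig)) {
        elig <- elig[order(-reads[elig], umis[elig])]
        pick <- c(i, elig[1])
        break
      }
    }
    if (is.null(pick)) break
    reads[pick[2]] <- reads[pick[2]] + reads[pick[1]]
    umis <- umis[-pick[1]]
    reads <- reads[-pick[1]]
  }
  o <- order(umis)
  data.frame(umi = umis[o], reads = reads[o], stringsAsFactors = FALSE)
}

# Exhaustive scan of all two-class splits minimising total within-class
# sum of squares; returns the low-class members when the class means are
# separated by at least `margin`, else integer(0).
oracle_dbec_low_class <- function(values, margin = 1) {
  n <- length(values)
  if (n < 2 || length(unique(values)) < 2) return(integer(0))
  v <- sort(values)
  best_ss <- Inf
  best_k <- NA
  for (k in 1:(n - 1)) {
    if (v[k] == v[k + 1]) next
    lo <- v[1:k]
    hi <- v[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best_k <- k
    }
  }
  if (is.na(best_k)) return(integer(0))
  lo <- v[1:best_k]
  hi <- v[(best_k + 1):n]
  if (mean(hi) - mean(lo) >= margin) {
    which(values <= v[best_k])
  } else {
    integer(0)
  }
}

# PCA oracle: eigendecomposition of the sample covariance matrix.
oracle_pca <- function(x, k) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  scores <- xc %*% ev$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores,
       ratio = (ev$values / sum(ev$values))[seq_len(k)])
}
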
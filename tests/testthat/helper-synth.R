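# shared fixtures, generated in code (cached so the expensive default-scale
# dataset is built once per test run)
.cache <- new.env(parent = emptyenv())

defaultSynthData <- function() {
  if (is.null(.cache$full)) .cache$full <- simulateDataset(seed = 1)
  .cache$full
}

smallSynthData <- function() {
  if (is.null(.cache$small))
    .cache$small <- simulateDataset(12, 20, seed = 42, canvas = c(64, 64))
  .cache$small
}

# independent per-pixel counting oracle: assigns each pixel to its column
# and row strip by cumulative strip sizes and sums white pixels in a loop
bruteGridCounts <- function(mask, grid) {
  nr <- nrow(mask); nc <- ncol(mask)
  sizesOf <- function(n, k) {
    q <- n %/% k; r <- n %% k
    c(rep(q + 1L, r), rep(q, k - r))
  }
  colStrip <- findInterval(seq_len(nc), cumsum(sizesOf(nc, grid[2])) + 1L) + 1L
  rowStrip <- findInterval(seq_len(nr), cumsum(sizesOf(nr, grid[1])) + 1L) + 1L
  colCounts <- numeric(grid[2]); rowCounts <- numeric(grid[1])
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] != 0) {
      colCounts[colStrip[j]] <- colCounts[colStrip[j]] + 1
      rowCounts[rowStrip[i]] <- rowCounts[rowStrip[i]] + 1
    }
  }
  c(colCounts, rowCounts)
}

randomMask <- function(nr, nc, p = 0.4) {
  matrix(ifelse(runif(nr * nc) < p, 255L, 0L), nr, nc)
}

# entropy-based information gain of a binary threshold split, computed from
# first principles for the decision-tree oracle
infoGain <- function(feature, labels, cut) {
  ent <- function(y) {
    p <- table(y) / length(y)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  left <- labels[feature < cut]; right <- labels[feature >= cut]
  if (!length(left) || !length(right)) return(-Inf)
  ent(labels) - (length(left) * ent(left) + length(right) * ent(right)) /
    length(labels)
}
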
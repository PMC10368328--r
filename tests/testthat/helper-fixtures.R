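# in-code fixtures shared across test files

aaAlphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# small random alignment with an optional perfectly/partially separating
# column planted at 'signalAt'
makeToyAlignment <- function(n0 = 12, n1 = 16, L = 20, signalAt = integer(0),
                             penetrance = 1, seed = 1,
                             labels = c("C3", "C4"), gene = "toy") {
  set.seed(seed)
  n <- n0 + n1
  m <- matrix(sample(c("A", "S"), n * L, replace = TRUE,
                     prob = c(0.7, 0.3)), n, L)
  lab <- rep(labels, c(n0, n1))
  for (j in signalAt) {
    m[, j] <- "G"
    alt <- lab == labels[2] & runif(n) < penetrance
    m[alt, j] <- "W"
  }
  ids <- sprintf("s%02d", seq_len(n))
  seqs <- setNames(apply(m, 1, paste0, collapse = ""), ids)
  LabeledAlignment(seqs, gene = gene, labels = lab)
}

# plain numeric design matrix with labels, for CV-engine tests
makeToyMatrix <- function(n0 = 20, n1 = 20, p = 5, signalCols = integer(0),
                          flip = 0, seed = 1) {
  set.seed(seed)
  n <- n0 + n1
  X <- matrix(rbinom(n * p, 1, 0.4), n, p)
  y <- rep(c("neg", "pos"), c(n0, n1))
  for (j in signalCols) {
    X[, j] <- as.numeric(y == "pos")
    if (flip > 0) {
      k <- sample(n, round(flip * n))
      X[k, j] <- 1 - X[k, j]
    }
  }
  colnames(X) <- paste0("toy:", seq_len(p))
  list(X = X, y = y)
}

# independent double-loop MPD oracle (gap==gap same, gap!=residue differ)
mpdOracle <- function(rows) {
  rows <- toupper(rows)
  n <- length(rows)
  tot <- 0
  cmp <- strsplit(rows, "")
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(cmp[[i]] != cmp[[j]])
  tot / (n * (n - 1) / 2)
}

quietCV <- function(...) suppressWarnings(repeatedSubsampleCV(...))
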
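# shared fixture builders; everything is generated in code at test time

# assemble a SymptomDataset directly from parts
makeDataset <- function(X, drug, sev, symptom = "tox") {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = X),
    colData = S4Vectors::DataFrame(drug = drug,
                                   severity = as.integer(sev),
                                   occurrence = sev >= 1L,
                                   row.names = colnames(X)))
  new("SymptomDataset", se, symptom = symptom)
}

# random labelled expression matrix with dimnames
randomExpr <- function(p, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(p * n), p, n,
         dimnames = list(sprintf("g%03d", seq_len(p)),
                         sprintf("s%03d", seq_len(n))))
}

# small multi-drug dataset with a planted linear severity signal in the
# first `nsig` genes; drugs partition the samples evenly
plantedDataset <- function(nDrugs = 12, perDrug = 10, p = 60, nsig = 4,
                           es = 1.0, seed = 1, symptom = "tox") {
  set.seed(seed)
  n <- nDrugs * perDrug
  drug <- rep(sprintf("D%02d", seq_len(nDrugs)), each = perDrug)
  toxic <- rep(c(TRUE, FALSE), length.out = nDrugs)
  sev <- integer(n)
  for (d in which(toxic)) {
    i <- (d - 1) * perDrug + seq_len(perDrug)
    sev[i] <- pmin(4L, floor((seq_len(perDrug) - 1) / perDrug * 5))
  }
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%03d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  for (j in seq_len(nsig)) X[j, ] <- X[j, ] + es * sev
  makeDataset(X, drug, sev, symptom)
}

# brute-force Spearman: average ranks, then Pearson
oracleSpearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# brute-force AUC: exhaustive case-control pair counting, ties credited 1/2
oracleAuc <- function(pred, occ) {
  pos <- pred[occ]; neg <- pred[!occ]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force one-way ANOVA from sums of squares
oracleAnova <- function(x, g) {
  groups <- split(x, g)
  k <- length(groups); n <- length(x)
  grand <- mean(x)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = F, p = stats::pf(F, k - 1, n - k, lower.tail = FALSE))
}

# closed-form Welch t with Satterthwaite df
oracleWelch <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  v1 <- stats::var(x1); v0 <- stats::var(x0)
  se2 <- v1 / n1 + v0 / n0
  t <- (mean(x1) - mean(x0)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# exhaustive upper-tail hypergeometric by direct combinatorial enumeration
oracleHyper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
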
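# Shared fixtures: everything is generated in code at test time.

# Short chains for unit tests; production defaults are larger.
fastControl <- function(chains = 2, adapt = 250, burnin = 150, iter = 500)
  mcmcControl(chains = chains, adapt = adapt, burnin = burnin, iter = iter,
              minEss = 20)

# Small class-parameter fixture with a mix of null and non-null metabolites.
tinyParams <- function(m = 6) {
  delta <- seq(0, 1, length.out = m) * rep_len(c(1, -1), m)
  R <- matrix(0.2, m, m); diag(R) <- 1
  nm <- paste0("met", seq_len(m))
  muD <- delta / 2; muS <- -delta / 2
  names(muD) <- names(muS) <- nm
  dimnames(R) <- list(nm, nm)
  new("ClassParams", muD = muD, SigmaD = R, muS = muS, SigmaS = R,
      nD = 50L, nS = 50L)
}

# Complete log-z-scaled MetaboSet with known class structure.
makeZSet <- function(nPerGroup = 50, m = 6, delta = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(delta)) delta <- seq(0, 1, length.out = m)
  xd <- sweep(matrix(rnorm(nPerGroup * m), nPerGroup, m), 2, delta / 2, `+`)
  xs <- sweep(matrix(rnorm(nPerGroup * m), nPerGroup, m), 2, -delta / 2, `+`)
  MetaboSet(rbind(xd, xs), outcome = rep(c(1, 0), each = nPerGroup),
            scaleState = "log_zscaled")
}

# Raw-scale concentration table written to a temp CSV.
writeRawCsv <- function(values, outcome, path = tempfile(fileext = ".csv")) {
  df <- data.frame(sample_id = paste0("s", seq_len(nrow(values))),
                   died = outcome)
  df <- cbind(df, as.data.frame(values))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# Independent step-up BH oracle (direct implementation of the definition).
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent Newton-Raphson logistic MLE oracle.
newtonLogistic <- function(x, y, iters = 50) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(iters)) {
    eta <- as.numeric(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    b <- b + solve(t(X) %*% (X * W), t(X) %*% (y - p))
  }
  as.numeric(b)
}
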
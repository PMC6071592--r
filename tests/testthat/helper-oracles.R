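# Independent brute-force oracles used to cross-check the package kernels.
# These recompute everything from first principles (contingency tables,
# explicit normal equations) and deliberately share no code with R/.

# r^2 from the 2x2 genotype contingency table, complete pairs only
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  p11 <- sum(x == 1 & y == 1) / n
  px <- sum(x == 1) / n
  py <- sum(y == 1) / n
  d <- p11 - px * py
  d^2 / (px * (1 - px) * py * (1 - py))
}

# second-order LD by explicitly building the four one-vs-rest recodings of
# the two-locus genotype classes and taking the max defined r^2
oracle_second_order <- function(g1, g2, q) {
  ok <- !is.na(g1) & !is.na(g2) & !is.na(q)
  g1 <- g1[ok]
  g2 <- g2[ok]
  q <- q[ok]
  combos <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)) # AB, Ab, aB, ab
  r2 <- vapply(combos, function(cm) {
    p <- as.integer(g1 == cm[1] & g2 == cm[2])
    oracle_r2(p, q)
  }, numeric(1))
  if (all(is.na(r2))) {
    list(r2 = NA_real_, per = r2, best = NA_integer_)
  } else {
    list(r2 = max(r2, na.rm = TRUE), per = r2, best = which.max(r2))
  }
}

# OLS of y on X by explicit normal equations, with t-test p-values
oracle_ols <- function(y, X) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  tval <- as.numeric(beta) / se
  list(
    beta = as.numeric(beta), se = se,
    p = 2 * pt(-abs(tval), df = df)
  )
}

# random polymorphic genotype column (retries until polymorphic)
random_column <- function(n, p = NULL) {
  repeat {
    if (is.null(p)) p <- runif(1, 0.1, 0.9)
    g <- rbinom(n, 1, p)
    if (length(unique(g)) == 2) return(g)
  }
}

# small random genotype matrix with a deterministic uniform map
random_panel <- function(n, m, seed, chromosome = "1") {
  withr::with_seed(seed, {
    codes <- vapply(seq_len(m), function(i) random_column(n), integer(n))
    geno_matrix(
      codes,
      paste0("i", seq_len(n)),
      tibble::tibble(
        marker_id = paste0("m", seq_len(m)),
        chromosome = chromosome,
        position = as.integer(seq(1e5, 3e7, length.out = m))
      )
    )
  })
}

# random marker map over a few chromosomes (positions unique per chromosome)
random_map <- function(n_markers, seed, n_chrom = 3) {
  withr::with_seed(seed, {
    chrom <- sample(as.character(seq_len(n_chrom)), n_markers, replace = TRUE)
    pos <- integer(n_markers)
    for (ch in unique(chrom)) {
      k <- sum(chrom == ch)
      pos[chrom == ch] <- sample.int(5e6, k)
    }
    tibble::tibble(
      marker_id = paste0("r", seq_len(n_markers)),
      chromosome = chrom, position = pos
    )
  })
}
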
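test_that("additive coding maps homozygotes to +1/-1 and products to the
           coupling/repulsion indicator", {
  expect_equal(encode_additive(c(0, 1, NA)), c(1, -1, NA))
  # one individual per two-locus class AB, Ab, aB, ab
  a1 <- encode_additive(c(0, 0, 1, 1))
  a2 <- encode_additive(c(0, 1, 0, 1))
  expect_equal(a1 * a2, c(1, -1, -1, 1))
})

test_that("the perfectly tagged scenario yields beta12 = +0.25 with zero noise", {
  sc <- make_perfect_tag_scenario(n_per_class = 2)
  f <- fit_two_locus_model(
    sc$phenotype$value,
    marker_codes(sc$genotypes, "M1"),
    marker_codes(sc$genotypes, "M2")
  )
  est <- tidy(f)$estimate
  expect_equal(est, c(0.25, -0.25, -0.25, 0.25), tolerance = 1e-12)
  # the generative model is single-locus additive: the interaction is
  # statistical, not functional
  expect_false(any(f$aliased))
})

test_that("an exactly additive phenotype has zero interaction", {
  a1 <- encode_additive(c(0, 0, 1, 1, 0, 0, 1, 1))
  g2 <- c(0, 1, 0, 1, 0, 1, 0, 1)
  f <- fit_two_locus_model(a1, c(0, 0, 1, 1, 0, 0, 1, 1), g2)
  est <- tidy(f)$estimate
  expect_equal(est[2], 1, tolerance = 1e-12)
  expect_equal(est[3], 0, tolerance = 1e-12)
  expect_equal(est[4], 0, tolerance = 1e-12)
  expect_equal(glance(f)$r.squared, 1)
})

test_that("OLS fits match an explicit normal-equations oracle", {
  withr::with_seed(201, {
    for (rep in 1:25) {
      n <- 30
      g1 <- random_column(n)
      g2 <- random_column(n)
      y <- rnorm(n)
      a1 <- encode_additive(g1)
      a2 <- encode_additive(g2)
      X <- cbind(1, a1, a2, a1 * a2)
      if (qr(X)$rank < 4) next
      f <- fit_two_locus_model(y, g1, g2)
      orc <- oracle_ols(y, X)
      expect_equal(tidy(f)$estimate, orc$beta, tolerance = 1e-10)
      expect_equal(tidy(f)$std.error, unname(orc$se), tolerance = 1e-10)
      expect_equal(tidy(f)$p.value, unname(orc$p), tolerance = 1e-10)
    }
  })
})

test_that("fits are invariant to allele relabeling up to coefficient signs", {
  withr::with_seed(211, {
    g1 <- random_column(40)
    g2 <- random_column(40)
    y <- rnorm(40)
    f <- fit_two_locus_model(y, g1, g2)
    fr <- fit_two_locus_model(y, 1 - g1, g2)
    expect_equal(abs(tidy(f)$estimate[-1]), abs(tidy(fr)$estimate[-1]))
    expect_equal(p_interaction(f), p_interaction(fr))
  })
})

test_that("an empty two-locus class aliases the interaction term", {
  # no ab individuals: a1 a2 is collinear with a1 + a2
  g1 <- c(0, 0, 0, 0, 1, 1, 1)
  g2 <- c(0, 0, 1, 1, 0, 0, 0)
  y <- rnorm(7)
  f <- fit_two_locus_model(y, g1, g2)
  expect_true(any(f$aliased))
  expect_true(is.na(p_interaction(f)))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_two_locus_model(rnorm(4), c(0, 1, 0, 1), c(0, 0, 1, 1)), "5")
  expect_error(
    fit_two_locus_model(rnorm(6), rep(0, 6), c(0, 1, 0, 1, 0, 1)),
    "polymorphic"
  )
})

test_that("the scan's closed-form path equals the model-fitting path", {
  # balanced columns so every two-locus class is occupied (no aliasing)
  g <- withr::with_seed(221, {
    codes <- vapply(1:6, function(i) sample(rep(0:1, c(18, 17))), integer(35))
    geno_matrix(
      codes, paste0("i", 1:35),
      tibble::tibble(
        marker_id = paste0("m", 1:6), chromosome = "1",
        position = as.integer(seq(1e5, 3e7, length.out = 6))
      )
    )
  })
  y <- withr::with_seed(222, rnorm(35))
  hits <- epistasis_scan(y, g, p_threshold = 1)
  expect_false(any(hits$aliased))
  expect_equal(nrow(hits), choose(6, 2)) # threshold 1: all pairs reported
  for (k in seq_len(nrow(hits))) {
    f <- fit_two_locus_model(
      y, marker_codes(g, hits$marker_i[k]), marker_codes(g, hits$marker_j[k])
    )
    expect_equal(hits$p12[k], p_interaction(f), tolerance = 1e-10)
    expect_equal(hits$beta12[k], tidy(f)$estimate[4], tolerance = 1e-10)
  }
  expect_equal(hits$p12, sort(hits$p12))
})

test_that("a strong truly epistatic pair ranks first in the scan", {
  withr::with_seed(231, {
    g <- random_panel(200, 10, seed = 232)
    arch <- architecture_spec(
      causal = c("m3", "m7"), effects = c(0, 0),
      noise_sd = 1, mode = "true_epistasis", epistasis_effect = 1.5
    )
    y <- simulate_phenotype(g, arch, seed = 233)$value
    hits <- epistasis_scan(y, g, p_threshold = 0.05 / choose(10, 2))
    expect_gt(nrow(hits), 0)
    expect_setequal(c(hits$marker_i[1], hits$marker_j[1]), c("m3", "m7"))
  })
})

test_that("type-I error of the interaction test is at most nominal", {
  withr::with_seed(241, {
    hits <- 0
    n_fits <- 400
    for (rep in seq_len(n_fits)) {
      g1 <- random_column(50)
      g2 <- random_column(50)
      f <- fit_two_locus_model(rnorm(50), g1, g2)
      p <- p_interaction(f)
      if (!is.na(p) && p < 0.05) hits <- hits + 1
    }
    # binomial 3-sigma allowance around 0.05 * 400 = 20
    expect_lte(hits, 20 + 3 * sqrt(400 * 0.05 * 0.95))
  })
})

test_that("Bonferroni thresholds reproduce the published significance levels", {
  expect_equal(signif(bonferroni_threshold(0.05, n_marker_pairs(1.6e6)), 2), 3.9e-14)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 1.5625e8), 2), 3.2e-10)
})

test_that("genomic kinship matches a hand-computed standardised cross-product", {
  codes <- matrix(c(
    0L, 1L, 0L, 1L,
    1L, 0L, 0L, 1L,
    0L, 0L, 1L, 1L
  ), nrow = 3, byrow = TRUE)
  g <- geno_matrix(
    codes, c("i1", "i2", "i3"),
    tibble::tibble(
      marker_id = paste0("m", 1:4), chromosome = "1",
      position = c(10L, 20L, 30L, 40L)
    )
  )
  # marker 4 is monomorphic and carries no information
  Z <- scale(codes[, 1:3])
  expect_equal(unname(genomic_kinship(g)), unname(tcrossprod(Z) / 3))
})

test_that("kinship is symmetric PSD and duplicates share their diagonal", {
  g <- random_panel(20, 15, seed = 251)
  g2 <- geno_matrix(
    rbind(g$codes, g$codes[1, ]), c(g$individual_ids, "dup"), g$map
  )
  K <- genomic_kinship(g2)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_equal(K["dup", g$individual_ids[1]], K["dup", "dup"])
})

test_that("an identity kinship or lambda = 0 reproduces the OLS fit", {
  withr::with_seed(261, {
    g1 <- random_column(40)
    g2 <- random_column(40)
    y <- rnorm(40)
    ols <- fit_two_locus_model(y, g1, g2)
    mm_id <- refit_with_kinship(y, g1, g2, diag(40))
    expect_equal(tidy(mm_id)$estimate, tidy(ols)$estimate, tolerance = 1e-6)
    K <- genomic_kinship(random_panel(40, 30, seed = 262))
    mm0 <- refit_with_kinship(y, g1, g2, K, lambda = 0)
    expect_equal(tidy(mm0)$estimate, tidy(ols)$estimate, tolerance = 1e-10)
    expect_equal(tidy(mm0)$std.error, tidy(ols)$std.error, tolerance = 1e-10)
    expect_equal(tidy(mm0)$p.value, tidy(ols)$p.value, tolerance = 1e-10)
    expect_true(mm0$corrected)
  })
})

test_that("kinship refit deflates interaction p-values under polygenic structure", {
  # clone groups with a strongly heritable purely additive polygenic trait:
  # residuals are correlated within groups, so the uncorrected interaction
  # test is anti-conservative; the mixed model absorbs the polygenic
  # covariance and is not
  p_unc <- c()
  p_cor <- c()
  for (rep in 1:40) {
    sim <- withr::with_seed(300 + rep, {
      n_fam <- 12
      clone <- 8
      m <- 40
      n <- n_fam * clone
      founders <- matrix(rbinom(n_fam * m, 1, 0.5), n_fam)
      codes <- founders[rep(seq_len(n_fam), each = clone), ]
      flip <- matrix(runif(n * m) < 0.05, n, m)
      codes[flip] <- 1L - codes[flip]
      codes <- codes[, apply(codes, 2, function(cl) length(unique(cl)) == 2)]
      gv <- as.numeric(scale(codes %*% rnorm(ncol(codes))))
      list(codes = codes, y = gv + rnorm(n, 0, 0.5))
    })
    g <- geno_matrix(
      sim$codes, paste0("i", seq_len(nrow(sim$codes))),
      tibble::tibble(
        marker_id = paste0("m", seq_len(ncol(sim$codes))),
        chromosome = "1",
        position = as.integer(seq(1e5, 3e7, length.out = ncol(sim$codes)))
      )
    )
    K <- genomic_kinship(g)
    i <- 1L
    j <- n_markers(g)
    p_unc <- c(p_unc, p_interaction(
      fit_two_locus_model(sim$y, g$codes[, i], g$codes[, j])
    ))
    p_cor <- c(p_cor, p_interaction(
      refit_with_kinship(sim$y, g$codes[, i], g$codes[, j], K)
    ))
  }
  expect_lt(median(p_unc, na.rm = TRUE), median(p_cor, na.rm = TRUE))
})

test_that("a non-PSD or asymmetric matrix is rejected", {
  y <- rnorm(10)
  g1 <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1)
  g2 <- c(0, 0, 1, 1, 0, 0, 1, 1, 0, 1)
  K_bad <- diag(10)
  K_bad[1, 2] <- 5 # asymmetric
  expect_error(refit_with_kinship(y, g1, g2, K_bad), "symmetric")
  K_npd <- diag(10)
  K_npd[1, 1] <- -2
  expect_error(refit_with_kinship(y, g1, g2, K_npd), "positive semi-definite")
})
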
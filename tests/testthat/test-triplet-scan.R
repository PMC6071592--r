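test_that("the 1 Mb rule classifies triplets by cis predictor count", {
  map <- tibble::tibble(
    marker_id = c("p1", "p2", "p3", "p4", "q"),
    chromosome = c("2", "2", "3", "1", "2"),
    position = c(10100000L, 11200000L, 5000000L, 1L, 10500000L)
  )
  expect_equal(classify_triplet(map, 1, 2, 5), "cis_cis")
  expect_equal(classify_triplet(map, 1, 3, 5), "cis_trans")
  expect_equal(classify_triplet(map, 3, 4, 5), "trans_trans")
  # the window is inclusive: exactly 1 Mb away is still cis
  map2 <- tibble::tibble(
    marker_id = c("p", "q"), chromosome = c("1", "1"),
    position = c(1L, 1000001L)
  )
  expect_equal(classify_triplet(map2, 1, 1, 2), "cis_cis")
  # same distance on different chromosomes is always trans
  map3 <- tibble::tibble(
    marker_id = c("p", "q"), chromosome = c("1", "2"),
    position = c(1L, 2L)
  )
  expect_equal(classify_triplet(map3, 1, 1, 2), "trans_trans")
})

test_that("targets tagged by a single predictor are skipped", {
  p <- random_panel(30, 3, seed = 101)
  tgt <- p[, 2]
  tgt$map$marker_id <- "t1"
  tgt$map$position <- tgt$map$position + 7L
  scan <- scan_triplets(p, tgt, quiet = TRUE)
  expect_equal(scan$n_targets_filtered, 1)
  expect_equal(nrow(scan$triplets), 0)
  expect_equal(sum(scan$evaluated$evaluated_pairs), 0)
})

test_that("the perfectly tagged triplet is found among background markers", {
  sc <- make_perfect_tag_scenario(n_per_class = 5)
  g <- sc$genotypes
  withr::with_seed(111, {
    bg <- vapply(1:6, function(i) random_column(n_individuals(g)), integer(n_individuals(g)))
  })
  preds <- geno_matrix(
    cbind(marker_codes(g, "M1"), marker_codes(g, "M2"), bg),
    g$individual_ids,
    tibble::tibble(
      marker_id = c("M1", "M2", paste0("bg", 1:6)),
      chromosome = c("1", "2", rep("4", 6)),
      position = c(5000000L, 5000000L, as.integer(seq(1e6, 2e7, length.out = 6)))
    )
  )
  targets <- g[, "Q"]
  scan <- scan_triplets(preds, targets, quiet = TRUE)
  strong <- scan$triplets[scan$triplets$strong, ]
  expect_equal(nrow(strong), 1)
  expect_setequal(c(strong$predictor_i, strong$predictor_j), c("M1", "M2"))
  expect_equal(strong$second_order_r2, 1)
  expect_equal(strong$best_pseudomarker, 4L)
  expect_equal(strong$class, "cis_trans")
  # all unordered pairs of the 8 predictors were evaluated for the target
  expect_equal(sum(scan$evaluated$evaluated_pairs), choose(8, 2))
})

test_that("evaluated-pair denominators count unordered pairs per target", {
  p <- random_panel(40, 3, seed = 121)
  tgt <- random_panel(40, 1, seed = 122)
  tgt$map$marker_id <- "t"
  tgt$map$position <- 999L
  scan <- scan_triplets(p, tgt, keep_r2 = 0, quiet = TRUE)
  expect_equal(sum(scan$evaluated$evaluated_pairs), 3) # C(3,2)
})

test_that("scan records agree with the brute-force oracle (seeded audit)", {
  p <- random_panel(25, 8, seed = 131)
  tgt <- random_panel(25, 4, seed = 132, chromosome = "2")
  scan <- scan_triplets(p, tgt, keep_r2 = 0, quiet = TRUE)
  recs <- scan$triplets
  expect_gt(nrow(recs), 0)
  audit <- withr::with_seed(133, {
    recs[sample(nrow(recs), min(25, nrow(recs))), ]
  })
  for (k in seq_len(nrow(audit))) {
    g1 <- marker_codes(p, audit$predictor_i[k])
    g2 <- marker_codes(p, audit$predictor_j[k])
    q <- marker_codes(tgt, audit$target[k])
    expect_equal(audit$second_order_r2[k], oracle_second_order(g1, g2, q)$r2)
  }
})

test_that("possible-pair counts follow the per-target cis combinatorics", {
  # 1 target, 3 predictors all cis
  pm <- tibble::tibble(
    marker_id = paste0("p", 1:3), chromosome = "1",
    position = c(100L, 200L, 300L)
  )
  tm <- tibble::tibble(marker_id = "t", chromosome = "1", position = 150L)
  cnt <- count_possible_pairs(pm, tm)
  expect_equal(cnt$n_possible[cnt$class == "cis_cis"], 3)
  expect_equal(sum(cnt$n_possible), 3)
  # c_q = 1 of P = 3: enumerate the three pairs
  pm2 <- tibble::tibble(
    marker_id = paste0("p", 1:3), chromosome = c("1", "2", "2"),
    position = c(100L, 5000000L, 9000000L)
  )
  cnt2 <- count_possible_pairs(pm2, tm)
  expect_equal(cnt2$n_possible, c(0, 2, 1))
})

test_that("the three classes partition all possible triplets (random maps)", {
  for (s in 1:20) {
    pm <- random_map(sample(5:30, 1), seed = 1000 + s)
    tm <- random_map(sample(2:12, 1), seed = 2000 + s)
    cnt <- count_possible_pairs(pm, tm)
    expect_equal(
      sum(cnt$n_possible),
      choose(nrow(pm), 2) * nrow(tm)
    )
    expect_true(all(cnt$n_possible >= 0))
  }
})

test_that("scan denominators match the map-based class totals", {
  p <- random_panel(30, 6, seed = 141)
  tgt <- random_panel(30, 3, seed = 142, chromosome = "2")
  scan <- scan_triplets(p, tgt, target_filter_r2 = 1.01, quiet = TRUE)
  cnt <- count_possible_pairs(p$map, tgt$map)
  expect_equal(scan$evaluated$evaluated_pairs, cnt$n_possible)
})

test_that("genome extrapolation multiplies pooled proportions by totals", {
  totals <- tibble::tibble(
    class = c("cis_cis", "cis_trans", "trans_trans"),
    n_possible = c(1e6, 5e9, 1e12)
  )
  one <- tibble::tibble(
    window = 1, class = "cis_trans",
    observed_strong = 2, evaluated_pairs = 1e7
  )
  est <- extrapolate_genome(one, totals)
  expect_equal(
    est$genome_estimate[est$class == "cis_trans"],
    2 / 1e7 * 5e9
  )
  expect_true(is.na(est$estimation_error[est$class == "cis_trans"]))
  # class never evaluated: undefined, not zero
  expect_true(is.na(est$proportion[est$class == "cis_cis"]))
})

test_that("the estimation error is the sample SD of per-window estimates", {
  totals <- tibble::tibble(class = "trans_trans", n_possible = 1e10)
  wr <- tibble::tibble(
    window = 1:3, class = "trans_trans",
    observed_strong = c(8, 10, 12), evaluated_pairs = 1e8
  )
  est <- extrapolate_genome(wr, totals)
  tt <- est[est$class == "trans_trans", ]
  expect_equal(tt$genome_estimate, 30 / 3e8 * 1e10)
  expect_equal(tt$estimation_error, sd(c(800, 1000, 1200)))
  # all-zero windows: estimate 0 with error 0
  wr0 <- dplyr::mutate(wr, observed_strong = 0)
  est0 <- extrapolate_genome(wr0, totals)
  tt0 <- est0[est0$class == "trans_trans", ]
  expect_equal(tt0$genome_estimate, 0)
  expect_equal(tt0$estimation_error, 0)
})

test_that("extrapolation accepts a list of scan objects as windows", {
  p <- random_panel(25, 5, seed = 151)
  tgt <- random_panel(25, 2, seed = 152, chromosome = "3")
  s1 <- scan_triplets(p, tgt, quiet = TRUE)
  totals <- count_possible_pairs(p$map, tgt$map)
  est <- extrapolate_genome(list(s1, s1), totals)
  expect_s3_class(est, "extrapolation_estimate")
  expect_equal(
    est$evaluated_pairs,
    2 * s1$evaluated$evaluated_pairs[match(est$class, s1$evaluated$class)]
  )
})

test_that("Monte Carlo proportions agree with exhaustive scanning on small panels", {
  p <- random_panel(50, 12, seed = 161)
  tgt <- random_panel(50, 5, seed = 162, chromosome = "2")
  scan <- scan_triplets(p, tgt, strong_r2 = 0.2, quiet = TRUE)
  exact <- scan$evaluated$observed_strong / scan$evaluated$evaluated_pairs
  mc <- estimate_strong_proportion(
    p, tgt,
    n_samples = 60000, seed = 163, strong_r2 = 0.2, quiet = TRUE
  )
  for (k in which(scan$evaluated$evaluated_pairs > 0)) {
    expect_lt(abs(mc$proportion[k] - exact[k]), 0.05)
  }
})

test_that("tidy and glance summarise a scan", {
  p <- random_panel(25, 5, seed = 171)
  tgt <- random_panel(25, 2, seed = 172, chromosome = "2")
  scan <- scan_triplets(p, tgt, quiet = TRUE)
  expect_identical(tidy(scan), scan$triplets)
  gl <- glance(scan)
  expect_equal(gl$triplets_evaluated, sum(scan$evaluated$evaluated_pairs))
  expect_equal(gl$n_individuals, 25)
})
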
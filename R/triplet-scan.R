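#' Classify a predictor pair relative to a target by genomic distance
#'
#' A predictor is *cis* to a target when it lies on the same chromosome
#' within `window_bp` (inclusive); predictors on other chromosomes are
#' always *trans*. A (predictor pair, target) triplet is `cis_cis` when
#' both predictors are cis, `cis_trans` when exactly one is, and
#' `trans_trans` when neither is.
#'
#' @param map A marker-map tibble (`marker_id`, `chromosome`, `position`).
#' @param i,j Predictor marker indices into `map` (vectorised).
#' @param q Target marker indices into `map` (vectorised).
#' @param window_bp The cis window, default 1 Mb.
#' @return Character vector in `{"cis_cis", "cis_trans", "trans_trans"}`.
#' @export
#' @examples
#' map <- tibble::tibble(
#'   marker_id = c("a", "b", "t"), chromosome = c("2", "2", "2"),
#'   position = c(10100000L, 11200000L, 10500000L)
#' )
#' classify_triplet(map, 1, 2, 3) # cis_cis
classify_triplet <- function(map, i, j, q, window_bp = 1e6) {
  cis_i <- .is_cis(map$chromosome[i], map$position[i],
    map$chromosome[q], map$position[q], window_bp)
  cis_j <- .is_cis(map$chromosome[j], map$position[j],
    map$chromosome[q], map$position[q], window_bp)
  .class_from_cis(cis_i + cis_j)
}

.is_cis <- function(chr_p, pos_p, chr_t, pos_t, window_bp) {
  chr_p == chr_t & abs(as.numeric(pos_p) - as.numeric(pos_t)) <= window_bp
}

.class_from_cis <- function(n_cis) {
  c("trans_trans", "cis_trans", "cis_cis")[n_cis + 1L]
}

.triplet_classes <- c("cis_cis", "cis_trans", "trans_trans")

#' Exhaustive scan for high-order LD triplets
#'
#' Evaluates the second-order LD ([second_order_ld()]) of every unordered
#' predictor pair to every eligible target. Targets already tagged well by
#' a single predictor (best individual r-squared `>= target_filter_r2`) are
#' skipped, mirroring the focus on variation an individual marker cannot
#' capture. Triplets with second-order r-squared strictly above `keep_r2`
#' are retained; those strictly above `strong_r2` are flagged strong.
#' Per-class evaluated-triplet denominators are recorded for downstream
#' extrapolation whether or not any record is kept.
#'
#' @param predictors,targets [geno_matrix()] panels over the same
#'   individuals (aligned by id; the intersection is used).
#' @param keep_r2 Retention threshold on the second-order r-squared
#'   (default 0.3, strict).
#' @param strong_r2 Strong-triplet threshold (default 0.6, strict).
#' @param target_filter_r2 Targets whose best individual predictor
#'   r-squared is at or above this are skipped (default 0.6).
#' @param window_bp Cis window for classification (default 1 Mb).
#' @param quiet Suppress progress messages.
#' @return An object of class `triplet_scan`: list with `triplets` (tibble
#'   of retained records), `evaluated` (per-class evaluated / kept / strong
#'   counts), `n_targets`, `n_targets_filtered`, `n_individuals` and
#'   `thresholds`.
#' @export
scan_triplets <- function(predictors, targets, keep_r2 = 0.3, strong_r2 = 0.6,
                          target_filter_r2 = 0.6, window_bp = 1e6,
                          quiet = FALSE) {
  if (n_markers(predictors) < 2L) stop("need at least two predictors", call. = FALSE)
  common <- intersect(predictors$individual_ids, targets$individual_ids)
  if (length(common) == 0L) stop("panels share no individuals", call. = FALSE)
  P <- predictors[match(common, predictors$individual_ids), ]
  Tg <- targets[match(common, targets$individual_ids), ]

  np <- n_markers(P)
  pairs_i <- rep(seq_len(np - 1L), times = (np - 1L):1L)
  pairs_j <- sequence((np - 1L):1L, from = 2L:np)

  pmap <- P$map
  tmap <- Tg$map
  has_na <- anyNA(P$codes) || anyNA(Tg$codes)

  evaluated <- stats::setNames(numeric(3), .triplet_classes)
  kept_by_class <- stats::setNames(numeric(3), .triplet_classes)
  strong_by_class <- stats::setNames(numeric(3), .triplet_classes)
  records <- vector("list", n_markers(Tg))
  n_filtered <- 0L

  for (t in seq_len(n_markers(Tg))) {
    q <- Tg$codes[, t]
    best_ind <- max_individual_r2(q, P)$r2
    if (!is.na(best_ind) && best_ind >= target_filter_r2) {
      n_filtered <- n_filtered + 1L
      next
    }
    cis <- .is_cis(pmap$chromosome, pmap$position,
      tmap$chromosome[t], tmap$position[t], window_bp)
    cls <- .class_from_cis(as.integer(cis[pairs_i]) + as.integer(cis[pairs_j]))
    evaluated <- evaluated + table(factor(cls, levels = .triplet_classes))

    if (!has_na) {
      res <- .triplet_r2_batch(
        P$codes[, pairs_i, drop = FALSE],
        P$codes[, pairs_j, drop = FALSE],
        matrix(q, nrow = length(q), ncol = length(pairs_i))
      )
      per <- res$per_r2
      max_r2 <- res$max_r2
      best <- res$best
      n_used <- rep(length(q), length(pairs_i))
    } else {
      fits <- purrr::map(seq_along(pairs_i), function(k) {
        second_order_ld(P$codes[, pairs_i[k]], P$codes[, pairs_j[k]], q)
      })
      per <- do.call(rbind, purrr::map(fits, "per_pseudomarker_r2"))
      max_r2 <- purrr::map_dbl(fits, "r2")
      best <- purrr::map_int(fits, ~ as.integer(.x$best_pseudomarker))
      n_used <- purrr::map_int(fits, "n_used")
    }

    keep <- !is.na(max_r2) & max_r2 > keep_r2
    strong <- keep & max_r2 > strong_r2
    kept_by_class <- kept_by_class +
      table(factor(cls[keep], levels = .triplet_classes))
    strong_by_class <- strong_by_class +
      table(factor(cls[strong], levels = .triplet_classes))
    if (any(keep)) {
      ki <- pairs_i[keep]
      kj <- pairs_j[keep]
      records[[t]] <- tibble::tibble(
        predictor_i = pmap$marker_id[ki],
        predictor_j = pmap$marker_id[kj],
        target = tmap$marker_id[t],
        chrom_i = pmap$chromosome[ki], pos_i = pmap$position[ki],
        chrom_j = pmap$chromosome[kj], pos_j = pmap$position[kj],
        chrom_q = tmap$chromosome[t], pos_q = tmap$position[t],
        r2_p1 = per[keep, 1], r2_p2 = per[keep, 2],
        r2_p3 = per[keep, 3], r2_p4 = per[keep, 4],
        second_order_r2 = max_r2[keep],
        best_pseudomarker = best[keep],
        max_individual_r2 = if (is.null(best_ind)) NA_real_ else best_ind,
        class = cls[keep],
        strong = strong[keep],
        n_used = n_used[keep]
      )
    }
  }
  if (!quiet) {
    message(
      n_filtered, " of ", n_markers(Tg),
      " target(s) skipped (individual r2 >= ", target_filter_r2, ")"
    )
  }
  structure(
    list(
      triplets = dplyr::bind_rows(records),
      evaluated = tibble::tibble(
        class = .triplet_classes,
        evaluated_pairs = as.numeric(evaluated),
        kept = as.numeric(kept_by_class),
        observed_strong = as.numeric(strong_by_class)
      ),
      n_targets = n_markers(Tg),
      n_targets_filtered = n_filtered,
      n_individuals = length(common),
      thresholds = list(
        keep_r2 = keep_r2, strong_r2 = strong_r2,
        target_filter_r2 = target_filter_r2, window_bp = window_bp
      )
    ),
    class = "triplet_scan"
  )
}

#' @export
print.triplet_scan <- function(x, ...) {
  cat(
    "<triplet_scan> ", sum(x$evaluated$evaluated_pairs), " triplets evaluated over ",
    x$n_targets - x$n_targets_filtered, " target(s), ", x$n_individuals,
    " individuals\n", sep = ""
  )
  print(x$evaluated)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the retained records of a triplet scan
#' @param x A `triplet_scan` object.
#' @param ... Unused.
#' @return The tibble of retained triplet records.
#' @export
tidy.triplet_scan <- function(x, ...) x$triplets

#' One-row summary of a triplet scan
#' @param x A `triplet_scan` object.
#' @param ... Unused.
#' @return Tibble with totals and thresholds.
#' @export
glance.triplet_scan <- function(x, ...) {
  tibble::tibble(
    n_individuals = x$n_individuals,
    n_targets = x$n_targets,
    n_targets_filtered = x$n_targets_filtered,
    triplets_evaluated = sum(x$evaluated$evaluated_pairs),
    triplets_kept = sum(x$evaluated$kept),
    triplets_strong = sum(x$evaluated$observed_strong),
    keep_r2 = x$thresholds$keep_r2,
    strong_r2 = x$thresholds$strong_r2
  )
}

#' Genome-wide totals of possible triplets per distance class
#'
#' For every target, counts the predictors in cis (same chromosome, within
#' `window_bp`); with `P` predictors overall and `c_q` in cis the target
#' contributes `choose(c_q, 2)` cis-cis, `c_q (P - c_q)` cis-trans and
#' `choose(P - c_q, 2)` trans-trans (predictor pair, target) triplets.
#' Totals are summed over targets; the three classes always partition the
#' `choose(P, 2) * n_targets` possible triplets.
#'
#' @param predictor_map,target_map Marker-map tibbles.
#' @param window_bp Cis window, default 1 Mb.
#' @return Tibble with `class` and `n_possible` (numeric; counts can exceed
#'   integer range genome-wide).
#' @export
count_possible_pairs <- function(predictor_map, target_map, window_bp = 1e6) {
  P <- nrow(predictor_map)
  c_q <- numeric(nrow(target_map))
  for (chr in unique(target_map$chromosome)) {
    tsel <- target_map$chromosome == chr
    ppos <- sort(as.numeric(predictor_map$position[predictor_map$chromosome == chr]))
    if (length(ppos) == 0L) next
    tpos <- as.numeric(target_map$position[tsel])
    c_q[tsel] <- findInterval(tpos + window_bp, ppos) -
      findInterval(tpos - window_bp, ppos, left.open = TRUE)
  }
  tibble::tibble(
    class = .triplet_classes,
    n_possible = c(
      sum(c_q * (c_q - 1) / 2),
      sum(c_q * (P - c_q)),
      sum((P - c_q) * (P - c_q - 1) / 2)
    )
  )
}

#' Extrapolate windowed strong-triplet counts to the genome
#'
#' Pools the per-window counts of strong triplets per class into a single
#' proportion (sum of observed over sum of evaluated), multiplies by the
#' genome-wide totals of possible triplets per class, and reports the
#' sample standard deviation of the per-window genome estimates as the
#' estimation error.
#'
#' @param window_results Tibble with columns `window`, `class`,
#'   `observed_strong`, `evaluated_pairs` (one row per window x class), or
#'   a list of `triplet_scan` objects (windows) whose `evaluated` tables
#'   are used.
#' @param genome_totals Output of [count_possible_pairs()] on the
#'   genome-wide maps (or a tibble with `class`, `n_possible`).
#' @return A tibble of class `extrapolation_estimate` with per-class
#'   `observed_strong`, `evaluated_pairs`, `proportion`, `n_possible`,
#'   `genome_estimate` and `estimation_error`. Classes with zero evaluated
#'   triplets get `NA` (undefined) proportion and estimate.
#' @export
extrapolate_genome <- function(window_results, genome_totals) {
  if (is.list(window_results) && !is.data.frame(window_results)) {
    window_results <- purrr::imap_dfr(window_results, function(w, idx) {
      ev <- if (inherits(w, "triplet_scan")) w$evaluated else w
      dplyr::mutate(ev[c("class", "observed_strong", "evaluated_pairs")],
        window = idx, .before = 1
      )
    })
  }
  need <- c("window", "class", "observed_strong", "evaluated_pairs")
  if (!all(need %in% names(window_results))) {
    stop("window results need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  totals <- stats::setNames(genome_totals$n_possible, genome_totals$class)

  per_window <- window_results |>
    dplyr::mutate(
      est = ifelse(.data$evaluated_pairs > 0,
        .data$observed_strong / .data$evaluated_pairs * totals[.data$class],
        NA_real_
      )
    )
  out <- per_window |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      observed_strong = sum(.data$observed_strong),
      evaluated_pairs = sum(.data$evaluated_pairs),
      estimation_error = if (sum(!is.na(.data$est)) >= 2) {
        stats::sd(.data$est[!is.na(.data$est)])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::right_join(
      tibble::tibble(class = .triplet_classes),
      by = "class"
    ) |>
    dplyr::mutate(
      observed_strong = dplyr::coalesce(.data$observed_strong, 0),
      evaluated_pairs = dplyr::coalesce(.data$evaluated_pairs, 0)
    ) |>
    dplyr::mutate(
      proportion = ifelse(.data$evaluated_pairs > 0,
        .data$observed_strong / .data$evaluated_pairs, NA_real_
      ),
      n_possible = unname(totals[.data$class]),
      genome_estimate = .data$proportion * .data$n_possible
    ) |>
    dplyr::select(
      "class", "observed_strong", "evaluated_pairs", "proportion",
      "n_possible", "genome_estimate", "estimation_error"
    ) |>
    dplyr::arrange(match(.data$class, .triplet_classes))
  class(out) <- c("extrapolation_estimate", class(out))
  out
}

#' Monte Carlo estimate of the strong-triplet proportion per class
#'
#' For genome-scale panels the full (predictor pair, target) cross product
#' is far too large to enumerate, but the per-class proportion of strong
#' triplets is a population quantity that a uniform random sample of
#' triplets estimates without bias. Triplets are drawn uniformly (predictor
#' pair and eligible target independent), classified by the 1 Mb rule, and
#' the second-order LD of each is computed with the vectorised kernel; the
#' per-class proportion is the fraction of sampled triplets of that class
#' that are strong. Target filtering (best individual r-squared) is applied
#' before sampling, as in [scan_triplets()].
#'
#' @inheritParams scan_triplets
#' @param n_samples Number of triplets to draw.
#' @param seed Integer seed (deterministic).
#' @param chunk Triplets per vectorised block.
#' @return Tibble with per-class `sampled`, `strong` and `proportion`.
#' @export
estimate_strong_proportion <- function(predictors, targets, n_samples, seed,
                                       strong_r2 = 0.6, target_filter_r2 = 0.6,
                                       window_bp = 1e6, chunk = 20000L,
                                       quiet = FALSE) {
  common <- intersect(predictors$individual_ids, targets$individual_ids)
  if (length(common) == 0L) stop("panels share no individuals", call. = FALSE)
  P <- predictors[match(common, predictors$individual_ids), ]
  Tg <- targets[match(common, targets$individual_ids), ]
  if (anyNA(P$codes) || anyNA(Tg$codes)) {
    stop("Monte Carlo sampler requires complete genotypes", call. = FALSE)
  }
  np <- n_markers(P)

  best_ind <- max_individual_r2_all(Tg, P)
  eligible <- which(is.na(best_ind) | best_ind < target_filter_r2)
  if (!quiet) {
    message(
      n_markers(Tg) - length(eligible), " of ", n_markers(Tg),
      " target(s) skipped (individual r2 >= ", target_filter_r2, ")"
    )
  }
  if (length(eligible) == 0L) stop("no targets pass the filter", call. = FALSE)

  sampled <- stats::setNames(numeric(3), .triplet_classes)
  strong <- stats::setNames(numeric(3), .triplet_classes)
  withr::with_seed(seed, {
    left <- n_samples
    while (left > 0L) {
      m <- min(chunk, left)
      left <- left - m
      i <- sample.int(np, m, replace = TRUE)
      j <- sample.int(np - 1L, m, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j) # uniform unordered pair, i != j
      t <- eligible[sample.int(length(eligible), m, replace = TRUE)]

      cis_i <- .is_cis(P$map$chromosome[i], P$map$position[i],
        Tg$map$chromosome[t], Tg$map$position[t], window_bp)
      cis_j <- .is_cis(P$map$chromosome[j], P$map$position[j],
        Tg$map$chromosome[t], Tg$map$position[t], window_bp)
      cls <- .class_from_cis(as.integer(cis_i) + as.integer(cis_j))

      res <- .triplet_r2_batch(
        P$codes[, i, drop = FALSE],
        P$codes[, j, drop = FALSE],
        Tg$codes[, t, drop = FALSE]
      )
      hit <- !is.na(res$max_r2) & res$max_r2 > strong_r2
      sampled <- sampled + table(factor(cls, levels = .triplet_classes))
      strong <- strong + table(factor(cls[hit], levels = .triplet_classes))
    }
  })
  tibble::tibble(
    class = .triplet_classes,
    sampled = as.numeric(sampled),
    strong = as.numeric(strong),
    proportion = ifelse(sampled > 0, as.numeric(strong / sampled), NA_real_)
  )
}

#' Best individual predictor r-squared for every target
#'
#' Vectorised (matrix-product) version of [max_individual_r2()] over a
#' whole target panel; requires complete genotypes (falls back to the
#' per-target loop otherwise).
#'
#' @param targets,predictors [geno_matrix()] panels over identical
#'   individuals (same order).
#' @param chunk Targets per block.
#' @return Numeric vector, one value per target (`NA` when undefined).
#' @export
max_individual_r2_all <- function(targets, predictors, chunk = 1000L) {
  X <- predictors$codes
  Q <- targets$codes
  if (anyNA(X) || anyNA(Q)) {
    return(apply(Q, 2L, function(q) max_individual_r2(q, predictors)$r2))
  }
  n <- nrow(X)
  sx <- colSums(X)
  px <- sx / n
  vx <- px * (1 - px)
  out <- numeric(ncol(Q))
  for (start in seq(1L, ncol(Q), by = chunk)) {
    idx <- start:min(start + chunk - 1L, ncol(Q))
    Qb <- Q[, idx, drop = FALSE]
    sq <- colSums(Qb)
    pq <- sq / n
    vq <- pq * (1 - pq)
    # joint frequencies via one matrix product: t(X) %*% Qb
    pxy <- crossprod(X, Qb) / n
    d <- pxy - outer(px, pq)
    r2 <- d * d / outer(vx, vq)
    r2[vx == 0, ] <- NA_real_
    if (any(vq == 0)) r2[, vq == 0] <- NA_real_
    out[idx] <- suppressWarnings(apply(r2, 2L, max, na.rm = TRUE))
  }
  out[!is.finite(out)] <- NA_real_
  out
}
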
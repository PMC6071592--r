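#' Pairwise LD r-squared between two inbred genotype columns
#'
#' In inbred individuals the genotype at a locus identifies the haplotype,
#' so the haplotypic LD measure \eqn{r^2 = D^2 / (p_x(1-p_x)\,p_y(1-p_y))}
#' with \eqn{D = p_{xy} - p_x p_y} can be computed directly from joint
#' genotype frequencies. Frequencies use pairwise-complete individuals.
#'
#' @param x,y Integer vectors of codes in `{0, 1, NA}`, same length.
#' @return List with `r2` (in `[0, 1]`, or `NA` when either locus is
#'   monomorphic among the complete observations — undefined, not zero) and
#'   `n_used` (complete observations).
#' @export
#' @examples
#' ld_r2(c(0, 0, 1, 1), c(0, 0, 1, 1))$r2 # 1
#' ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1))$r2 # 0
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("columns differ in length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  r2 <- .r2_counts(n, sum(x[ok]), sum(y[ok]), sum(x[ok] * y[ok]))
  list(r2 = r2, n_used = n)
}

# r2 from 2x2 joint counts: n obs, sx = #(x==1), sy = #(y==1), sxy = #(both 1)
.r2_counts <- function(n, sx, sy, sxy) {
  if (n == 0L || sx == 0L || sx == n || sy == 0L || sy == n) return(NA_real_)
  p <- sx / n
  q <- sy / n
  d <- sxy / n - p * q
  (d * d) / (p * (1 - p) * q * (1 - q))
}

#' The four pseudomarkers of a two-locus genotype
#'
#' A pair of bi-allelic markers M1 (alleles A/a, codes 0/1) and M2 (alleles
#' B/b, codes 0/1) forms four two-locus genotypes AB, Ab, aB, ab. Each is
#' recoded one-vs-rest into a bi-allelic pseudomarker:
#' P1 = \{AB vs non-AB\}, P2 = \{Ab vs non-Ab\}, P3 = \{aB vs non-aB\},
#' P4 = \{ab vs non-ab\}. Individuals missing at either locus are missing
#' in all four; among complete individuals exactly one of P1..P4 is 1.
#'
#' @param g1,g2 Integer code vectors in `{0, 1, NA}`, same length.
#' @return An integer matrix (individuals x 4, columns `P1`..`P4`) of class
#'   `pseudomarker_set`.
#' @export
make_pseudomarkers <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("columns differ in length", call. = FALSE)
  p1 <- as.integer(g1 == 0L & g2 == 0L) # AB
  p2 <- as.integer(g1 == 0L & g2 == 1L) # Ab
  p3 <- as.integer(g1 == 1L & g2 == 0L) # aB
  p4 <- as.integer(g1 == 1L & g2 == 1L) # ab
  out <- cbind(P1 = p1, P2 = p2, P3 = p3, P4 = p4)
  out[is.na(g1) | is.na(g2), ] <- NA_integer_
  class(out) <- c("pseudomarker_set", class(out))
  out
}

#' Second-order (high-order) LD between a predictor pair and a target
#'
#' The second-order LD of predictors (M1, M2) to target Q is the largest
#' pairwise LD r-squared between Q and the four pseudomarkers of the
#' two-locus M1/M2 genotype (see [make_pseudomarkers()]). It measures how
#' well the *joint* predictor genotype tags the target, and can exceed the
#' best single-predictor r-squared. Computed on triplet-complete
#' individuals; pseudomarkers that are monomorphic among those individuals
#' have no defined r-squared and are excluded from the maximum. Ties are
#' broken by the lowest pseudomarker index.
#'
#' @param g1,g2 Predictor code vectors in `{0, 1, NA}`.
#' @param q Target code vector, same length.
#' @return List with `r2` (the maximum, `NA` if all four are undefined,
#'   e.g. a monomorphic target), `per_pseudomarker_r2` (length-4 numeric,
#'   `NA` where undefined), `best_pseudomarker` (index 1..4 of the maximum,
#'   `NA` if none defined) and `n_used`.
#' @export
second_order_ld <- function(g1, g2, q) {
  if (length(g1) != length(g2) || length(g1) != length(q)) {
    stop("columns differ in length", call. = FALSE)
  }
  ok <- !is.na(g1) & !is.na(g2) & !is.na(q)
  n <- sum(ok)
  res <- .triplet_r2_batch(
    matrix(g1[ok]), matrix(g2[ok]), matrix(q[ok])
  )
  list(
    r2 = res$max_r2[1],
    per_pseudomarker_r2 = res$per_r2[1, ],
    best_pseudomarker = res$best[1],
    n_used = n
  )
}

# Vectorised kernel: column t of Gi, Gj, Q (0/1, no NA) is one triplet.
# Returns per-triplet pseudomarker r2 (m x 4), max and argmax (lowest-index
# ties). All four r2 come from the 2x2x2 joint counts, obtained with seven
# column sums per block.
.triplet_r2_batch <- function(gi, gj, q) {
  n <- nrow(gi)
  si <- unname(colSums(gi))
  sj <- unname(colSums(gj))
  sq <- unname(colSums(q))
  gij <- gi * gj
  sij <- unname(colSums(gij))
  siq <- unname(colSums(gi * q))
  sjq <- unname(colSums(gj * q))
  sijq <- unname(colSums(gij * q))

  # one-vs-rest counts for each pseudomarker: total carriers m, joint with q
  m_ab <- sij # ab  (g1 = 1, g2 = 1)
  c_ab <- sijq
  m_aB <- si - sij # aB
  c_aB <- siq - sijq
  m_Ab <- sj - sij # Ab
  c_Ab <- sjq - sijq
  m_AB <- n - si - sj + sij # AB
  c_AB <- sq - siq - sjq + sijq

  r2_vec <- function(m, cc) {
    p <- m / n
    pq <- sq / n
    d <- cc / n - p * pq
    den <- p * (1 - p) * pq * (1 - pq)
    out <- d * d / den
    out[m == 0 | m == n | sq == 0 | sq == n] <- NA_real_
    out
  }
  per <- cbind(
    r2_vec(m_AB, c_AB), r2_vec(m_Ab, c_Ab),
    r2_vec(m_aB, c_aB), r2_vec(m_ab, c_ab)
  )
  colnames(per) <- c("P1", "P2", "P3", "P4")
  max_r2 <- suppressWarnings(apply(per, 1L, max, na.rm = TRUE))
  max_r2[!is.finite(max_r2)] <- NA_real_
  best <- rep(NA_integer_, nrow(per))
  def <- !is.na(max_r2)
  if (any(def)) {
    best[def] <- max.col(
      replace(per[def, , drop = FALSE], is.na(per[def, , drop = FALSE]), -Inf),
      ties.method = "first"
    )
  }
  list(per_r2 = per, max_r2 = max_r2, best = best)
}

#' Best single-predictor LD to a target
#'
#' Maximum pairwise [ld_r2()] between a target column and every predictor
#' column; used to filter targets that are already well tagged by an
#' individual marker before scanning for high-order LD.
#'
#' @param q Target code vector.
#' @param predictors A [geno_matrix()] (or 0/1 matrix) of predictor columns
#'   over the same individuals.
#' @return List with `r2` (`NA` if no pair has a defined value), `index`
#'   (argmax predictor column, `NA` if none defined) and `marker_id` when
#'   available.
#' @export
max_individual_r2 <- function(q, predictors) {
  codes <- if (inherits(predictors, "geno_matrix")) predictors$codes else predictors
  if (is.null(dim(codes)) || ncol(codes) == 0L) {
    stop("empty predictor panel", call. = FALSE)
  }
  if (length(q) != nrow(codes)) stop("columns differ in length", call. = FALSE)
  if (!anyNA(q) && !anyNA(codes)) {
    n <- length(q)
    sx <- colSums(codes)
    sq <- sum(q)
    sxq <- as.numeric(crossprod(codes, q))
    r2 <- vapply(
      seq_along(sx),
      function(k) .r2_counts(n, sx[k], sq, sxq[k]),
      numeric(1)
    )
  } else {
    r2 <- apply(codes, 2L, function(col) ld_r2(col, q)$r2)
  }
  if (all(is.na(r2))) {
    idx <- NA_integer_
    best <- NA_real_
  } else {
    idx <- which.max(r2)
    best <- r2[idx]
  }
  list(
    r2 = unname(best), index = unname(idx),
    marker_id = if (inherits(predictors, "geno_matrix") && !is.na(idx)) {
      predictors$map$marker_id[idx]
    } else {
      NA_character_
    }
  )
}
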
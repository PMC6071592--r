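#' Inbred bi-allelic genotype matrix with a marker map
#'
#' The central container of the package: an individuals x markers matrix of
#' genotype codes for inbred (effectively haploid) individuals, together with
#' a marker map. Codes are `0` (reference / major-allele homozygote), `1`
#' (alternative / minor-allele homozygote) or `NA` (no call). Because the
#' individuals are inbred, genotype frequencies equal allele (haplotype)
#' frequencies, and every pairwise LD statistic in the package works directly
#' on these codes.
#'
#' @param codes Integer (or coercible) matrix, individuals in rows, markers in
#'   columns, entries in `{0, 1, NA}`.
#' @param individual_ids Character vector of unique individual identifiers,
#'   one per row of `codes`.
#' @param map Data frame with one row per marker column: `marker_id`
#'   (unique character), `chromosome` (character label), `position` (1-based
#'   bp, strictly positive integer) and optionally `allele_major`,
#'   `allele_minor` (single characters). `(chromosome, position)` must be
#'   unique.
#'
#' @details Markers are sorted by `(chromosome, position)` at construction
#'   and the columns of `codes` are reordered to match, so positional scans
#'   can assume sorted maps. Monomorphic columns are allowed in a freshly
#'   constructed object (synthetic generators may produce them); use
#'   [filter_maf()] to enforce polymorphism / a MAF threshold.
#'
#' @return An object of class `geno_matrix`: a list with elements `codes`
#'   (integer matrix with dimnames), `individual_ids` and `map` (tibble).
#' @seealso [filter_maf()], [compute_maf()], [subsample_individuals()],
#'   [read_vcf()], [read_geno_table()]
#' @export
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0, 0, 1, 1, 0, 1, 0, 1), nrow = 4),
#'   individual_ids = paste0("acc", 1:4),
#'   map = tibble::tibble(
#'     marker_id = c("m1", "m2"), chromosome = c("1", "1"),
#'     position = c(1000L, 2000L)
#'   )
#' )
#' g
geno_matrix <- function(codes, individual_ids, map) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  map <- tibble::as_tibble(map)

  if (!all(c("marker_id", "chromosome", "position") %in% names(map))) {
    stop("`map` needs columns marker_id, chromosome and position", call. = FALSE)
  }
  map$marker_id <- as.character(map$marker_id)
  map$chromosome <- as.character(map$chromosome)
  map$position <- as.integer(map$position)
  individual_ids <- as.character(individual_ids)

  if (nrow(codes) != length(individual_ids)) {
    stop("row count of `codes` must match length of `individual_ids`", call. = FALSE)
  }
  if (ncol(codes) != nrow(map)) {
    stop("column count of `codes` must match the number of map rows", call. = FALSE)
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicated individual ids", call. = FALSE)
  }
  if (anyDuplicated(map$marker_id)) {
    stop("duplicated marker ids in `map`", call. = FALSE)
  }
  if (any(is.na(map$position)) || any(map$position < 1L)) {
    stop("marker positions must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(map[c("chromosome", "position")])) {
    stop("duplicated (chromosome, position) in `map`", call. = FALSE)
  }
  bad <- !(codes %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    stop("genotype codes must be 0, 1 or NA", call. = FALSE)
  }

  ord <- order(map$chromosome, map$position)
  map <- map[ord, , drop = FALSE]
  codes <- codes[, ord, drop = FALSE]
  dimnames(codes) <- list(individual_ids, map$marker_id)

  structure(
    list(codes = codes, individual_ids = individual_ids, map = map),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(
    "<geno_matrix> ", n_individuals(x), " individuals x ", n_markers(x),
    " markers on ", length(unique(x$map$chromosome)), " chromosome(s)\n",
    sep = ""
  )
  n_na <- sum(is.na(x$codes))
  if (n_na > 0) cat("  missing calls: ", n_na, "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Number of individuals / markers in a genotype matrix
#' @param g A [geno_matrix()].
#' @return Integer count.
#' @export
n_individuals <- function(g) nrow(g$codes)

#' @rdname n_individuals
#' @export
n_markers <- function(g) ncol(g$codes)

#' Subset a genotype matrix
#'
#' `i` selects individuals (rows), `j` markers (columns, by index or
#' marker id). The map is subset accordingly.
#'
#' @param x A [geno_matrix()].
#' @param i,j Row / column indices (numeric, logical or character).
#' @param ... Unused.
#' @return A [geno_matrix()].
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$codes))
  if (missing(j)) j <- seq_len(ncol(x$codes))
  if (is.character(j)) j <- match(j, x$map$marker_id)
  if (anyNA(j)) stop("unknown marker id", call. = FALSE)
  codes <- x$codes[i, j, drop = FALSE]
  geno_matrix(codes, rownames(codes), x$map[j, , drop = FALSE])
}

#' Extract one marker column
#' @param g A [geno_matrix()].
#' @param marker Marker id or column index.
#' @return Integer vector of codes named by individual id.
#' @export
marker_codes <- function(g, marker) {
  if (is.character(marker)) marker <- match(marker, g$map$marker_id)
  if (anyNA(marker) || length(marker) != 1L) stop("unknown marker", call. = FALSE)
  g$codes[, marker]
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$codes), .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(individual_id = x$individual_ids), out)
}

#' Minor-allele frequency of a genotype column
#'
#' For inbred individuals the minor-homozygote genotype frequency equals the
#' minor-allele frequency, so the MAF of a column of codes is
#' `min(p, 1 - p)` with `p` the frequency of code 1 among non-missing
#' entries.
#'
#' @param g Integer vector of codes in `{0, 1, NA}` (one marker column).
#' @return A fraction in `[0, 0.5]`.
#' @export
#' @examples
#' compute_maf(c(0, 0, 0, 1)) # 0.25
compute_maf <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("all entries missing; MAF undefined", call. = FALSE)
  p <- mean(g == 1L)
  min(p, 1 - p)
}

#' Per-marker minor-allele frequencies
#' @param g A [geno_matrix()].
#' @return Tibble with `marker_id` and `maf`.
#' @export
marker_maf <- function(g) {
  tibble::tibble(
    marker_id = g$map$marker_id,
    maf = apply(g$codes, 2L, compute_maf)
  )
}

#' Drop markers at or below a minor-allele-frequency threshold
#'
#' Retains markers with MAF strictly greater than `maf_min` (a threshold of
#' 0.05 reads "MAF > 0.05"); `maf_min = 0` keeps exactly the polymorphic
#' markers.
#'
#' @param g A [geno_matrix()].
#' @param maf_min Threshold in `[0, 0.5)`.
#' @param quiet Suppress the dropped-marker message.
#' @return A filtered [geno_matrix()].
#' @export
filter_maf <- function(g, maf_min = 0.05, quiet = FALSE) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  maf <- apply(g$codes, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(0)
    p <- mean(col == 1L)
    min(p, 1 - p)
  })
  keep <- maf > maf_min
  if (!any(keep)) {
    stop("no markers left after MAF filtering (empty panel)", call. = FALSE)
  }
  if (!quiet && any(!keep)) {
    message(sum(!keep), " marker(s) dropped at MAF threshold ", maf_min)
  }
  g[, which(keep)]
}

#' Subsample individuals without replacement
#'
#' Draws a uniform random subset of individuals, then re-checks every marker
#' for polymorphism (and optionally MAF) in the subsample, dropping markers
#' that became monomorphic. Deterministic given `seed`.
#'
#' @param g A [geno_matrix()].
#' @param n_sub Number of individuals to keep (`<= n_individuals(g)`).
#' @param seed Integer seed.
#' @param maf_min MAF threshold re-applied to the subsample (default 0:
#'   drop monomorphic markers only).
#' @param quiet Suppress messages.
#' @return A [geno_matrix()] with `n_sub` individuals.
#' @export
subsample_individuals <- function(g, n_sub, seed, maf_min = 0, quiet = FALSE) {
  n <- n_individuals(g)
  if (n_sub > n) stop("`n_sub` exceeds the number of individuals", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n, n_sub))
  sub <- g[sort(idx), ]
  filter_maf(sub, maf_min = maf_min, quiet = quiet)
}

#' Construct a phenotype table
#'
#' @param individual_ids Character ids (unique).
#' @param value Numeric trait values (arbitrary units), same length.
#' @return Tibble with columns `individual_id`, `value`.
#' @export
phenotype <- function(individual_ids, value) {
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids", call. = FALSE)
  if (length(individual_ids) != length(value)) {
    stop("ids and values differ in length", call. = FALSE)
  }
  tibble::tibble(individual_id = individual_ids, value = as.numeric(value))
}

#' Align a phenotype table with a genotype matrix
#'
#' Explicit inner join on individual id; errors if no individuals overlap.
#'
#' @param g A [geno_matrix()].
#' @param pheno A phenotype tibble ([phenotype()]).
#' @return List with `g` (subset, in phenotype order) and `y` (numeric
#'   vector aligned to its rows).
#' @export
align_phenotype <- function(g, pheno) {
  common <- intersect(pheno$individual_id, g$individual_ids)
  if (length(common) == 0L) stop("no shared individual ids", call. = FALSE)
  pheno <- pheno[match(common, pheno$individual_id), ]
  gs <- g[match(common, g$individual_ids), ]
  list(g = gs, y = pheno$value)
}
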
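#' Read an inbred genotype matrix from a VCF file
#'
#' Reads bi-allelic SNP records from a VCF (v4.x, GT field) into a
#' [geno_matrix()]. Samples are assumed inbred: homozygous reference calls
#' become code 0, homozygous alternative calls code 1, and heterozygous
#' calls are handled according to `het_policy` (residual heterozygosity in
#' inbred accessions is normally treated as a no-call). Columns are
#' re-polarised so that code 0 is the major allele whenever the alternative
#' allele is the more common one (ties keep the reference as 0), and the
#' `allele_major` / `allele_minor` map columns record the bases.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param maf_min Markers with minor-allele frequency not strictly greater
#'   than this are dropped (default 0: drop monomorphic only).
#' @param het_policy One of `"missing"` (heterozygous call becomes `NA`),
#'   `"drop_marker"` (whole marker removed), `"error"`.
#' @param quiet Suppress skip-count messages.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, maf_min = 0,
                     het_policy = c("missing", "drop_marker", "error"),
                     quiet = FALSE) {
  het_policy <- match.arg(het_policy)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!is_snp)
  if (!quiet && n_skipped > 0) {
    message(n_skipped, " non-SNP / multi-allelic record(s) skipped")
  }
  if (!any(is_snp)) stop("no bi-allelic SNP records in VCF (empty panel)", call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  # markers x individuals character -> integer codes
  alleles <- function(x) strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
  code_one <- function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- strsplit(chartr("|", "/", x), "/", fixed = TRUE)[[1]]
    a <- a[a != "."]
    if (length(a) == 0L) return(NA_integer_)
    u <- unique(a)
    if (length(u) > 1L) return(-1L) # heterozygous sentinel
    if (u == "0") 0L else if (u == "1") 1L else NA_integer_
  }
  codes <- matrix(
    vapply(gt, code_one, integer(1)),
    nrow = nrow(gt), dimnames = dimnames(gt)
  )

  het_rows <- apply(codes, 1L, function(r) any(r == -1L, na.rm = TRUE))
  if (any(het_rows)) {
    if (het_policy == "error") {
      stop("heterozygous calls present (samples assumed inbred)", call. = FALSE)
    }
    if (het_policy == "drop_marker") {
      codes <- codes[!het_rows, , drop = FALSE]
      fix <- fix[!het_rows, , drop = FALSE]
      if (!quiet) message(sum(het_rows), " marker(s) dropped for heterozygous calls")
    } else {
      codes[codes == -1L] <- NA_integer_
    }
  }
  if (nrow(codes) == 0L) stop("all markers dropped (empty panel)", call. = FALSE)

  ids <- unname(fix[, "ID"])
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[is.na(ids) | ids == ".", "CHROM"], "_", fix[is.na(ids) | ids == ".", "POS"]
  )

  # polarise: code 0 = major allele (strictly; ties keep REF as 0)
  a_major <- unname(fix[, "REF"])
  a_minor <- unname(fix[, "ALT"])
  p_alt <- rowMeans(codes == 1L, na.rm = TRUE)
  flip <- !is.na(p_alt) & p_alt > 0.5
  if (any(flip)) {
    codes[flip, ] <- 1L - codes[flip, , drop = FALSE]
    tmp <- a_major[flip]
    a_major[flip] <- a_minor[flip]
    a_minor[flip] <- tmp
  }

  map <- tibble::tibble(
    marker_id = as.character(ids),
    chromosome = as.character(unname(fix[, "CHROM"])),
    position = as.integer(unname(fix[, "POS"])),
    allele_major = a_major,
    allele_minor = a_minor
  )
  g <- geno_matrix(t(codes), colnames(codes), map)
  filter_maf(g, maf_min = maf_min, quiet = quiet)
}

#' Read / write delimited genotype tables
#'
#' Plain-text genotype tables in two orientations. With
#' `orientation = "markers_in_rows"` the file has columns `marker_id`,
#' `chromosome`, `position` followed by one column of `{0, 1, NA}` codes per
#' individual. With `orientation = "markers_in_columns"` the file has one
#' row per individual, a leading `individual_id` column and one marker
#' column per locus whose header packs the map as
#' `marker_id|chromosome|position`. Writing then reading either orientation
#' round-trips codes, ids and map exactly.
#'
#' @param path File path (tab- or comma-delimited; inferred from extension,
#'   `.csv` means comma).
#' @param orientation Table layout, see Details.
#' @return `read_geno_table()` returns a [geno_matrix()];
#'   `write_geno_table()` returns `path` invisibly.
#' @export
read_geno_table <- function(path,
                            orientation = c("markers_in_rows", "markers_in_columns")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    na = c("NA", "")
  )
  if (orientation == "markers_in_rows") {
    need <- c("marker_id", "chromosome", "position")
    if (!all(need %in% names(tab))) {
      stop("expected columns marker_id, chromosome, position", call. = FALSE)
    }
    ids <- setdiff(names(tab), need)
    codes <- t(as.matrix(tab[ids]))
    .check_codes(codes)
    geno_matrix(codes, ids, tab[need])
  } else {
    if (names(tab)[1] != "individual_id") {
      stop("expected first column individual_id", call. = FALSE)
    }
    parts <- strsplit(names(tab)[-1], "|", fixed = TRUE)
    if (any(lengths(parts) != 3L)) {
      stop("marker headers must be marker_id|chromosome|position", call. = FALSE)
    }
    map <- tibble::tibble(
      marker_id = vapply(parts, `[`, "", 1L),
      chromosome = vapply(parts, `[`, "", 2L),
      position = as.integer(vapply(parts, `[`, "", 3L))
    )
    codes <- as.matrix(tab[-1])
    .check_codes(codes)
    geno_matrix(codes, tab$individual_id, map)
  }
}

.check_codes <- function(codes) {
  if (!is.numeric(codes)) stop("non-numeric genotype codes", call. = FALSE)
  if (!all(codes %in% c(0, 1, NA))) {
    stop("genotype codes must be 0, 1 or NA", call. = FALSE)
  }
  invisible(codes)
}

#' @rdname read_geno_table
#' @param g A [geno_matrix()] to write.
#' @export
write_geno_table <- function(g, path,
                             orientation = c("markers_in_rows", "markers_in_columns")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  if (orientation == "markers_in_rows") {
    tab <- dplyr::bind_cols(
      g$map[c("marker_id", "chromosome", "position")],
      tibble::as_tibble(t(g$codes), .name_repair = "minimal")
    )
  } else {
    codes <- tibble::as_tibble(g$codes, .name_repair = "minimal")
    names(codes) <- paste(g$map$marker_id, g$map$chromosome, g$map$position,
      sep = "|"
    )
    tab <- dplyr::bind_cols(tibble::tibble(individual_id = g$individual_ids), codes)
  }
  readr::write_delim(tab, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write a two-column phenotype table
#'
#' Delimited text with columns `individual_id` and `value`.
#'
#' @param path File path (`.csv` for comma, otherwise tab).
#' @return `read_phenotype()` returns a phenotype tibble;
#'   `write_phenotype()` returns `path` invisibly.
#' @export
read_phenotype <- function(path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  if (!all(c("individual_id", "value") %in% names(tab))) {
    stop("expected columns individual_id and value", call. = FALSE)
  }
  phenotype(tab$individual_id, tab$value)
}

#' @rdname read_phenotype
#' @param pheno A phenotype tibble ([phenotype()]).
#' @export
write_phenotype <- function(pheno, path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(pheno, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}
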
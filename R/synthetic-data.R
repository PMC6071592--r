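#' Haplotype table: the distribution a synthetic inbred population is drawn from
#'
#' In a fully inbred population each individual carries a single (doubled)
#' haplotype, so a population is characterised by a set of haplotypes and
#' their frequencies. Sampling individuals i.i.d. from this distribution
#' produces a [geno_matrix()] whose genotype codes equal the haplotype
#' allele codes.
#'
#' @param haplotypes K x L matrix of 0/1 allele codes (rows are haplotypes).
#' @param frequencies K non-negative reals summing to 1 (within 1e-12 is
#'   renormalised).
#' @param map Marker map for the L loci.
#' @return An object of class `haplotype_table`.
#' @export
haplotype_table <- function(haplotypes, frequencies, map) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (!all(haplotypes %in% c(0L, 1L))) stop("haplotype codes must be 0/1", call. = FALSE)
  if (nrow(haplotypes) < 1L) stop("need at least one haplotype", call. = FALSE)
  if (length(frequencies) != nrow(haplotypes)) {
    stop("one frequency per haplotype required", call. = FALSE)
  }
  if (any(frequencies < 0)) stop("negative haplotype frequency", call. = FALSE)
  if (abs(sum(frequencies) - 1) > 1e-12) {
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  }
  map <- tibble::as_tibble(map)
  if (nrow(map) != ncol(haplotypes)) {
    stop("map length must equal the number of loci", call. = FALSE)
  }
  structure(
    list(haplotypes = haplotypes, frequencies = frequencies / sum(frequencies),
      map = map),
    class = "haplotype_table"
  )
}

#' Sample an inbred population from a haplotype table
#'
#' Draws `n` individuals i.i.d. from the haplotype distribution; the
#' genotype of an individual is its haplotype (inbred). Deterministic for a
#' given seed.
#'
#' @param table A [haplotype_table()].
#' @param n Number of individuals (`>= 1`).
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated individual ids.
#' @return A [geno_matrix()].
#' @export
sample_population <- function(table, n, seed, id_prefix = "ind") {
  stopifnot(inherits(table, "haplotype_table"), n >= 1)
  idx <- withr::with_seed(
    seed,
    sample.int(nrow(table$haplotypes), n, replace = TRUE, prob = table$frequencies)
  )
  geno_matrix(
    table$haplotypes[idx, , drop = FALSE],
    sprintf("%s%0*d", id_prefix, nchar(n), seq_len(n)),
    table$map
  )
}

#' Evenly spaced marker map over several chromosomes
#'
#' Convenience map builder for simulated genomes: `n_markers` markers laid
#' out in equal numbers across `n_chrom` chromosomes of length `chrom_bp`,
#' evenly spaced.
#'
#' @param n_markers Total marker count.
#' @param n_chrom Number of chromosomes (default 5).
#' @param chrom_bp Chromosome length in bp (default 30 Mb).
#' @param prefix Marker-id prefix.
#' @return A marker-map tibble.
#' @export
uniform_marker_map <- function(n_markers, n_chrom = 5L, chrom_bp = 30e6,
                               prefix = "m") {
  per <- rep(n_markers %/% n_chrom, n_chrom)
  extra <- n_markers %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  purrr::map_dfr(seq_len(n_chrom), function(ch) {
    tibble::tibble(
      chromosome = as.character(ch),
      position = as.integer(round(seq(1, chrom_bp, length.out = per[ch])))
    )
  }) |>
    dplyr::mutate(
      marker_id = paste0(prefix, dplyr::row_number()),
      .before = 1
    )
}

#' Simulate a founder-mosaic inbred genome with distance-decaying LD
#'
#' Each individual's genome is a recombination mosaic of a small set of
#' founder haplotypes. Walking along each chromosome, the current founder
#' is re-drawn between adjacent markers with probability
#' `1 - exp(-recomb_per_bp * gap)`, so LD between markers decays with
#' their bp distance while markers on different chromosomes are
#' independent. With `recomb_per_bp = 0` every individual is an intact
#' founder copy.
#'
#' Founder allele frequencies are drawn per marker log-uniformly on
#' `freq_range` (density proportional to 1/p, the shape of a neutral
#' site-frequency spectrum), so that low-frequency variants are common as
#' in real sequencing data; chance near-coincidence of such rare alleles
#' is what produces strong spurious high-order LD in small samples.
#'
#' @param map Marker map (e.g. [uniform_marker_map()]).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param n_founders Number of founder haplotypes (default 20).
#' @param recomb_per_bp Founder-switch rate per bp (default 1e-6, i.e. a
#'   1 Mb switching scale).
#' @param freq_range Founder allele-frequency range for the code-1 allele
#'   (default `c(0.05, 0.95)`, log-uniform).
#' @return A [geno_matrix()] (columns may include monomorphic markers; use
#'   [filter_maf()] before analysis).
#' @export
simulate_mosaic_genome <- function(map, n, seed, n_founders = 20L,
                                   recomb_per_bp = 1e-6,
                                   freq_range = c(0.05, 0.95)) {
  stopifnot(
    recomb_per_bp >= 0, n >= 1, n_founders >= 1,
    length(freq_range) == 2L, freq_range[1] > 0, freq_range[2] < 1,
    freq_range[1] <= freq_range[2]
  )
  map <- tibble::as_tibble(map)
  ord <- order(map$chromosome, map$position)
  map <- map[ord, , drop = FALSE]
  L <- nrow(map)
  codes <- withr::with_seed(seed, {
    p_m <- exp(stats::runif(L, log(freq_range[1]), log(freq_range[2])))
    founders <- matrix(
      as.integer(stats::runif(n_founders * L) < rep(p_m, each = n_founders)),
      nrow = n_founders
    )
    out <- matrix(0L, nrow = n, ncol = L)
    for (chr in unique(map$chromosome)) {
      cols <- which(map$chromosome == chr)
      pos <- as.numeric(map$position[cols])
      cur <- sample.int(n_founders, n, replace = TRUE)
      out[, cols[1L]] <- founders[cbind(cur, cols[1L])]
      if (length(cols) > 1L) {
        p_switch <- 1 - exp(-recomb_per_bp * diff(pos))
        for (k in 2L:length(cols)) {
          sw <- stats::runif(n) < p_switch[k - 1L]
          if (any(sw)) cur[sw] <- sample.int(n_founders, sum(sw), replace = TRUE)
          out[, cols[k]] <- founders[cbind(cur, cols[k])]
        }
      }
    }
    out
  })
  geno_matrix(codes, sprintf("ind%0*d", nchar(n), seq_len(n)), map)
}

#' The perfectly tagged hidden-locus scenario
#'
#' Constructs the canonical configuration in which statistical epistasis
#' emerges from high-order LD alone: two genotyped predictors M1 (alleles
#' A/a) and M2 (B/b) and one hidden target Q whose causal allele is carried
#' *exactly* by the ab two-locus class. The population has the four
#' two-locus classes AB, Ab, aB, ab in equal numbers (`n_per_class` each),
#' so neither predictor alone tags Q well (each individual r-squared is
#' 1/3) while pseudomarker P4 = \{ab vs non-ab\} tags it perfectly
#' (second-order r-squared 1). The phenotype is the indicator of the causal
#' Q allele plus optional Gaussian noise — a purely single-locus additive
#' generative model with no interaction term, yet the fitted two-locus
#' model shows a nonzero interaction (with zero noise and equal classes,
#' beta12 = +0.25 for a unit allele effect).
#'
#' @param n_per_class Individuals per two-locus class (`>= 1`).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param noise_sd Phenotype noise standard deviation (default 0).
#' @param effect Phenotypic effect of the causal Q allele (default 1).
#' @return List with `genotypes` (a [geno_matrix()] with markers `M1`,
#'   `M2`, `Q`), `phenotype` (tibble), and `classes` (factor of two-locus
#'   classes).
#' @export
make_perfect_tag_scenario <- function(n_per_class, seed = 1L, noise_sd = 0, effect = 1) {
  stopifnot(n_per_class >= 1)
  cls <- rep(c("AB", "Ab", "aB", "ab"), each = n_per_class)
  g1 <- as.integer(cls %in% c("aB", "ab")) # a allele = code 1
  g2 <- as.integer(cls %in% c("Ab", "ab")) # b allele = code 1
  q <- as.integer(cls == "ab") # causal allele exactly in ab
  map <- tibble::tibble(
    marker_id = c("M1", "M2", "Q"),
    chromosome = c("1", "2", "2"),
    position = c(5000000L, 5000000L, 5400000L)
  )
  ids <- sprintf("acc%0*d", nchar(length(cls)), seq_along(cls))
  g <- geno_matrix(cbind(g1, g2, q), ids, map)
  y <- effect * q
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, stats::rnorm(length(q), 0, noise_sd))
  }
  list(
    genotypes = g,
    phenotype = phenotype(ids, y),
    classes = factor(cls, levels = c("AB", "Ab", "aB", "ab"))
  )
}

#' Genetic-architecture specification for phenotype simulation
#'
#' @param causal Marker ids (or column indices) of the causal loci.
#' @param effects Signed per-allele effects, trait units, one per causal
#'   locus (carried by the code-1 allele).
#' @param noise_sd Gaussian noise standard deviation (`>= 0`).
#' @param mode `"single_locus"`, `"linked_block"` or `"true_epistasis"`.
#' @param epistasis_effect For `mode = "true_epistasis"` (exactly two
#'   causal loci): coefficient of the product of the two additive 1/-1
#'   codes added to the phenotype.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(causal, effects, noise_sd = 0.5,
                              mode = c("single_locus", "linked_block", "true_epistasis"),
                              epistasis_effect = 0) {
  mode <- match.arg(mode)
  if (length(causal) != length(effects)) {
    stop("one effect per causal locus required", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (mode == "true_epistasis" && length(causal) != 2L) {
    stop("true_epistasis mode needs exactly two causal loci", call. = FALSE)
  }
  structure(
    list(causal = causal, effects = as.numeric(effects), noise_sd = noise_sd,
      mode = mode, epistasis_effect = epistasis_effect),
    class = "architecture_spec"
  )
}

#' Simulate a phenotype from a genotype matrix under a known architecture
#'
#' Additive signed allele effects at the causal loci (the code-1 allele of
#' each causal locus carries its effect), plus, in `true_epistasis` mode,
#' an interaction term on the product of the two additive 1/-1 codes, plus
#' Gaussian noise. Deterministic per seed.
#'
#' @param G A [geno_matrix()].
#' @param arch An [architecture_spec()] valid for `G`.
#' @param seed Integer seed.
#' @return A phenotype tibble.
#' @export
simulate_phenotype <- function(G, arch, seed) {
  stopifnot(inherits(arch, "architecture_spec"))
  idx <- arch$causal
  if (is.character(idx)) idx <- match(idx, G$map$marker_id)
  if (anyNA(idx) || any(idx < 1) || any(idx > n_markers(G))) {
    stop("causal loci not found in the panel", call. = FALSE)
  }
  carriers <- G$codes[, idx, drop = FALSE]
  y <- as.numeric(carriers %*% arch$effects)
  if (arch$mode == "true_epistasis" && arch$epistasis_effect != 0) {
    a1 <- encode_additive(G$codes[, idx[1]])
    a2 <- encode_additive(G$codes[, idx[2]])
    y <- y + arch$epistasis_effect * a1 * a2
  }
  if (arch$noise_sd > 0) {
    y <- y + withr::with_seed(seed, stats::rnorm(length(y), 0, arch$noise_sd))
  }
  phenotype(G$individual_ids, y)
}

#' The complex multi-allelic locus scenario
#'
#' Emulates a trait architecture in which one chromosome region carries a
#' tight block of four hidden effect loci — three trait-increasing and one
#' trait-decreasing — in incomplete mutual LD, none of which is genotyped.
#' The population falls into four groups defined by a *cis* predictor
#' (near the block) and a *trans* predictor (another chromosome): the
#' carrier frequencies of the hidden alleles differ by group such that the
#' trans-A group has intermediate phenotypes regardless of the cis
#' genotype, while among trans-G individuals the cis genotype separates a
#' low group (frequent decreaser allele) from a high group (frequent
#' increaser alleles). The cis/trans pair therefore tags the hidden
#' allele combinations far better than any single predictor, and a
#' two-locus scan over the (non-causal) predictor panel detects strong
#' statistical epistasis.
#'
#' @param n Number of accessions (default 340).
#' @param seed Integer seed.
#' @param arch An [architecture_spec()] with `mode = "linked_block"`
#'   supplying the four signed effects and noise (default: effects
#'   `c(+1, +1, +1, -1)` — two trait-increasing SNP-like loci, one
#'   increasing insertion-like locus, one decreasing deletion-like locus;
#'   noise sd 0.5).
#' @param n_background Background (non-causal, unstructured-effect)
#'   predictor markers in the genotyped panel (default 46).
#' @return List with `predictors` (genotyped panel, causal loci excluded),
#'   `targets` (the four hidden causal loci as a [geno_matrix()]),
#'   `phenotype`, `truth` (per-individual group and carrier record),
#'   `pair` (the cis and trans predictor marker ids) and `causal`
#'   (hidden marker ids).
#' @export
make_complex_locus_scenario <- function(n = 340L, seed = 1L,
                                        arch = architecture_spec(
                                          causal = c("hid_inc1", "hid_inc2", "hid_ins", "hid_del"),
                                          effects = c(1, 1, 1, -1),
                                          noise_sd = 0.5,
                                          mode = "linked_block"
                                        ),
                                        n_background = 46L) {
  stopifnot(arch$mode == "linked_block", length(arch$causal) == 4L)
  groups <- c("AC", "AT", "GC", "GT")
  group_freq <- c(AC = 0.30, AT = 0.30, GC = 0.15, GT = 0.25)
  # carrier probability of each hidden minor allele, by group
  # (columns: increaser1, increaser2, increaser3-ins, decreaser-del)
  carrier_prob <- rbind(
    AC = c(0.60, 0.20, 0.00, 0.00),
    AT = c(0.50, 0.30, 0.00, 0.00),
    GC = c(0.10, 0.00, 0.00, 0.80),
    GT = c(0.90, 0.90, 0.70, 0.00)
  )

  sim <- withr::with_seed(seed, {
    grp <- sample(groups, n, replace = TRUE, prob = group_freq)
    hidden <- matrix(0L, n, 4L)
    for (k in 1:4) {
      hidden[, k] <- as.integer(stats::runif(n) < carrier_prob[grp, k])
    }
    # background predictors: group-structured allele frequencies
    p_bg <- matrix(stats::rbeta(4L * n_background, 2, 2), nrow = 4L,
      dimnames = list(groups, NULL))
    bg <- matrix(0L, n, n_background)
    for (m in seq_len(n_background)) {
      bg[, m] <- as.integer(stats::runif(n) < p_bg[grp, m])
    }
    list(grp = grp, hidden = hidden, bg = bg)
  })

  g_trans <- as.integer(substr(sim$grp, 1, 1) == "G") # trans predictor, chr1
  g_cis <- as.integer(substr(sim$grp, 2, 2) == "T") # cis predictor, chr2

  bg_map <- uniform_marker_map(n_background, n_chrom = 5L, prefix = "bg")
  # keep background markers away from the two focal predictors
  pred_map <- dplyr::bind_rows(
    tibble::tibble(marker_id = "pred_trans", chromosome = "1", position = 5315502L),
    tibble::tibble(marker_id = "pred_cis", chromosome = "2", position = 10928720L),
    bg_map
  )
  ids <- sprintf("acc%0*d", nchar(n), seq_len(n))
  predictors <- geno_matrix(
    cbind(g_trans, g_cis, sim$bg), ids, pred_map
  )
  tgt_map <- tibble::tibble(
    marker_id = arch$causal,
    chromosome = "2",
    position = c(10935000L, 10960000L, 10985000L, 11010000L)
  )
  targets <- geno_matrix(sim$hidden, ids, tgt_map)

  y_gen <- as.numeric(sim$hidden %*% arch$effects)
  if (arch$noise_sd > 0) {
    y_gen <- y_gen + withr::with_seed(
      seed + 1L, stats::rnorm(n, 0, arch$noise_sd)
    )
  }
  truth <- tibble::tibble(
    individual_id = ids,
    group = sim$grp,
    genetic_value = as.numeric(sim$hidden %*% arch$effects)
  )
  truth[arch$causal] <- as.data.frame(sim$hidden)

  list(
    predictors = predictors,
    targets = targets,
    phenotype = phenotype(ids, y_gen),
    truth = truth,
    pair = c(cis = "pred_cis", trans = "pred_trans"),
    causal = arch$causal
  )
}
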
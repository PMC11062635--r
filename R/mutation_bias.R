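#' Read a mutation TSV
#'
#' Columns: lineage, position, class (SNP/indel/structural), context
#' (genic/intergenic), effect (nonsynonymous/synonymous/NA), gene, essential.
#' Indel and structural records are located at their leftmost affected
#' coordinate.
#'
#' @param path TSV path.
#' @return data.frame of class `mutation_tbl`.
#' @export
read_mutations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                          stringsAsFactors = FALSE)
  req <- c("lineage", "position", "class", "context", "effect", "gene",
           "essential")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("mutation table lacks columns: ", paste(miss, collapse = ", "))
  class(df) <- c("mutation_tbl", "data.frame")
  df
}

#' Per-lineage mutation summary
#'
#' Reproduces the standard fixed-mutation overview: per lineage the counts of
#' all mutations, intergenic mutations, genic indels, genic SNPs, and the
#' nonsynonymous (N) / synonymous (S) split of the genic SNPs, plus a totals
#' row. Structural events count toward "all" but toward no category, so
#' intergenic + genic indel + genic SNP <= all.
#'
#' @param records a `mutation_tbl` data.frame.
#' @param lineages optional lineage ordering; defaults to sorted unique ids.
#' @return data.frame with one row per lineage plus a `Sum` row; columns
#'   lineage, all, intergenic, genic_indel, genic_snp, N, S.
#' @export
summarize_mutations <- function(records, lineages = NULL) {
  if (nrow(records) == 0) {
    out <- data.frame(lineage = "Sum", all = 0L, intergenic = 0L,
                      genic_indel = 0L, genic_snp = 0L, N = 0L, S = 0L,
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(lineages)) lineages <- sort(unique(records$lineage))
  unknown <- setdiff(records$lineage, lineages)
  if (length(unknown) > 0)
    stop("unknown lineage id(s): ", paste(unknown, collapse = ", "))
  one <- function(lin) {
    r <- records[records$lineage == lin, ]
    structural <- r$class == "structural"
    data.frame(
      lineage = lin,
      all = nrow(r),
      intergenic = sum(r$context == "intergenic" & !structural),
      genic_indel = sum(r$context == "genic" & r$class == "indel"),
      genic_snp = sum(r$context == "genic" & r$class == "SNP"),
      N = sum(r$context == "genic" & r$class == "SNP" &
                r$effect == "nonsynonymous", na.rm = TRUE),
      S = sum(r$context == "genic" & r$class == "SNP" &
                r$effect == "synonymous", na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  per <- do.call(rbind, lapply(lineages, one))
  tot <- data.frame(lineage = "Sum", t(colSums(per[-1])),
                    stringsAsFactors = FALSE)
  rbind(per, tot)
}

#' Circular distance to the nearest scar
#'
#' On a circular chromosome of length L, the distance from position p to scar
#' s is min(|p - s|, L - |p - s|); the result is the minimum over all scars.
#' With `linear = TRUE` the wrap-around arc is ignored.
#'
#' @param position bp position(s), vectorized.
#' @param layout a [genome_layout()] with >= 1 scar.
#' @param linear treat the chromosome as linear.
#' @return bp distance(s).
#' @export
#' @examples
#' ly <- genome_layout(1000, scars = c(100, 900))
#' distance_to_nearest_scar(1, ly)  # 99: wraps past the origin to 900
distance_to_nearest_scar <- function(position, layout, linear = FALSE) {
  stopifnot(inherits(layout, "genome_layout"))
  if (length(layout$scars) == 0) stop("layout has no scars")
  if (any(position < 1 | position > layout$length))
    stop("position outside [1, genome length]")
  d <- abs(outer(position, layout$scars, "-"))
  if (!linear && layout$circular) d <- pmin(d, layout$length - d)
  apply(d, 1, min)
}

#' Welch's two-sample t-test
#'
#' t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b) with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. Degenerate
#' inputs (zero variance in both samples) return p = 1 when the means are
#' equal and p = 0 otherwise.
#'
#' @param a,b numeric vectors, each >= 2 values.
#' @return list(t, df, p).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t needs >= 2 values per sample")
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  se2 <- va + vb
  if (se2 == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = na + nb - 2, p = if (eq) 1 else 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Randomization test for mutation locational bias
#'
#' For each of `n_replicates` replicates, draws as many uniform positions on
#' the chromosome as there are observed mutations, computes their distances
#' to the nearest scar, and runs a two-sided Welch's t-test against the
#' observed distances. The decision statistic is mu_p, the mean of the
#' replicate p-values; mu_p > 0.05 reads "no locational bias". The 95%
#' interval for mu_p is the normal approximation
#' mu_p +/- 1.96 * SD(p) / sqrt(n_replicates).
#'
#' @param observed a `mutation_tbl` (or data.frame with a `position` column),
#'   >= 2 records.
#' @param layout a [genome_layout()] with >= 1 scar.
#' @param n_replicates number of random replicates (default 1000).
#' @param seed integer seed; same seed, same result, bit for bit.
#' @param linear passed to [distance_to_nearest_scar()].
#' @return object of class `randomization_result`: observed_distances,
#'   p_values, mu_p, ci95, n_replicates, seed, sidedness, verdict.
#' @export
randomization_test <- function(observed, layout, n_replicates = 1000,
                               seed = 1L, linear = FALSE) {
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(observed) < 2)
    stop("randomization test needs >= 2 observed mutations")
  if (length(layout$scars) == 0) stop("layout has no scars")
  n <- nrow(observed)
  d_obs <- distance_to_nearest_scar(observed$position, layout, linear)
  L <- layout$length
  withr::with_seed(as.integer(seed), {
    p <- vapply(seq_len(n_replicates), function(i) {
      pos <- ceiling(stats::runif(n, 0, L))
      d_rand <- distance_to_nearest_scar(pos, layout, linear)
      welch_t(d_rand, d_obs)$p
    }, numeric(1))
  })
  mu_p <- mean(p)
  half <- 1.96 * stats::sd(p) / sqrt(n_replicates)
  structure(list(
    observed_distances = d_obs, p_values = p, mu_p = mu_p,
    ci95 = c(mu_p - half, mu_p + half), n_replicates = n_replicates,
    seed = as.integer(seed), sidedness = "two-sided",
    verdict = if (mu_p > 0.05) "no locational bias" else "locational bias"
  ), class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "randomization_result: %d replicates, mu_p = %.4f (95%% CI %.4f-%.4f)\n  %s\n",
    x$n_replicates, x$mu_p, x$ci95[1], x$ci95[2], x$verdict))
  invisible(x)
}

#' Essential-gene ratio contingency test
#'
#' Compares the essential-gene fraction among mutated genes (k of n) with the
#' genome-wide fraction (K of N) by a Pearson chi-square test on the 2x2
#' table mutated/not x essential/not. Both the uncorrected and the
#' Yates-corrected variants are computed; `correct` selects which pair is
#' reported as `chi2`/`p`.
#'
#' @param k_ess_mut essential genes among mutated genes.
#' @param n_mut number of mutated genes.
#' @param K_ess essential genes in the genome.
#' @param N_genes genes in the genome.
#' @param correct use the Yates continuity correction (default FALSE).
#' @return list: ratio_mut and ratio_all (percent), chi2, p, chi2_corrected,
#'   p_corrected, warning (NULL or text).
#' @export
#' @examples
#' essentiality_ratio_test(11, 49, 286, 3290)
essentiality_ratio_test <- function(k_ess_mut, n_mut, K_ess, N_genes,
                                    correct = FALSE) {
  if (k_ess_mut > n_mut || K_ess > N_genes || n_mut > N_genes)
    stop("inconsistent counts")
  if (k_ess_mut > K_ess) stop("more essential mutated genes than essentials")
  # 2x2: rows mutated / not mutated, cols essential / not
  tab <- rbind(c(k_ess_mut, n_mut - k_ess_mut),
               c(K_ess - k_ess_mut, N_genes - n_mut - (K_ess - k_ess_mut)))
  warning_txt <- NULL
  rs <- rowSums(tab); cs <- colSums(tab); tot <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    chi2 <- chi2c <- 0
    p <- pc <- 1
    warning_txt <- "degenerate margin: chi-square undefined, p set to 1"
  } else {
    expd <- outer(rs, cs) / tot
    if (any(expd < 1))
      warning_txt <- "expected cell count < 1: chi-square approximation unreliable"
    chi2 <- sum((tab - expd)^2 / expd)
    chi2c <- sum((abs(tab - expd) - 0.5)^2 / expd)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    pc <- stats::pchisq(chi2c, df = 1, lower.tail = FALSE)
  }
  out <- list(ratio_mut = 100 * k_ess_mut / n_mut,
              ratio_all = 100 * K_ess / N_genes,
              chi2 = if (correct) chi2c else chi2,
              p = if (correct) pc else p,
              chi2_uncorrected = chi2, p_uncorrected = p,
              chi2_corrected = chi2c, p_corrected = pc,
              warning = warning_txt)
  if (!is.null(warning_txt)) warning(warning_txt, call. = FALSE)
  out
}

#' Normalized genomic positions
#'
#' Positions rescaled to fractions of the genome, for cross-genome plots.
#'
#' @param records a `mutation_tbl`.
#' @param layout a [genome_layout()].
#' @return numeric vector in [0, 1).
#' @export
normalized_positions <- function(records, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  if (any(records$position < 1 | records$position > layout$length))
    stop("position outside genome")
  (records$position - 1) / layout$length
}
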
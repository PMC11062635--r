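#' Gene annotation map
#'
#' One annotation scheme (gene categories, regulons, GO-like terms): a map
#' from label to gene set, plus the background universe.
#'
#' @param universe character vector of background gene ids.
#' @param labels named list: label -> character vector of member gene ids.
#' @return object of class `annotation_map`.
#' @export
annotation_map <- function(universe, labels) {
  universe <- unique(as.character(universe))
  labels <- lapply(labels, function(g) unique(as.character(g)))
  out_of <- unlist(lapply(labels, setdiff, y = universe))
  if (length(out_of) > 0)
    stop("labelled gene(s) outside the universe: ",
         paste(utils::head(out_of, 5), collapse = ", "))
  structure(list(universe = universe, labels = labels),
            class = "annotation_map")
}

#' Read an annotation TSV (gene_id, scheme, label) into annotation maps
#'
#' @param path TSV path.
#' @param universe background gene ids; defaults to all genes in the file.
#' @return named list of [annotation_map()], one per scheme.
#' @export
read_annotations <- function(path, universe = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (is.null(universe)) universe <- unique(df$gene_id)
  lapply(split(df, df$scheme), function(d) {
    annotation_map(universe, split(d$gene_id, d$label))
  })
}

#' Binomial enrichment with Bonferroni correction
#'
#' For each label with more than `min_label_size` members, tests whether the
#' query hits it more (or less) often than the background fraction K/N
#' predicts: p_over = P(X >= k), p_under = P(X <= k) for X ~ Binomial(n,
#' K/N). Bonferroni multiplies by the number of labels actually tested.
#' A hypergeometric variant (sampling without replacement) is available for
#' comparison.
#'
#' @param query character vector of gene ids, non-empty, within the universe.
#' @param annot an [annotation_map()].
#' @param min_label_size labels must have strictly more members than this
#'   (default 15) to be tested.
#' @param model `"binomial"` (default) or `"hypergeometric"`.
#' @return data.frame of class `enrichment_result`: label, k, n, K, N,
#'   expected, direction, p_raw, p_adjusted, sorted by p_adjusted.
#' @export
binomial_enrichment <- function(query, annot, min_label_size = 15,
                                model = c("binomial", "hypergeometric")) {
  model <- match.arg(model)
  stopifnot(inherits(annot, "annotation_map"))
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query")
  outside <- setdiff(query, annot$universe)
  if (length(outside) > 0)
    stop("query gene(s) not in universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  keep <- names(annot$labels)[vapply(annot$labels, length, 1L) > min_label_size]
  if (length(keep) == 0)
    return(structure(data.frame(), class = c("enrichment_result",
                                             "data.frame")))
  N <- length(annot$universe)
  n <- length(query)
  rows <- lapply(keep, function(lb) {
    members <- annot$labels[[lb]]
    K <- length(members)
    k <- length(intersect(query, members))
    if (model == "binomial") {
      p_over <- stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
      p_under <- stats::pbinom(k, n, K / N)
    } else {
      p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      p_under <- stats::phyper(k, K, N - K, n)
    }
    over <- k >= n * K / N
    data.frame(label = lb, k = k, n = n, K = K, N = N,
               expected = n * K / N,
               direction = if (over) "over" else "under",
               p_raw = if (over) p_over else p_under,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- pmin(1, res$p_raw * nrow(res))
  res <- res[order(res$p_adjusted, res$p_raw, res$label), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Adjust enrichment p-values with an alternative correction
#'
#' Benjamini-Hochberg is offered for FDR-style workflows; Bonferroni is the
#' default the enrichment table already carries.
#'
#' @param result an `enrichment_result`.
#' @param method `"bonferroni"` or `"BH"`.
#' @return the result with `p_adjusted` recomputed.
#' @export
adjust_enrichment <- function(result, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  result$p_adjusted <- stats::p.adjust(result$p_raw, method = method)
  result
}

#' Overlap structure of named gene sets
#'
#' Intersection size of every combination of two or more sets, and the
#' per-gene multiplicity histogram (how many genes occur in exactly m sets).
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @return list: `combinations` (data.frame sets, size, intersection),
#'   `multiplicity` (data.frame n_sets, n_genes).
#' @export
overlap_table <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  nm <- names(sets)
  combos <- list()
  for (m in 2:length(sets)) {
    cb <- utils::combn(nm, m, simplify = FALSE)
    combos <- c(combos, cb)
  }
  comb_df <- do.call(rbind, lapply(combos, function(cb) {
    inter <- Reduce(intersect, sets[cb])
    data.frame(sets = paste(cb, collapse = "+"), size = length(cb),
               intersection = length(inter), stringsAsFactors = FALSE)
  }))
  all_genes <- unique(unlist(sets))
  mult <- vapply(all_genes, function(g) {
    sum(vapply(sets, function(s) g %in% s, logical(1)))
  }, integer(1))
  mult_df <- as.data.frame(table(factor(mult, levels = 1:length(sets))),
                           stringsAsFactors = FALSE)
  names(mult_df) <- c("n_sets", "n_genes")
  mult_df$n_sets <- as.integer(mult_df$n_sets)
  list(combinations = comb_df, multiplicity = mult_df)
}
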
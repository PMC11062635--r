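#' Genome layout: the shared coordinate frame
#'
#' A `genome_layout` holds the circular chromosome length, the positions of
#' deletion scar junctions, and the gene coordinate table. All coordinates are
#' 1-based inclusive on a circular chromosome; scars are point junctions (the
#' residual boundary of an excised fragment), not intervals.
#'
#' @param length chromosome length in bp.
#' @param scars numeric vector of scar junction positions (bp), any order.
#' @param genes data.frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `essential`, `category`, `regulons` (comma-separated labels, may be "").
#' @param circular logical; circular chromosome (the default and the only
#'   topology the distance machinery fully supports).
#' @return object of class `genome_layout`.
#' @export
genome_layout <- function(length, scars = numeric(0), genes = NULL,
                          circular = TRUE) {
  length <- as.numeric(length)
  if (!is.finite(length) || length <= 0) stop("genome length must be positive")
  scars <- sort(as.numeric(scars))
  if (any(scars < 1 | scars > length))
    stop("scar positions must lie in [1, length]")
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0),
                        essential = logical(0), category = character(0),
                        regulons = character(0), stringsAsFactors = FALSE)
  }
  req <- c("gene_id", "start", "end", "strand", "essential", "category",
           "regulons")
  miss <- setdiff(req, names(genes))
  if (length(miss) > 0)
    stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (nrow(genes) > 0) {
    if (any(genes$start > genes$end))
      stop("gene start must be <= end (no wrap-around genes)")
    if (any(genes$start < 1 | genes$end > length))
      stop("gene coordinates must lie in [1, length]")
  }
  structure(list(length = length, circular = isTRUE(circular),
                 scars = scars, genes = genes),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %.0f bp (%s), %d scars, %d genes\n",
              x$length, if (x$circular) "circular" else "linear",
              length(x$scars), nrow(x$genes)))
  invisible(x)
}

#' Generate a synthetic reduced-genome layout
#'
#' Scar junctions are drawn uniformly on the circle. Genes are laid out
#' non-overlapping in genome order with lengths uniform around 1 kb and the
#' residual intergenic space split at uniform random cuts. Each gene is
#' flagged essential with probability 286/3290 (the essential-gene ratio of
#' the reduced genome) and assigned a functional category and 0-2 regulons.
#'
#' @param cfg a [sim_config()].
#' @return a [genome_layout()].
#' @export
#' @examples
#' layout <- gen_genome_layout(sim_config(seed = 1))
#' layout
gen_genome_layout <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  withr::with_seed(derive_seed(cfg$seed, "layout"), {
    L <- cfg$genome_length
    n <- cfg$n_genes
    scars <- if (cfg$n_scars > 0) sort(ceiling(stats::runif(cfg$n_scars, 0, L)))
             else numeric(0)
    if (n == 0) return(genome_layout(L, scars))
    lens <- round(stats::runif(n, 800, 1200))
    total <- sum(lens)
    if (total > L)
      stop("infeasible layout: total gene span ", total,
           " bp exceeds genome length ", L, " bp")
    # split the leftover space into n gaps via uniform cuts on [0, slack]
    slack <- L - total
    cuts <- sort(stats::runif(n - 1, 0, slack))
    gaps <- diff(c(0, cuts, slack))
    starts <- cumsum(c(1, lens[-n] + gaps[-n]))
    ends <- starts + lens - 1
    ess <- stats::runif(n) < 286 / 3290
    cats <- sample(.gene_categories, n, replace = TRUE)
    n_reg <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
    regs <- vapply(n_reg, function(k) {
      if (k == 0) "" else paste(sample(.regulon_names, k), collapse = ",")
    }, character(1))
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n)),
      start = starts, end = ends,
      strand = sample(c("+", "-"), n, replace = TRUE),
      essential = ess, category = cats, regulons = regs,
      stringsAsFactors = FALSE
    )
    genome_layout(L, scars, genes)
  })
}

.gene_categories <- c(
  "Transporter", "Enzyme", "Unknown function", "Transcription factor",
  "Membrane", "Carrier", "Regulator", "Factor", "Cell process", "Structure",
  "Phage/IS", "RNA", "Lipoprotein", "Carbon metabolism", "Amino acid",
  "Nucleotide", "Cofactor", "Energy", "Cell division", "Stress", "Motility"
)

.regulon_names <- sprintf("R_%02d", 1:46)

#' Write / read a genome layout as plain-text files
#'
#' The on-disk form is a directory with `genome.txt` (length + circular flag),
#' `scars.bed` (BED 3-column, 0-based half-open width-1 intervals marking the
#' junction points) and `genes.tsv`.
#'
#' @param layout a [genome_layout()].
#' @param dir output directory (created if absent).
#' @return `write_genome_layout` returns `dir` invisibly;
#'   `read_genome_layout` returns a [genome_layout()].
#' @export
write_genome_layout <- function(layout, dir) {
  stopifnot(inherits(layout, "genome_layout"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(sprintf("length\t%.0f", layout$length),
               sprintf("circular\t%s", if (layout$circular) "true" else "false")),
             file.path(dir, "genome.txt"))
  # BED is 0-based half-open: junction at 1-based p becomes [p-1, p)
  bed <- data.frame(chrom = "chr",
                    start = as.integer(layout$scars - 1),
                    end = as.integer(layout$scars))
  utils::write.table(bed, file.path(dir, "scars.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(layout$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_genome_layout
#' @export
read_genome_layout <- function(dir) {
  hdr <- utils::read.table(file.path(dir, "genome.txt"), sep = "\t",
                           stringsAsFactors = FALSE)
  len <- as.numeric(hdr[hdr[[1]] == "length", 2])
  circ <- tolower(hdr[hdr[[1]] == "circular", 2]) == "true"
  bed_path <- file.path(dir, "scars.bed")
  scars <- numeric(0)
  if (file.exists(bed_path) && file.size(bed_path) > 0) {
    bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE)
    scars <- as.numeric(bed[[3]])  # half-open end == 1-based junction
  }
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = c(regulons = "character"))
  genes$regulons[is.na(genes$regulons)] <- ""
  genome_layout(len, scars, genes, circular = circ)
}
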
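# Shared fixtures, all built in code.

# Transcription of the nine-lineage fixed-mutation overview used throughout:
# per lineage (all, intergenic, genic indel, genic SNP, N, S); rows where the
# four categories undercount `all` are padded with structural events.
table1_counts <- function() {
  data.frame(
    lineage = c("A1", "A2", "B2", "C2", "D2", "E2", "F2", "G2", "H2"),
    all = c(3, 2, 13, 11, 7, 3, 8, 12, 6),
    intergenic = c(0, 1, 0, 1, 0, 1, 1, 2, 0),
    genic_indel = c(0, 0, 1, 0, 1, 0, 0, 2, 2),
    genic_snp = c(2, 1, 11, 9, 5, 1, 6, 6, 4),
    N = c(1, 1, 9, 8, 4, 1, 5, 4, 3),
    S = c(1, 0, 2, 1, 1, 0, 1, 2, 1),
    stringsAsFactors = FALSE
  )
}

# expand the counts into one mutation record per event
table1_records <- function(genome_length = 3670000) {
  tc <- table1_counts()
  rows <- list()
  pos <- 0
  add <- function(lineage, n, class, context, effect) {
    if (n == 0) return(NULL)
    p <- pos + seq_len(n)
    pos <<- pos + n
    data.frame(lineage = lineage, position = p * 1000, class = class,
               context = context, effect = effect,
               gene = if (context == "genic") sprintf("g%03d", p)
                      else NA_character_,
               essential = NA, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tc))) {
    lin <- tc$lineage[i]
    rows <- c(rows, list(
      add(lin, tc$intergenic[i], "SNP", "intergenic", NA_character_),
      add(lin, tc$genic_indel[i], "indel", "genic", NA_character_),
      add(lin, tc$N[i], "SNP", "genic", "nonsynonymous"),
      add(lin, tc$S[i], "SNP", "genic", "synonymous"),
      add(lin, tc$all[i] - tc$intergenic[i] - tc$genic_indel[i] -
            tc$genic_snp[i], "structural", "genic", NA_character_)
    ))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  stopifnot(max(out$position) <= genome_length)
  class(out) <- c("mutation_tbl", "data.frame")
  out
}

# small deterministic layout for unit tests
tiny_layout <- function(length = 1000, scars = c(100, 900)) {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    start = c(10, 300, 700), end = c(110, 400, 800),
    strand = c("+", "-", "+"), essential = c(TRUE, FALSE, FALSE),
    category = c("Enzyme", "Transporter", "Unknown function"),
    regulons = c("R_01", "", "R_02,R_03"), stringsAsFactors = FALSE
  )
  genome_layout(length, scars, genes)
}

# brute-force circular distance oracle, independent of the implementation
brute_scar_distance <- function(position, scars, L) {
  vapply(position, function(p) {
    min(vapply(scars, function(s) {
      d <- abs(p - s)
      min(d, L - d)
    }, numeric(1)))
  }, numeric(1))
}

# brute-force DFT periodogram oracle (O(n^2), tiny n only)
brute_periodogram <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- floor((n - 1) / 2)
  vapply(seq_len(m), function(k) {
    w <- 2 * pi * k * (0:(n - 1)) / n
    (sum(x * cos(w))^2 + sum(x * sin(w))^2) / n
  }, numeric(1))
}
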
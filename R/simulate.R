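#' Deterministic logistic growth trajectory
#'
#' od(t) = K * od0 * exp(r t) / (K + od0 * (exp(r t) - 1)).
#'
#' @param t time in hours (vector).
#' @param r per-hour exponential rate.
#' @param K carrying capacity (OD600).
#' @param od0 inoculum density (OD600).
#' @return OD600 values.
#' @export
logistic_od <- function(t, r, K, od0) {
  if (r <= 0 || K <= 0 || od0 <= 0 || K <= od0)
    stop("logistic parameters require r > 0 and K > od0 > 0")
  e <- exp(r * t)
  K * od0 * e / (K + od0 * (e - 1))
}

# OD detection floor; plate readers cannot resolve below this
.od_floor <- 0.001

#' Simulate mutations on a genome layout
#'
#' Under the `null` model, positions are i.i.d. uniform on `[1, length]` —
#' the null the randomization test draws from. Under `scar_biased`, each
#' position is a uniformly chosen scar plus a signed exponential offset with
#' scale `bias_scale`, wrapped on the circle; this model exists to give the
#' locational-bias test something to detect in power checks.
#'
#' Each record is classified genic/intergenic against the layout's genes;
#' mutation class is sampled (SNP/indel/structural) and genic SNPs get a
#' nonsynonymous/synonymous call.
#'
#' @param layout a [genome_layout()].
#' @param n number of mutations.
#' @param model `"null"` or `"scar_biased"`.
#' @param bias_scale exponential scale (bp) for the biased model.
#' @param seed integer seed.
#' @param n_lineages lineage ids are cycled over this many lineages.
#' @return data.frame of class `mutation_tbl` with columns lineage, position,
#'   class, context, effect, gene, essential.
#' @export
gen_mutations <- function(layout, n, model = c("null", "scar_biased"),
                          bias_scale = 10000, seed = 1L, n_lineages = 9L) {
  stopifnot(inherits(layout, "genome_layout"), n >= 0)
  model <- match.arg(model)
  if (model == "scar_biased" && length(layout$scars) == 0)
    stop("scar_biased placement requires at least one scar")
  L <- layout$length
  withr::with_seed(derive_seed(seed, "mutations"), {
    if (n == 0) {
      pos <- numeric(0)
    } else if (model == "null") {
      pos <- ceiling(stats::runif(n, 0, L))
    } else {
      s <- sample(layout$scars, n, replace = TRUE)
      off <- stats::rexp(n, rate = 1 / max(bias_scale, .Machine$double.xmin)) *
        sample(c(-1, 1), n, replace = TRUE)
      if (bias_scale == 0) off <- rep(0, n)
      pos <- ((s + round(off) - 1) %% L) + 1
    }
    cls <- if (n > 0) sample(c("SNP", "indel", "structural"), n,
                             replace = TRUE, prob = c(0.75, 0.15, 0.10))
           else character(0)
    gene_idx <- locate_genes(pos, layout)
    context <- ifelse(is.na(gene_idx), "intergenic", "genic")
    effect <- rep(NA_character_, n)
    genic_snp <- which(cls == "SNP" & context == "genic")
    if (length(genic_snp) > 0)
      effect[genic_snp] <- sample(c("nonsynonymous", "synonymous"),
                                  length(genic_snp), replace = TRUE,
                                  prob = c(0.8, 0.2))
    gene <- ifelse(is.na(gene_idx), NA_character_,
                   layout$genes$gene_id[gene_idx])
    ess <- ifelse(is.na(gene_idx), NA, layout$genes$essential[gene_idx])
    lineage <- if (n > 0)
      sprintf("L%d", ((seq_len(n) - 1) %% n_lineages) + 1) else character(0)
    out <- data.frame(lineage = lineage, position = pos, class = cls,
                      context = context, effect = effect, gene = gene,
                      essential = ess, stringsAsFactors = FALSE)
    class(out) <- c("mutation_tbl", "data.frame")
    out
  })
}

# index of the gene containing each position, NA if intergenic;
# assumes non-overlapping genes (the layout convention)
locate_genes <- function(pos, layout) {
  g <- layout$genes
  if (nrow(g) == 0 || length(pos) == 0) return(rep(NA_integer_, length(pos)))
  o <- order(g$start)
  idx <- findInterval(pos, g$start[o])
  hit <- idx >= 1
  inside <- hit & pos <= g$end[o][pmax(idx, 1)]
  ifelse(inside, o[pmax(idx, 1)], NA_integer_)
}

#' Simulate a plate-reader growth curve
#'
#' Logistic trajectory sampled on the plate-reader grid plus i.i.d. Gaussian
#' noise, floored at the 0.001 OD detection limit.
#'
#' @param r_true per-hour exponential rate (> 0).
#' @param K carrying capacity, OD600 (> od0).
#' @param od0 inoculum OD600 (> 0).
#' @param noise_sd OD noise SD.
#' @param cfg a [sim_config()] supplying the time grid.
#' @param seed integer seed.
#' @param replicate,lineage ids stored on the curve.
#' @return a [growth_curve()].
#' @export
gen_growth_curve <- function(r_true, K, od0 = 0.005, noise_sd = 0.005,
                             cfg = sim_config(), seed = 1L,
                             replicate = "rep1", lineage = "anc") {
  cfg <- validate_sim_config(cfg)
  times <- seq(0, cfg$od_duration, by = cfg$od_interval / 60)
  od_clean <- logistic_od(times, r_true, K, od0)
  withr::with_seed(derive_seed(seed, "growth"), {
    od <- od_clean + stats::rnorm(length(times), 0, noise_sd)
  })
  od <- pmax(od, .od_floor)
  growth_curve(times, od, replicate = replicate, lineage = lineage)
}

#' Simulate a per-gene expression profile with a chromosomal wave
#'
#' Per-gene log10 expression is
#' `baseline + amplitude * sin(2*pi*(midpoint + phase) * period_count / L)`
#' plus Gaussian noise — the spatial signal whose period the periodicity
#' pipeline is supposed to recover.
#'
#' @param layout a [genome_layout()] (supplies gene coordinates and L).
#' @param period_count integer cycles per genome.
#' @param amplitude sinusoid amplitude (log10 units).
#' @param phase phase offset in bp.
#' @param baseline mean log10 expression.
#' @param noise_sd per-gene noise SD (log10 units).
#' @param seed integer seed.
#' @param sample_id id stored on the profile.
#' @return an [expression_profile()].
#' @export
gen_expression_profile <- function(layout, period_count = 6L, amplitude = 0.2,
                                   phase = 0, baseline = 1.0, noise_sd = 0.2,
                                   seed = 1L, sample_id = "S1") {
  stopifnot(inherits(layout, "genome_layout"), period_count >= 0)
  g <- layout$genes
  if (nrow(g) < 2) stop("expression profile needs at least 2 genes")
  mid <- (g$start + g$end) / 2
  signal <- baseline +
    amplitude * sin(2 * pi * (mid + phase) * period_count / layout$length)
  withr::with_seed(derive_seed(seed, "expression"), {
    expr <- signal + stats::rnorm(nrow(g), 0, noise_sd)
  })
  expression_profile(g$gene_id, g$start, g$end, expr,
                     genome_length = layout$length, sample_id = sample_id)
}

#' Simulate a serial-transfer daily log
#'
#' Emulates the daily routine of the serial-transfer regime: each day the
#' previous culture is diluted at one of four tenfold ratios (10^3-10^6) and
#' regrown; the well transferred is the one whose OD at transfer lands in the
#' early exponential window 0.01-0.1. Preference order: the largest dilution
#' that reaches the window at the nominal ~24 h interval; failing that, the
#' interval is stretched or shortened (12-72 h, mimicking the experimenter
#' waiting for a slow culture) toward a mid-window target; days where no
#' dilution/interval combination reaches the window are flagged `infeasible`
#' but still recorded.
#'
#' @param r_true_schedule per-day per-hour exponential rates.
#' @param dilutions candidate fold-dilutions, subset of c(1e3,1e4,1e5,1e6).
#' @param cfg a [sim_config()].
#' @param seed integer seed (jitters the measured ODs by 2% lognormal).
#' @param K carrying capacity for the daily growth.
#' @param od_init OD600 of the founding culture before the first dilution.
#' @param interval_h nominal transfer interval, hours.
#' @return a `transfer_log` data.frame: day, dilution, od_start, od_end,
#'   interval_h, infeasible.
#' @export
gen_serial_transfer_log <- function(r_true_schedule,
                                    dilutions = c(1e3, 1e4, 1e5, 1e6),
                                    cfg = sim_config(), seed = 1L,
                                    K = 1.0, od_init = 0.05,
                                    interval_h = 24) {
  if (length(r_true_schedule) == 0) stop("rate schedule must be non-empty")
  if (!all(dilutions %in% c(1e3, 1e4, 1e5, 1e6)))
    stop("dilutions must be from {1e3, 1e4, 1e5, 1e6}")
  dilutions <- sort(dilutions)
  n_days <- length(r_true_schedule)
  grow <- function(od0, r, t) logistic_od(t, r, K, min(od0, K * 0.999))
  withr::with_seed(derive_seed(seed, "transfer"), {
    jitter <- matrix(exp(stats::rnorm(2 * n_days, 0, 0.02)), ncol = 2)
    prev_end <- od_init
    rec <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      r <- r_true_schedule[d]
      cand0 <- pmax(prev_end / dilutions, 1e-12)
      end_nominal <- vapply(cand0, grow, numeric(1), r = r, t = interval_h)
      ok <- end_nominal >= 0.01 & end_nominal <= 0.1
      if (any(ok)) {
        pick <- max(which(ok))  # most dilute well still in the window
        dt <- interval_h
        od_end <- end_nominal[pick]
        infeasible <- FALSE
      } else {
        # stretch/shorten the interval toward a mid-window target
        target <- min(0.05, 0.9 * K)
        t_need <- vapply(cand0, function(x) {
          if (x >= target) return(12)
          log(target * (K - x) / (x * (K - target))) / r
        }, numeric(1))
        dt_cand <- pmin(pmax(t_need, 12), 72)
        end_cand <- mapply(grow, cand0, t = dt_cand,
                           MoreArgs = list(r = r))
        okw <- end_cand >= 0.01 & end_cand <= 0.1
        if (any(okw)) {
          pool <- which(okw)
          pick <- pool[which.min(abs(dt_cand[pool] - interval_h))]
          infeasible <- FALSE
        } else {
          pick <- which.min(abs(log10(pmax(end_cand, 1e-12)) - log10(0.05)))
          infeasible <- TRUE
        }
        dt <- dt_cand[pick]
        od_end <- end_cand[pick]
      }
      od_start <- cand0[pick] * jitter[d, 1]
      od_end <- od_end * jitter[d, 2]
      rec[[d]] <- data.frame(day = d, dilution = dilutions[pick],
                             od_start = od_start, od_end = od_end,
                             interval_h = dt, infeasible = infeasible)
      prev_end <- od_end
    }
  })
  out <- do.call(rbind, rec)
  class(out) <- c("transfer_log", "data.frame")
  out
}

#' Write simulated inputs as plain-text files
#'
#' Emits the standard on-disk forms every downstream stage reads: layout
#' directory, wide plate-reader CSV (`time_min` + one column per well),
#' mutation TSV, transfer-log TSV and expression TSV.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory.
#' @return invisibly, a list of the generated in-memory objects.
#' @export
simulate_inputs <- function(cfg, outdir) {
  cfg <- validate_sim_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  layout <- gen_genome_layout(cfg)
  write_genome_layout(layout, file.path(outdir, "layout"))

  muts <- gen_mutations(layout, cfg$n_mutations, model = "null",
                        seed = cfg$seed, n_lineages = cfg$n_lineages)
  utils::write.table(muts, file.path(outdir, "mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # one curve per lineage plus the ancestor, rates spread over a realistic band
  rates <- seq(0.25, 0.45, length.out = cfg$n_lineages)
  curves <- lapply(seq_len(cfg$n_lineages), function(i) {
    gen_growth_curve(rates[i], K = 0.9, cfg = cfg, seed = cfg$seed + i,
                     replicate = "rep1", lineage = sprintf("L%d", i))
  })
  times <- curves[[1]]$times
  od_mat <- vapply(curves, function(cv) cv$od, numeric(length(times)))
  plate <- data.frame(time_min = times * 60, od_mat)
  names(plate)[-1] <- sprintf("L%d", seq_len(cfg$n_lineages))
  utils::write.csv(plate, file.path(outdir, "plate.csv"), row.names = FALSE,
                   quote = FALSE)

  tlog <- gen_serial_transfer_log(
    r_true_schedule = seq(0.3, 0.45, length.out = 30),
    cfg = cfg, seed = cfg$seed)
  utils::write.table(tlog, file.path(outdir, "transfers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  prof <- gen_expression_profile(layout, period_count = cfg$period_count,
                                 amplitude = cfg$amplitude,
                                 noise_sd = cfg$noise_sd, seed = cfg$seed)
  write_expression_profile(prof, file.path(outdir, "expression.tsv"))

  invisible(list(layout = layout, mutations = muts, curves = curves,
                 transfer_log = tlog, expression = prof))
}
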
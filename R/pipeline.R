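#' Pipeline configuration
#'
#' Builds (or reads from JSON) the configuration for [run_pipeline()]: a
#' [sim_config()] block, stage toggles, and the numeric options of each
#' stage. CLI-style overrides win over file values.
#'
#' @param outdir output directory.
#' @param sim list of [sim_config()] overrides (e.g. `list(seed = 7)`).
#' @param stages character subset of
#'   `c("simulate","growth","generations","mutbias","periodicity","enrich")`.
#' @param cv_max,bin_bp,smooth_bp,reps,min_label_size stage options.
#' @param seed master seed (also fed to the sim block unless overridden).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "evokit_out",
                            sim = list(),
                            stages = c("simulate", "growth", "generations",
                                       "mutbias", "periodicity", "enrich"),
                            cv_max = 0.2, bin_bp = 1000, smooth_bp = 100000,
                            reps = 1000, min_label_size = 15, seed = 1L) {
  known <- c("simulate", "growth", "generations", "mutbias", "periodicity",
             "enrich")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(sim$seed)) sim$seed <- seed
  structure(list(outdir = outdir, sim = do.call(sim_config, sim),
                 stages = stages, cv_max = cv_max, bin_bp = bin_bp,
                 smooth_bp = smooth_bp, reps = reps,
                 min_label_size = min_label_size, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with any subset of the fields above (`sim` as an
#'   object).
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- js[intersect(names(js), names(formals(pipeline_config)))]
  if (!is.null(args$sim)) args$sim <- as.list(args$sim)
  do.call(pipeline_config, args)
}

#' Run the end-to-end replay pipeline
#'
#' Executes the enabled stages in order on synthetic inputs: simulate writes
#' the input files; growth estimates rates from the plate CSV; generations
#' accumulates the transfer log; mutbias runs the scar-distance randomization
#' test; periodicity fits the chromosomal expression wave; enrich tests the
#' mutated genes against the category and regulon annotation. A manifest
#' (seeds, options, per-stage outputs with md5 hashes) is written to
#' `manifest.json`; identical configs produce identical manifests.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[evokit] ", ...)
  outputs <- character(0)
  run_stage <- function(name, fn) {
    say("stage ", name)
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", function() simulate_inputs(cfg$sim, cfg$outdir))
    outputs <- c(outputs, "layout/genome.txt", "layout/scars.bed",
                 "layout/genes.tsv", "mutations.tsv", "plate.csv",
                 "transfers.tsv", "expression.tsv")
  }

  if ("growth" %in% cfg$stages) {
    run_stage("growth", function() {
      curves <- read_plate_csv(file.path(cfg$outdir, "plate.csv"))
      est <- do.call(rbind, lapply(curves, function(cv) {
        e <- estimate_growth(cv, cv_max = cfg$cv_max)
        data.frame(replicate = e$replicate, lineage = e$lineage,
                   rate = e$rate, window_start = e$rate_window[1],
                   carrying_capacity = e$carrying_capacity,
                   stringsAsFactors = FALSE)
      }))
      utils::write.table(est, file.path(cfg$outdir, "rates.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
    outputs <- c(outputs, "rates.tsv")
  }

  if ("generations" %in% cfg$stages) {
    run_stage("generations", function() {
      tl <- read_transfer_log(file.path(cfg$outdir, "transfers.tsv"))
      gen <- generations(tl)
      utils::write.table(gen, file.path(cfg$outdir, "generations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    outputs <- c(outputs, "generations.tsv")
  }

  if ("mutbias" %in% cfg$stages) {
    run_stage("mutbias", function() {
      layout <- read_genome_layout(file.path(cfg$outdir, "layout"))
      muts <- read_mutations(file.path(cfg$outdir, "mutations.tsv"))
      rr <- randomization_test(muts, layout, n_replicates = cfg$reps,
                               seed = cfg$seed)
      jsonlite::write_json(
        list(mu_p = rr$mu_p, ci95 = rr$ci95, n_replicates = rr$n_replicates,
             seed = rr$seed, sidedness = rr$sidedness, verdict = rr$verdict),
        file.path(cfg$outdir, "randomization.json"),
        auto_unbox = TRUE, digits = NA)
      hist_tab <- as.data.frame(table(cut(rr$p_values,
                                          breaks = seq(0, 1, 0.05))),
                                stringsAsFactors = FALSE)
      names(hist_tab) <- c("p_bin", "count")
      utils::write.table(hist_tab, file.path(cfg$outdir, "p_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    outputs <- c(outputs, "randomization.json", "p_histogram.tsv")
  }

  if ("periodicity" %in% cfg$stages) {
    run_stage("periodicity", function() {
      profs <- read_expression_profiles(file.path(cfg$outdir,
                                                  "expression.tsv"))
      muts <- if (file.exists(file.path(cfg$outdir, "mutations.tsv")))
        read_mutations(file.path(cfg$outdir, "mutations.tsv")) else NULL
      fit <- periodicity_pipeline(profs[[1]], bin_bp = cfg$bin_bp,
                                  smooth_bp = cfg$smooth_bp,
                                  mutations = muts)
      jsonlite::write_json(
        list(sample_id = fit$sample_id, T = fit$T,
             period_count = fit$period_count, a = fit$a, b = fit$b,
             c = fit$c, g = fit$g, p_g = fit$p_g, g_on = fit$g_on,
             sse = fit$sse),
        file.path(cfg$outdir, "periodicity.json"),
        auto_unbox = TRUE, digits = NA)
      utils::write.table(fit$track, file.path(cfg$outdir, "track.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    outputs <- c(outputs, "periodicity.json", "track.tsv")
  }

  if ("enrich" %in% cfg$stages) {
    run_stage("enrich", function() {
      layout <- read_genome_layout(file.path(cfg$outdir, "layout"))
      muts <- read_mutations(file.path(cfg$outdir, "mutations.tsv"))
      query <- unique(stats::na.omit(muts$gene))
      g <- layout$genes
      annot <- annotation_map(g$gene_id,
                              split(g$gene_id, g$category))
      res <- binomial_enrichment(query, annot,
                                 min_label_size = cfg$min_label_size)
      utils::write.table(as.data.frame(res),
                         file.path(cfg$outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    outputs <- c(outputs, "enrichment.tsv")
  }

  paths <- file.path(cfg$outdir, outputs)
  manifest <- list(
    package = "evokit",
    version = as.character(utils::packageVersion("evokit")),
    seed = cfg$seed,
    stages = cfg$stages,
    options = list(cv_max = cfg$cv_max, bin_bp = cfg$bin_bp,
                   smooth_bp = cfg$smooth_bp, reps = cfg$reps,
                   min_label_size = cfg$min_label_size),
    outputs = if (length(outputs) > 0)
      stats::setNames(as.list(unname(tools::md5sum(paths))), outputs)
    else stats::setNames(list(), character(0))
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", length(outputs), " outputs in ", cfg$outdir)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Dispatches `evokit <subcommand> [--key value ...]`. Subcommands: simulate,
#' growth, generations, mutbias, periodicity, enrich, replay. Every
#' subcommand accepts `--seed`; `replay` runs the whole pipeline from a JSON
#' config (`--config`) or defaults.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly (0 on success).
#' @export
evokit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: evokit <simulate|growth|generations|mutbias|periodicity|",
        "enrich|replay> [--key value ...]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_opts(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  quiet <- isTRUE(as.logical(opt$quiet %||% FALSE))
  outdir <- opt$outdir %||% "evokit_out"
  switch(cmd,
    simulate = {
      cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)$sim
             else sim_config(seed = seed)
      simulate_inputs(cfg, outdir)
    },
    growth = {
      curves <- read_plate_csv(opt$od)
      est <- do.call(rbind, lapply(curves, function(cv) {
        e <- estimate_growth(cv, cv_max = as.numeric(opt$cv_max %||% 0.2))
        data.frame(replicate = e$replicate, lineage = e$lineage,
                   rate = e$rate, carrying_capacity = e$carrying_capacity)
      }))
      utils::write.table(est, opt$out %||% "rates.tsv", sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    generations = {
      gen <- generations(read_transfer_log(opt$log))
      utils::write.table(gen, opt$out %||% "generations.tsv", sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    mutbias = {
      layout <- read_genome_layout(opt$genome)
      muts <- read_mutations(opt$mutations)
      rr <- randomization_test(muts, layout,
                               n_replicates = as.integer(opt$reps %||% 1000),
                               seed = seed,
                               linear = isTRUE(as.logical(opt$linear %||% FALSE)))
      jsonlite::write_json(list(mu_p = rr$mu_p, ci95 = rr$ci95,
                                n_replicates = rr$n_replicates, seed = seed,
                                verdict = rr$verdict),
                           opt$out %||% "randomization.json",
                           auto_unbox = TRUE, digits = NA)
    },
    periodicity = {
      profs <- read_expression_profiles(opt$expr)
      fit <- periodicity_pipeline(profs[[1]],
                                  bin_bp = as.numeric(opt$bin %||% 1000),
                                  smooth_bp = as.numeric(opt$smooth %||% 1e5))
      jsonlite::write_json(list(T = fit$T, period_count = fit$period_count,
                                a = fit$a, b = fit$b, c = fit$c, g = fit$g,
                                p_g = fit$p_g, g_on = fit$g_on),
                           opt$out %||% "periodicity.json",
                           auto_unbox = TRUE, digits = NA)
    },
    enrich = {
      query <- readLines(opt$query)
      maps <- read_annotations(opt$annot)
      scheme <- opt$scheme %||% names(maps)[1]
      res <- binomial_enrichment(query, maps[[scheme]],
                                 min_label_size =
                                   as.integer(opt$min_label_size %||% 15))
      utils::write.table(as.data.frame(res), opt$out %||% "enrichment.tsv",
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    replay = {
      cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
             else pipeline_config(outdir = outdir, seed = seed)
      run_pipeline(cfg, quiet = quiet)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}

# minimal --key value / --flag parser
parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      opt[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opt[[key]] <- TRUE
      i <- i + 1
    }
  }
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
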
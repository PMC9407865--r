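# End-to-end orchestration: simulate -> discover -> annotate -> popgen ->
# assoc -> expr as one reproducible run with a JSON config, a log, and a
# checksum manifest.

#' Run the full RIP pipeline from a JSON config
#'
#' Executes the requested stages in dependency order under `outdir`, writing
#' each stage's TSV outputs, a plain-text log with stage timings, and
#' `manifest.json` recording the config hash, seed, and input/output
#' checksums per stage. On a rerun, stages whose inputs and outputs are
#' unchanged (by checksum) are skipped. Config schema violations are
#' reported before any stage runs; a stage failure aborts with the failing
#' stage named.
#'
#' Config fields: `seed` (required), `outdir` (may be overridden by the
#' `outdir` argument), `stages` (default all of `simulate`, `discover`,
#' `annotate`, `popgen`, `assoc`, `expr`), plus optional per-stage parameter
#' blocks `sim`, `discover`, `annotate`, `assoc` (`trait`, `adjust_c`),
#' `expr` (`calibrator`, `control`). When `simulate` is not among the stages,
#' `bait`, `assemblies`, `library` and `gene_model` paths are required for
#' `discover`/`annotate`, and the table stages read `genotypes`,
#' `phenotypes`, `ct` and `luciferase` paths from the config.
#'
#' @param config Path to a JSON config file, or an equivalent named list.
#' @param outdir Output directory (overrides the config's `outdir`).
#' @return A `run_manifest` (invisibly): config hash, seed, and per-stage
#'   file checksums, parameters and timings.
#' @export
run_all <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) {
    jsonlite::fromJSON(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else config
  # ---- pre-flight schema validation (before any stage runs)
  if (is.null(cfg$seed)) stop("run_all: config error: 'seed' is required")
  stages <- cfg$stages %||% c("simulate", "discover", "annotate", "popgen",
                              "assoc", "expr")
  known <- c("simulate", "discover", "annotate", "popgen", "assoc", "expr")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("run_all: config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  outdir <- outdir %||% cfg$outdir
  if (is.null(outdir)) stop("run_all: config error: no 'outdir'")
  if (!"simulate" %in% stages) {
    if (any(c("discover", "annotate") %in% stages) &&
        (is.null(cfg$bait) || is.null(cfg$assemblies))) {
      stop("run_all: config error: 'bait' and 'assemblies' paths required ",
           "when 'discover' runs without 'simulate'")
    }
    if ("annotate" %in% stages &&
        (is.null(cfg$library) || is.null(cfg$gene_model))) {
      stop("run_all: config error: 'library' and 'gene_model' paths required ",
           "when 'annotate' runs without 'simulate'")
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  manifest_path <- file.path(outdir, "manifest.json")
  old <- read_manifest(manifest_path)
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    cat(msg, "\n", sep = "", file = logfile, append = TRUE)
    message(msg)
  }
  config_hash <- substr(jsonlite::base64_enc(serialize(cfg, NULL)), 1, 24)
  seed <- as.integer(cfg$seed)
  simcfg <- do.call(sim_config, c(list(seed = seed), cfg$sim %||% list()))
  dparams <- do.call(discovery_params, as.list(cfg$discover %||% list()))
  aparams <- do.call(annotation_params, as.list(cfg$annotate %||% list()))
  p <- function(f) file.path(outdir, f)
  files <- list(
    simulate = list(inputs = character(),
                    outputs = p(c("bait.fa", "assemblies.fa", "library.fa",
                                  "gene_model.tsv", "truth.tsv", "genotypes.tsv",
                                  "phenotypes.tsv", "ct.tsv", "luciferase.tsv"))),
    discover = list(inputs = c(cfg$bait %||% p("bait.fa"),
                               cfg$assemblies %||% p("assemblies.fa")),
                    outputs = p("candidates.tsv")),
    annotate = list(inputs = c(cfg$bait %||% p("bait.fa"),
                               p("candidates.tsv"),
                               cfg$library %||% p("library.fa"),
                               cfg$gene_model %||% p("gene_model.tsv")),
                    outputs = p(c("rips.tsv", "rips.bed", "rips.vcf"))),
    popgen = list(inputs = cfg$genotypes %||% p("genotypes.tsv"),
                  outputs = p("popgen.tsv")),
    assoc = list(inputs = cfg$phenotypes %||% p("phenotypes.tsv"),
                 outputs = p("assoc.tsv")),
    expr = list(inputs = c(cfg$ct %||% p("ct.tsv"),
                           cfg$luciferase %||% p("luciferase.tsv")),
                outputs = p(c("expr.tsv", "luc.tsv"))))
  runners <- list(
    simulate = function() simulate_all(simcfg, outdir),
    discover = function() {
      bait <- read_fasta(files$discover$inputs[1])[[1]]
      assemblies <- read_fasta(files$discover$inputs[2])
      svs <- discover_rips(bait, assemblies, dparams)
      write_tsv(do.call(rbind, c(list(data.frame(
        sv_type = character(), bait_pos = integer(), length = integer(),
        n_sources = integer(), sources = character(), seq = character())),
        lapply(svs, function(s) data.frame(
          sv_type = s$sv_type, bait_pos = s$bait_pos + 1L, length = s$length,
          n_sources = length(s$sources),
          sources = paste(s$sources, collapse = ","), seq = s$seq)))),
        files$discover$outputs[1])
    },
    annotate = function() {
      bait <- read_fasta(files$annotate$inputs[1])[[1]]
      cand <- read_tsv_strict(files$annotate$inputs[2],
                              c("sv_type", "bait_pos", "length", "sources", "seq"))
      libseqs <- read_fasta(files$annotate$inputs[3])
      lib <- lapply(libseqs, function(s) {
        repeat_consensus(s$name, guess_repeat_class(s$name), s$seq)
      })
      model <- read_gene_model(files$annotate$inputs[4])
      svs <- lapply(seq_len(nrow(cand)), function(i) {
        candidate_sv(cand$sv_type[i], cand$bait_pos[i] - 1L, cand$seq[i],
                     sources = strsplit(cand$sources[i], ",")[[1]])
      })
      rips <- annotate_rips(svs, lib, model, bait, aparams)
      write_rip_table(rips, files$annotate$outputs[1],
                      bed = files$annotate$outputs[2],
                      vcf = files$annotate$outputs[3])
    },
    popgen = function() {
      write_tsv(as.data.frame(popgen_table(
        read_genotype_counts(files$popgen$inputs[1]))),
        files$popgen$outputs[1])
    },
    assoc = function() {
      ph <- read_tsv_strict(files$assoc$inputs[1], "genotype")
      traits <- cfg$assoc$trait %||%
        setdiff(names(ph), c("animal_id", "genotype"))
      rows <- do.call(rbind, lapply(traits, function(tr) {
        res <- anova_tukey(ph, tr)
        st <- summary_table(res)
        data.frame(trait = tr, group = st$group, n = st$n, value = st$value,
                   F = res$F, anova_p = res$p)
      }))
      write_tsv(rows, files$assoc$outputs[1])
    },
    expr = function() {
      ct <- read_tsv_strict(files$expr$inputs[1],
                            c("group", "ct_target", "ct_reference"))
      ex <- ddct(ct, cfg$expr$calibrator %||% ct$group[1])
      write_tsv(ex$groups, files$expr$outputs[1])
      luc <- read_tsv_strict(files$expr$inputs[2],
                             c("construct", "firefly", "renilla"))
      lr <- luciferase_relative(luc, cfg$expr$control %||% luc$construct[1])
      write_tsv(lr$groups, files$expr$outputs[2])
    })
  manifest <- list(config_hash = config_hash, seed = seed,
                   tool = paste0("ripkit ", as.character(utils::packageVersion("ripkit"))),
                   stages = list())
  for (st in known) {
    if (!st %in% stages) next
    fi <- files[[st]]
    if (can_skip(old, st, config_hash, fi)) {
      logline("stage ", st, ": unchanged, skipped")
      entry <- old$stages[[st]]
      entry$skipped <- TRUE
      manifest$stages[[st]] <- entry
      next
    }
    t0 <- Sys.time()
    ok <- tryCatch({ runners[[st]](); TRUE }, error = function(e) {
      logline("stage ", st, " FAILED: ", conditionMessage(e))
      stop("run_all: stage '", st, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[st]] <- list(
      inputs = checksums(fi$inputs), outputs = checksums(fi$outputs),
      params = stage_params(st, simcfg, dparams, aparams, cfg),
      elapsed_sec = round(el, 3), skipped = FALSE)
    logline(sprintf("stage %s: done in %.2fs", st, el))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(structure(manifest, class = "run_manifest"))
}

guess_repeat_class <- function(name) {
  up <- toupper(name)
  if (grepl("LINE|^L1", up)) "LINE" else if (grepl("ERV|LTR", up)) "ERV" else "SINE"
}

checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
}

read_manifest <- function(path) {
  if (!file.exists(path)) return(NULL)
  tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
           error = function(e) NULL)
}

can_skip <- function(old, stage, config_hash, fi) {
  if (is.null(old) || !identical(old$config_hash, config_hash)) return(FALSE)
  entry <- old$stages[[stage]]
  if (is.null(entry)) return(FALSE)
  cur_in <- checksums(fi$inputs)
  cur_out <- checksums(fi$outputs)
  identical(lapply(entry$inputs, identity), lapply(cur_in, identity)) &&
    length(cur_out) == length(fi$outputs) &&
    identical(lapply(entry$outputs, identity), lapply(cur_out, identity))
}

stage_params <- function(stage, simcfg, dparams, aparams, cfg) {
  switch(stage,
         simulate = list(seed = simcfg$seed, locus_len = simcfg$locus_len,
                         n_exons = simcfg$n_exons,
                         n_insertions = length(simcfg$insertions),
                         n_breeds = length(simcfg$breeds)),
         discover = unclass(dparams),
         annotate = unclass(aparams),
         popgen = list(),
         assoc = list(trait = cfg$assoc$trait %||% "all"),
         expr = list(calibrator = cfg$expr$calibrator %||% "first group",
                     control = cfg$expr$control %||% "first construct"),
         list())
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, %d stage(s)\n", x$seed,
              length(x$stages)))
  for (st in names(x$stages)) {
    e <- x$stages[[st]]
    cat(sprintf("  %-9s %s (%d output file(s))\n", st,
                if (isTRUE(e$skipped)) "skipped" else
                  sprintf("%.2fs", e$elapsed_sec %||% NA_real_),
                length(e$outputs)))
  }
  invisible(x)
}
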
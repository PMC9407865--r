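# Synthetic-data generator: fabricates every input the pipeline consumes,
# with the statistical structure the downstream stages are designed to detect.
#
# All generators are pure functions of (config, seed): a single root seed is
# split into per-stage substreams so individual stages can be regenerated
# independently, and the caller's RNG state is never disturbed.

#' Simulation configuration
#'
#' Builds the configuration consumed by the `make_*` generators. The defaults
#' are the packaged fixture: a 15-kb locus carrying a 22-exon gene and three
#' SINE-like insertions of 286, 301 and 321 bp (strands -/+/+) in introns 1, 2
#' and 21, each with a 12-bp target site duplication and 2% per-copy
#' divergence, segregating across six simulated breed assemblies with a 1%
#' background SNP rate; breed genotype-count populations, per-genotype Gaussian
#' traits, qPCR Ct tables and luciferase readings mirror the bundled study
#' structure.
#'
#' @param seed Root seed; every stage derives its own substream from it.
#' @param locus_len Bait locus length (bp).
#' @param n_exons,exon_len,intron_len,gene_start,gene_name,gene_strand Gene
#'   model layout on the locus.
#' @param insertions List of insertion specs: `consensus` (name), `length`
#'   (consensus bp), `class`, `strand`, `tsd_len`, `divergence` (per-copy
#'   substitution rate in `[0, 0.2]`) and either `intron` (1-based intron index
#'   in transcription order) or `breakpoint` (0-based between-base offset).
#' @param breeds List of breed specs: `name`, `carries` (integer indices into
#'   `insertions`), `snp_rate`, `indel_rate` (small indels < 50 bp).
#' @param populations Data frame with `breed`, `locus`, `N`, `p_ins`, `f`
#'   (inbreeding coefficient).
#' @param phenotypes List with `n` (per-genotype counts) and `traits`, a named
#'   list of `list(mean = c(ii, id, dd), sd = c(...))`; defaults reproduce the
#'   bundled growth-trait structure with SD = SEM * sqrt(n).
#' @param expression List: `groups`, `fold` (true fold change per group,
#'   calibrator first), `n_per_group`, `ct_sd`, `ref_ct_mean`, `ref_ct_sd`,
#'   `base_dct`.
#' @param luciferase List: `constructs`, `mean_ratio`, `cv`, `n_wells`,
#'   `renilla_mean`, `cell_lines`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 20220810,
                       locus_len = 15000,
                       n_exons = 22,
                       exon_len = 120,
                       intron_len = 400,
                       gene_start = 2200,
                       gene_name = "simgene",
                       gene_strand = "+",
                       insertions = NULL,
                       breeds = NULL,
                       populations = NULL,
                       phenotypes = NULL,
                       expression = NULL,
                       luciferase = NULL) {
  if (is.null(insertions)) {
    insertions <- list(
      list(consensus = "SINEA1_286", length = 286L, class = "SINE",
           strand = "-", intron = 1L, tsd_len = 12L, divergence = 0.02),
      list(consensus = "SINEA1_301", length = 301L, class = "SINE",
           strand = "+", intron = 2L, tsd_len = 12L, divergence = 0.02),
      list(consensus = "SINEA1_321", length = 321L, class = "SINE",
           strand = "+", intron = 21L, tsd_len = 12L, divergence = 0.02))
  }
  if (is.null(breeds)) {
    breeds <- list(
      list(name = "Landrace",  carries = c(1L, 3L), snp_rate = 0.01, indel_rate = 5e-5),
      list(name = "Yorkshire", carries = 2L,        snp_rate = 0.01, indel_rate = 5e-5),
      list(name = "Meishan",   carries = c(1L, 2L), snp_rate = 0.01, indel_rate = 5e-5),
      list(name = "Rongchang", carries = 3L,        snp_rate = 0.01, indel_rate = 5e-5),
      list(name = "Jinhua",    carries = 1L,        snp_rate = 0.01, indel_rate = 5e-5),
      list(name = "Wuzhishan", carries = c(2L, 3L), snp_rate = 0.01, indel_rate = 5e-5))
  }
  if (is.null(populations)) populations <- default_population_specs()
  if (is.null(phenotypes)) {
    phenotypes <- list(
      n = c(63L, 297L, 90L),
      traits = list(
        body_weight   = list(mean = c(99.23, 105.10, 104.04),
                             sd = c(1.26, 0.66, 1.20) * sqrt(c(63, 297, 90))),
        backfat       = list(mean = c(11.17, 11.53, 11.64),
                             sd = c(0.37, 0.18, 0.34) * sqrt(c(63, 297, 90))),
        age_100kg     = list(mean = c(164.81, 160.49, 160.59),
                             sd = c(1.12, 0.59, 1.08) * sqrt(c(63, 297, 90))),
        backfat_100kg = list(mean = c(11.20, 11.02, 11.22),
                             sd = c(0.32, 0.15, 0.30) * sqrt(c(63, 297, 90)))))
  }
  if (is.null(expression)) {
    expression <- list(groups = c("+/+", "+/-", "-/-"),
                       fold = c(1, 1.2, 2.5), n_per_group = 4L,
                       ct_sd = 0.2, ref_ct_mean = 18, ref_ct_sd = 0.5,
                       base_dct = 5)
  }
  if (is.null(luciferase)) {
    luciferase <- list(constructs = c("pGL3-basic", "SINE-", "SINE+"),
                       mean_ratio = c(1, 4, 2), cv = 0.1, n_wells = 6L,
                       renilla_mean = 1e5, cell_lines = c("PK15", "3T3-L1"))
  }
  cfg <- list(seed = as.integer(seed), locus_len = as.integer(locus_len),
              n_exons = as.integer(n_exons), exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              gene_start = as.integer(gene_start), gene_name = gene_name,
              gene_strand = gene_strand, insertions = insertions,
              breeds = breeds, populations = populations,
              phenotypes = phenotypes, expression = expression,
              luciferase = luciferase)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (ins in cfg$insertions) {
    if (!is.null(ins$divergence) &&
        (ins$divergence < 0 || ins$divergence > 0.2)) {
      stop("sim_config: divergence must be in [0, 0.2]")
    }
    if (is.null(ins$intron) && is.null(ins$breakpoint)) {
      stop("sim_config: insertion needs an 'intron' or a 'breakpoint'")
    }
  }
  for (b in cfg$breeds) {
    if (b$snp_rate < 0 || b$snp_rate > 1 || b$indel_rate < 0 || b$indel_rate > 1) {
      stop("sim_config: rates must be probabilities")
    }
  }
  p <- cfg$populations
  if (nrow(p) > 0) {
    if (any(p$N < 1)) stop("sim_config: population N must be >= 1")
    if (any(p$p_ins < 0 | p$p_ins > 1)) stop("sim_config: p_ins must be in [0, 1]")
    if (any(p$f < -1 | p$f > 1)) stop("sim_config: F must be in [-1, 1]")
  }
  invisible(cfg)
}

# Population specs (p, F) back-computed from the bundled per-breed genotype
# counts so simulated populations reproduce the observed genotype structure.
default_population_specs <- function() {
  d <- rip_genotype_counts()
  n <- d$n_ins_ins + d$n_ins_del + d$n_del_del
  p <- (2 * d$n_ins_ins + d$n_ins_del) / (2 * n)
  hexp <- 2 * p * (1 - p)
  f <- ifelse(hexp > 0, 1 - (d$n_ins_del / n) / hexp, 0)
  data.frame(breed = d$breed, locus = d$locus, N = n, p_ins = p,
             f = pmin(1, pmax(-1, f)))
}

#' Simulate the bait locus, gene model and repeat consensus library
#'
#' @param cfg A [sim_config()].
#' @return List with `bait` ([locus_sequence()]), `model` ([gene_model()]),
#'   `library` (list of [repeat_consensus()]) and `breakpoints` (resolved
#'   0-based between-base insertion offsets, one per insertion spec).
#' @export
make_locus <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(substream_seed(cfg$seed, "locus"), {
    bait <- locus_sequence("bait", random_dna(cfg$locus_len), breed = "reference")
    starts <- cfg$gene_start + (seq_len(cfg$n_exons) - 1L) *
      (cfg$exon_len + cfg$intron_len)
    ex <- cbind(starts, starts + cfg$exon_len - 1L)
    if (ex[nrow(ex), 2] > cfg$locus_len) {
      stop("make_locus: gene model does not fit in the locus")
    }
    model <- gene_model(cfg$gene_name, ex, strand = cfg$gene_strand)
    lib <- list()
    for (ins in cfg$insertions) {
      if (is.null(lib[[ins$consensus]])) {
        lib[[ins$consensus]] <- repeat_consensus(
          ins$consensus, ins$class %||% "SINE", random_dna(ins$length))
      }
    }
    bps <- vapply(cfg$insertions, resolve_breakpoint, 0L, model = model,
                  locus_len = cfg$locus_len)
    list(bait = bait, model = model, library = unname(lib),
         breakpoints = bps)
  })
}

# breakpoint of an insertion spec: explicit offset, or an intron midpoint
resolve_breakpoint <- function(ins, model, locus_len) {
  if (!is.null(ins$breakpoint)) {
    bp <- as.integer(ins$breakpoint)
    if (bp < 0 || bp > locus_len) stop("breakpoint outside locus")
    return(bp)
  }
  k <- nrow(model$exons)
  if (k < 2) stop("make_locus: gene has no introns for an intronic insertion")
  i <- as.integer(ins$intron) # transcription order
  if (model$strand == "-") i <- k - i
  if (i < 1 || i > k - 1) stop("make_locus: no such intron: ", ins$intron)
  bp <- (model$exons[i, 2] + model$exons[i + 1, 1] - 1L) %/% 2L
  as.integer(bp)
}

#' Simulate breed assembly sequences with planted insertions
#'
#' Carrier breeds receive the consensus (reverse-complemented for strand
#' `"-"`), flanked by a duplicated target site of `tsd_len` bases, with
#' per-copy substitution divergence applied to the element. Background SNPs
#' and small indels (< 50 bp) at the breed-specific rates are applied to the
#' shared bait backbone only: the planted element and its target site
#' duplication are recent sequence and carry only the per-copy divergence
#' process. Element junction bases that happen to equal the flanking bait base
#' are resampled so the left-normalised planted coordinates are unambiguous
#' ground truth.
#'
#' @param bait Bait [locus_sequence()].
#' @param model Gene model (used only for the truth table's feature labels).
#' @param library List of [repeat_consensus()].
#' @param cfg A [sim_config()].
#' @return List with `assemblies` (list of [locus_sequence()], one per breed)
#'   and `truth` (data frame of planted insertions: breed, rip index,
#'   consensus, strand, bait-frame breakpoint, element length, TSD).
#' @export
make_assemblies <- function(bait, model, library, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  libmap <- stats::setNames(library, vapply(library, `[[`, "", "name"))
  bps <- vapply(cfg$insertions, resolve_breakpoint, 0L, model = model,
                locus_len = nchar(bait$seq))
  assemblies <- list()
  truth <- list()
  for (b in cfg$breeds) {
    res <- with_seed(substream_seed(cfg$seed, paste0("assembly:", b$name)), {
      build_assembly(bait, model, libmap, cfg$insertions, bps, b)
    })
    assemblies[[b$name]] <- res$seq
    truth[[b$name]] <- res$truth
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(assemblies = unname(assemblies), truth = truth)
}

build_assembly <- function(bait, model, libmap, insertions, bps, breed_spec) {
  bvec <- strsplit(bait$seq, "")[[1]]
  n <- length(bvec)
  carried <- sort(intersect(as.integer(breed_spec$carries %||% integer()),
                            seq_along(insertions)))
  # assemble alternating backbone / planted pieces, left to right
  pieces <- list()      # character vectors
  mutable <- logical()  # background mutation applies?
  cursor <- 1L
  truth <- list()
  for (i in carried) {
    ins <- insertions[[i]]
    bp <- bps[i]
    t <- as.integer(ins$tsd_len %||% 12L)
    if (bp - t < 0 || bp + t > n) stop("make_assemblies: TSD window outside locus")
    cons <- libmap[[ins$consensus]]
    if (is.null(cons)) stop("make_assemblies: consensus not in library: ", ins$consensus)
    elem <- if (identical(ins$strand, "-")) revcomp(cons$seq) else cons$seq
    ev <- strsplit(elem, "")[[1]]
    d <- ins$divergence %||% 0.02
    if (d > 0) {
      hit <- which(stats::runif(length(ev)) < d)
      for (h in hit) ev[h] <- sample(setdiff(DNA_BASES, ev[h]), 1)
    }
    tsd <- bvec[seq_len(t) + bp] # target site: the t bases after the breakpoint
    # junction disambiguation: planted coordinates must be the unique
    # left-normalised representation
    after <- bvec[bp + t + 1L] # first backbone base after the target site
    if (!is.na(after) && ev[1] == after) {
      ev[1] <- sample(setdiff(DNA_BASES, after), 1)
    }
    before <- if (bp >= 1L) bvec[bp] else NA_character_
    if (!is.na(before) && ev[length(ev)] == before) {
      ev[length(ev)] <- sample(setdiff(DNA_BASES, before), 1)
    }
    # backbone up to the breakpoint (mutable), then TSD copy 1 (immutable),
    # element, TSD copy 2 (immutable)
    if (bp >= cursor) {
      pieces <- c(pieces, list(bvec[cursor:bp])); mutable <- c(mutable, TRUE)
    }
    pieces <- c(pieces, list(tsd), list(ev), list(tsd))
    mutable <- c(mutable, FALSE, FALSE, FALSE)
    cursor <- bp + t + 1L
    truth[[length(truth) + 1L]] <- data.frame(
      breed = breed_spec$name, rip = i, consensus = cons$name,
      class = cons$class, strand = ins$strand %||% "+", bait_pos = bp,
      elem_len = length(ev), tsd = paste(tsd, collapse = ""), tsd_len = t,
      feature = label_feature(bp, model))
  }
  if (cursor <= n) {
    pieces <- c(pieces, list(bvec[cursor:n])); mutable <- c(mutable, TRUE)
  }
  out <- lapply(seq_along(pieces), function(j) {
    if (mutable[j]) {
      mutate_backbone(pieces[[j]], breed_spec$snp_rate, breed_spec$indel_rate)
    } else pieces[[j]]
  })
  seq <- locus_sequence(breed_spec$name, paste(unlist(out), collapse = ""),
                        breed = breed_spec$name)
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    breed = character(), rip = integer(), consensus = character(),
    class = character(), strand = character(), bait_pos = integer(),
    elem_len = integer(), tsd = character(), tsd_len = integer(),
    feature = character())
  list(seq = seq, truth = truth)
}

# background SNPs + small indels (capped at 49 bp so they never cross the
# large-SV threshold) on a backbone piece
mutate_backbone <- function(v, snp_rate, indel_rate) {
  m <- length(v)
  if (snp_rate > 0) {
    hit <- which(stats::runif(m) < snp_rate)
    for (h in hit) v[h] <- sample(setdiff(DNA_BASES, v[h]), 1)
  }
  if (indel_rate > 0) {
    hit <- which(stats::runif(m) < indel_rate)
    if (length(hit)) {
      out <- vector("list", 2L * length(hit) + 1L)
      prev <- 1L
      for (j in seq_along(hit)) {
        h <- hit[j]
        len <- min(49L, 1L + stats::rgeom(1, 1 / 6))
        out[[2L * j - 1L]] <- v[prev:h]
        if (stats::runif(1) < 0.5) { # insertion after position h
          out[[2L * j]] <- sample(DNA_BASES, len, replace = TRUE)
          prev <- h + 1L
        } else {                     # deletion of up to `len` following bases
          out[[2L * j]] <- character()
          prev <- min(m + 1L, h + 1L + len)
        }
      }
      out[[2L * length(hit) + 1L]] <- if (prev <= m) v[prev:m] else character()
      v <- unlist(out)
    }
  }
  v
}

#' Draw per-breed genotype counts from an inbreeding-adjusted trinomial
#'
#' Genotype probabilities are `P(+/+) = p^2 + Fpq`, `P(+/-) = 2pq(1 - F)`,
#' `P(-/-) = q^2 + Fpq` (clamped at zero and renormalised against rounding
#' error); `F` values implying negative probabilities are rejected.
#'
#' @param breed Breed label.
#' @param N Number of individuals.
#' @param p_ins Insertion allele frequency.
#' @param f Inbreeding coefficient in `[-1, 1]`.
#' @param seed Seed for the draw.
#' @return A [genotype_counts()].
#' @export
make_population <- function(breed, N, p_ins, f = 0, seed = 1L) {
  if (N < 1) stop("make_population: N must be >= 1")
  p <- p_ins; q <- 1 - p
  pr <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  if (any(pr < -1e-9)) {
    stop(sprintf("make_population: infeasible F = %.3f for p = %.3f", f, p))
  }
  pr <- pmax(pr, 0); pr <- pr / sum(pr)
  cnt <- with_seed(substream_seed(seed, paste0("population:", breed)),
                   as.integer(stats::rmultinom(1, N, pr)))
  genotype_counts(breed, cnt[1], cnt[2], cnt[3])
}

#' Simulate a genotype-phenotype table
#'
#' Gaussian trait values per genotype group.
#'
#' @param counts A [genotype_counts()] giving the group sizes, or an integer
#'   vector `c(n_ins_ins, n_ins_del, n_del_del)`.
#' @param traits Named list of `list(mean = c(ii, id, dd), sd = c(...))`; a
#'   scalar `sd` is recycled.
#' @param seed Seed.
#' @return Data frame with `animal_id`, `genotype` and one column per trait.
#' @export
make_phenotypes <- function(counts, traits, seed = 1L) {
  n <- if (inherits(counts, "genotype_counts")) {
    c(counts$n_ins_ins, counts$n_ins_del, counts$n_del_del)
  } else as.integer(counts)
  geno <- rep(c("+/+", "+/-", "-/-"), n)
  d <- data.frame(animal_id = sprintf("a%04d", seq_along(geno)),
                  genotype = geno, stringsAsFactors = FALSE)
  with_seed(substream_seed(seed, "phenotypes"), {
    for (tr in names(traits)) {
      sd <- rep_len(traits[[tr]]$sd, 3)
      if (any(sd < 0)) stop("make_phenotypes: negative SD")
      d[[tr]] <- unlist(lapply(1:3, function(g) {
        stats::rnorm(n[g], traits[[tr]]$mean[g], sd[g])
      }))
    }
    d
  })
}

#' Simulate a qPCR Ct table with a known group fold-change structure
#'
#' Reference-gene Ct values are Gaussian; target Ct is
#' `ct_reference + base_dct - log2(fold_group) + noise`, so each group's true
#' fold change relative to the first (calibrator) group is realised in
#' expectation on the `2^-ddCt` scale.
#'
#' @param spec List: `groups`, `fold` (per group; calibrator first, usually 1),
#'   `n_per_group`, `ct_sd`, `ref_ct_mean`, `ref_ct_sd`, `base_dct`.
#' @param seed Seed.
#' @return Data frame with `sample_id`, `group`, `ct_target`, `ct_reference`.
#' @export
make_ct_table <- function(spec, seed = 1L) {
  if (spec$ct_sd < 0) stop("make_ct_table: negative SD")
  with_seed(substream_seed(seed, "ct"), {
    rows <- lapply(seq_along(spec$groups), function(g) {
      n <- spec$n_per_group
      ref <- stats::rnorm(n, spec$ref_ct_mean, spec$ref_ct_sd)
      dct <- spec$base_dct - log2(spec$fold[g])
      data.frame(sample_id = sprintf("%s_%d", gsub("[^A-Za-z0-9]", "", spec$groups[g]), 1:n),
                 group = spec$groups[g], ct_target = ref + dct + stats::rnorm(n, 0, spec$ct_sd),
                 ct_reference = ref, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate dual-luciferase readings
#'
#' Renilla readings are lognormal around `renilla_mean`; firefly readings are
#' `renilla * mean_ratio * exp(noise)` with log-scale noise of magnitude `cv`,
#' so each construct's expected firefly/renilla ratio is `mean_ratio`.
#'
#' @param spec List: `constructs`, `mean_ratio` (per construct), `cv`,
#'   `n_wells`, `renilla_mean`, `cell_lines`.
#' @param seed Seed.
#' @return Data frame with `cell_line`, `construct`, `well`, `firefly`,
#'   `renilla`.
#' @export
make_luciferase <- function(spec, seed = 1L) {
  if (spec$cv < 0) stop("make_luciferase: negative CV")
  with_seed(substream_seed(seed, "luciferase"), {
    rows <- list()
    for (cl in spec$cell_lines %||% "cells") {
      for (i in seq_along(spec$constructs)) {
        n <- spec$n_wells
        ren <- spec$renilla_mean * exp(stats::rnorm(n, 0, 0.05))
        ratio <- spec$mean_ratio[i] * exp(stats::rnorm(n, 0, spec$cv))
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = cl, construct = spec$constructs[i], well = 1:n,
          firefly = ren * ratio, renilla = ren, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Run every generator and write the pipeline's input files
#'
#' Writes `bait.fa`, `assemblies.fa`, `library.fa`, `gene_model.tsv`,
#' `truth.tsv`, `genotypes.tsv`, `phenotypes.tsv`, `ct.tsv` and
#' `luciferase.tsv` under `outdir`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects (`bait`, `model`, `library`, `assemblies`, `truth`).
#' @export
simulate_all <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  loc <- make_locus(cfg)
  asm <- make_assemblies(loc$bait, loc$model, loc$library, cfg)
  paths <- list(
    bait = file.path(outdir, "bait.fa"),
    assemblies = file.path(outdir, "assemblies.fa"),
    library = file.path(outdir, "library.fa"),
    gene_model = file.path(outdir, "gene_model.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    genotypes = file.path(outdir, "genotypes.tsv"),
    phenotypes = file.path(outdir, "phenotypes.tsv"),
    ct = file.path(outdir, "ct.tsv"),
    luciferase = file.path(outdir, "luciferase.tsv"))
  write_fasta(loc$bait, paths$bait)
  write_fasta(asm$assemblies, paths$assemblies)
  libseqs <- lapply(loc$library, function(x) locus_sequence(x$name, x$seq))
  write_fasta(libseqs, paths$library)
  write_gene_model(loc$model, paths$gene_model)
  write_tsv(asm$truth, paths$truth)
  pops <- cfg$populations
  gen <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    gc <- make_population(pops$breed[i], pops$N[i], pops$p_ins[i], pops$f[i],
                          seed = substream_seed(cfg$seed, pops$locus[i]))
    data.frame(breed = gc$breed, locus = pops$locus[i],
               n_ins_ins = gc$n_ins_ins, n_ins_del = gc$n_ins_del,
               n_del_del = gc$n_del_del)
  }))
  write_tsv(gen, paths$genotypes)
  write_tsv(make_phenotypes(cfg$phenotypes$n, cfg$phenotypes$traits,
                            seed = cfg$seed), paths$phenotypes)
  write_tsv(make_ct_table(cfg$expression, seed = cfg$seed), paths$ct)
  write_tsv(make_luciferase(cfg$luciferase, seed = cfg$seed), paths$luciferase)
  invisible(list(paths = paths, bait = loc$bait, model = loc$model,
                 library = loc$library, assemblies = asm$assemblies,
                 truth = asm$truth))
}
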
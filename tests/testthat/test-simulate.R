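test_that("generators are pure functions of the config seed", {
  cfg <- clean_cfg(seed = 11, snp = 0.01, indel = 5e-5, divergence = 0.02)
  a <- make_locus(cfg); b <- make_locus(cfg)
  expect_identical(a$bait$seq, b$bait$seq)
  expect_identical(a$library[[1]]$seq, b$library[[1]]$seq)
  asm1 <- make_assemblies(a$bait, a$model, a$library, cfg)
  asm2 <- make_assemblies(a$bait, a$model, a$library, cfg)
  expect_identical(vapply(asm1$assemblies, `[[`, "", "seq"),
                   vapply(asm2$assemblies, `[[`, "", "seq"))
  expect_identical(asm1$truth, asm2$truth)

  # caller's RNG stream is not disturbed
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(make_locus(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("carriers gain exactly element + TSD bases; non-carriers match the bait", {
  cfg <- clean_cfg(seed = 5, tsd_len = 12L, divergence = 0, snp = 0, indel = 0)
  loc <- make_locus(cfg)
  asm <- make_assemblies(loc$bait, loc$model, loc$library, cfg)
  lens <- nchar(vapply(asm$assemblies, `[[`, "", "seq"))
  expect_equal(lens[[1]], nchar(loc$bait$seq) + 286L + 12L)
  expect_identical(asm$assemblies[[3]]$seq, loc$bait$seq)
  # the duplicated target site flanks the element
  tr <- asm$truth[1, ]
  carrier <- asm$assemblies[[1]]$seq
  expect_equal(substr(carrier, tr$bait_pos + 1, tr$bait_pos + 12), tr$tsd)
  expect_equal(substr(carrier, tr$bait_pos + 12 + tr$elem_len + 1,
                      tr$bait_pos + 12 + tr$elem_len + 12), tr$tsd)
})

test_that("minus-strand planting inserts the reverse complement of the consensus", {
  cfg <- clean_cfg(seed = 6, tsd_len = 0L, divergence = 0, strand = "-",
                   snp = 0, indel = 0)
  loc <- make_locus(cfg)
  asm <- make_assemblies(loc$bait, loc$model, loc$library, cfg)
  tr <- asm$truth[1, ]
  planted <- substr(asm$assemblies[[1]]$seq, tr$bait_pos + 1,
                    tr$bait_pos + tr$elem_len)
  want <- revcomp(loc$library[[1]]$seq)
  # junction bases may be resampled for ground-truth identifiability;
  # everything interior is the exact reverse complement
  expect_identical(substr(planted, 2, tr$elem_len - 1),
                   substr(want, 2, tr$elem_len - 1))
  mism <- sum(strsplit(planted, "")[[1]] != strsplit(want, "")[[1]])
  expect_lte(mism, 2)
})

test_that("population draws follow the inbreeding-adjusted trinomial", {
  gc <- make_population("b", 10L, 1, 0, seed = 1)
  expect_equal(gc$n_ins_ins, 10L)
  gc <- make_population("b", 400L, 0.5, 1, seed = 2)
  expect_equal(gc$n_ins_del, 0L)
  gc <- make_population("b", 1000000L, 0.47, 0, seed = 3)
  phat <- (2 * gc$n_ins_ins + gc$n_ins_del) / (2 * gc$total)
  expect_lt(abs(phat - 0.47), 0.002)
  het <- gc$n_ins_del / gc$total
  expect_lt(abs(het - 2 * 0.47 * 0.53), 0.002)
  expect_error(make_population("b", 10L, 0.9, -0.5, seed = 4), "infeasible")
})

test_that("phenotype, Ct and luciferase generators honour their specs", {
  tr <- list(age = list(mean = c(164.81, 160.49, 160.59), sd = 0))
  ph <- make_phenotypes(c(3L, 4L, 5L), tr, seed = 1)
  expect_equal(nrow(ph), 12L)
  expect_equal(as.numeric(tapply(ph$age, ph$genotype, mean)[c("+/+", "+/-", "-/-")]),
               c(164.81, 160.49, 160.59))
  expect_error(make_phenotypes(c(2L, 2L, 2L),
                               list(x = list(mean = 1:3, sd = -1)), seed = 1),
               "negative SD")

  spec <- list(groups = c("a", "b"), fold = c(1, 1), n_per_group = 5L,
               ct_sd = 0, ref_ct_mean = 20, ref_ct_sd = 0.4, base_dct = 4)
  ct <- make_ct_table(spec, seed = 2)
  res <- ddct(ct, "a")
  expect_equal(res$groups$mean_fold, c(1, 1))

  lspec <- list(constructs = c("ctrl", "test"), mean_ratio = c(1, 0.5),
                cv = 0, n_wells = 4L, renilla_mean = 1e5, cell_lines = "PK15")
  luc <- make_luciferase(lspec, seed = 3)
  expect_equal(luc$firefly / luc$renilla, rep(c(1, 0.5), each = 4))
})

test_that("single-exon genes reject intronic insertion specs", {
  expect_error(
    make_locus(sim_config(seed = 1, locus_len = 4000, n_exons = 1,
                          gene_start = 1000,
                          insertions = list(list(consensus = "S", length = 100L,
                                                 class = "SINE", strand = "+",
                                                 intron = 1L, tsd_len = 0L,
                                                 divergence = 0)))),
    "no introns")
})

test_that("planted truth is recovered end to end at study noise levels", {
  cfg <- sim_config(seed = 404)
  loc <- make_locus(cfg)
  asm <- make_assemblies(loc$bait, loc$model, loc$library, cfg)
  svs <- discover_rips(loc$bait, asm$assemblies)
  truth <- unique(asm$truth[, c("rip", "bait_pos", "elem_len", "tsd_len",
                                "consensus", "strand", "feature")])
  truth <- truth[order(truth$bait_pos), ]
  expect_equal(length(svs), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    expect_lte(abs(svs[[i]]$bait_pos - truth$bait_pos[i]), 5)
    expect_equal(svs[[i]]$length, truth$elem_len[i] + truth$tsd_len[i])
  }
  rips <- annotate_rips(svs, loc$library, loc$model, loc$bait)
  expect_equal(vapply(rips, `[[`, 0L, "length"), truth$elem_len)
  expect_equal(vapply(rips, `[[`, "", "family"), truth$consensus)
  expect_equal(vapply(rips, `[[`, "", "direction"), truth$strand)
  expect_equal(vapply(rips, `[[`, "", "feature_label"), truth$feature)
})
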
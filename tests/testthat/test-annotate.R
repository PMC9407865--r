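lib <- list(repeat_consensus("SINEA1", "SINE", random_seq(286, 81)),
            repeat_consensus("L1A", "LINE", random_seq(900, 82)))

test_that("perfect and reverse-complement copies classify with full scores", {
  sv <- candidate_sv("INS", 100L, lib[[1]]$seq, sources = "A")
  cls <- classify_insertion(sv, lib)
  expect_equal(cls[c("family", "class", "direction")],
               list(family = "SINEA1", class = "SINE", direction = "+"))
  expect_equal(cls$identity, 1)
  expect_equal(cls$insertion_coverage, 1)

  rc <- candidate_sv("INS", 100L, revcomp(lib[[1]]$seq), sources = "A")
  cls2 <- classify_insertion(rc, lib)
  expect_equal(cls2$direction, "-")
  expect_equal(cls2$identity, 1)
  expect_error(classify_insertion(sv, list()), "empty library")
})

test_that("random insertions stay unclassified at default thresholds", {
  for (s in 1:5) {
    sv <- candidate_sv("INS", 100L, random_seq(286, 8200 + s), sources = "A")
    cls <- classify_insertion(sv, lib)
    expect_equal(cls$family, "unclassified")
    expect_equal(cls$direction, ".")
    expect_equal(cls$class, "none")
  }
})

test_that("classification is antisymmetric under reverse complement", {
  for (s in 1:5) {
    mut <- mutate_seq(lib[[1]]$seq, 6, 830 + s)
    a <- classify_insertion(candidate_sv("INS", 1L, mut), lib)
    b <- classify_insertion(candidate_sv("INS", 1L, revcomp(mut)), lib)
    expect_equal(a$family, b$family)
    expect_equal(a$identity, b$identity)
    expect_equal(a$insertion_coverage, b$insertion_coverage)
    expect_true(a$direction != b$direction)
  }
})

test_that("mutating a perfect copy never increases identity", {
  for (s in 1:6) {
    k <- sample(1:20, 1)
    mut <- mutate_seq(lib[[1]]$seq, k, 840 + s)
    cls <- classify_insertion(candidate_sv("INS", 1L, mut), lib)
    expect_lte(cls$identity, 1)
    expect_lt(cls$identity, 1) # a substitution costs at least one column
  }
})

test_that("2%-diverged copies classify to the right family with high identity", {
  hits <- 0L
  for (s in 1:25) {
    mut <- mutate_seq(lib[[1]]$seq, rbinom(1, 286, 0.02), 860 + s)
    cls <- classify_insertion(candidate_sv("INS", 1L, mut), lib)
    if (cls$family == "SINEA1" && cls$identity >= 0.95) hits <- hits + 1L
  }
  expect_equal(hits, 25L)
})

test_that("planted TSDs are recovered exactly from simulated insertions", {
  cfg <- clean_cfg(seed = 55, tsd_len = 12L, divergence = 0.02, snp = 0, indel = 0)
  loc <- make_locus(cfg)
  asm <- make_assemblies(loc$bait, loc$model, loc$library, cfg)
  svs <- extract_svs(align_locus(loc$bait, asm$assemblies[[1]]))
  expect_length(svs, 1)
  expect_equal(detect_tsd(loc$bait, svs[[1]]), asm$truth$tsd[1])

  # no duplication present -> empty string
  cfg0 <- clean_cfg(seed = 55, tsd_len = 0L, divergence = 0, snp = 0, indel = 0)
  loc0 <- make_locus(cfg0)
  asm0 <- make_assemblies(loc0$bait, loc0$model, loc0$library, cfg0)
  svs0 <- extract_svs(align_locus(loc0$bait, asm0$assemblies[[1]]))
  expect_equal(detect_tsd(loc0$bait, svs0[[1]]), "")
})

test_that("exact duplications beat longer mismatched candidates", {
  # bait ...X [TSD] Y...; insert = TSD + element, crafted so a 13-mer with one
  # internal mismatch is also present
  tsd <- "ACGTTGCAAGGTC"
  bait <- locus_sequence("b", paste0(random_seq(200, 91), tsd, "AG",
                                     random_seq(200, 92)))
  # element begins "CG": a 15-mer duplication with one internal mismatch
  # (position 14, C vs A) exists, but the exact 13-mer must win
  elem <- paste0("CG", random_seq(80, 93))
  sv <- candidate_sv("INS", 200L, paste0(tsd, elem))
  got <- detect_tsd(bait, sv, annotation_params(tsd_max = 20L))
  expect_equal(got, tsd)
})

test_that("rip records assemble names, serials, spans and labels", {
  bait <- locus_sequence("bait", random_seq(2000, 94))
  model <- gene_model("LEPR", rbind(c(100, 200), c(500, 600), c(900, 1000)))
  cls <- list(family = "SINEA1", class = "SINE", direction = "+",
              identity = 0.98, insertion_coverage = 0.97)
  sv1 <- candidate_sv("INS", 300L, lib[[1]]$seq, sources = c("A", "B"))
  sv2 <- candidate_sv("INS", 700L, lib[[1]]$seq, sources = c("A", "C"))
  recs <- annotate_rips(list(sv1, sv2), lib, model, bait)
  expect_equal(vapply(recs, `[[`, "", "rip_name"),
               c("LEPR-SINE-RIP1", "LEPR-SINE-RIP2"))
  expect_equal(vapply(recs, `[[`, "", "feature_label"), c("Intron1", "Intron2"))
  # a gene's only RIP of a class carries no serial
  single <- annotate_rips(list(sv1), lib, model, bait)
  expect_equal(single[[1]]$rip_name, "LEPR-SINE-RIP")
  # unclassified insertions keep class "none" and direction "."
  un <- build_rip_record(candidate_sv("INS", 300L, random_seq(100, 95)),
                         list(family = "unclassified", class = "none",
                              direction = ".", identity = 0.4,
                              insertion_coverage = 0.5), "", model, bait)
  expect_equal(un$direction, ".")
  expect_match(un$rip_name, "-SV-RIP")
  # breakpoint span is the flanking 2-bp interval in the locus frame
  expect_equal(recs[[1]]$chrom_span, "bait:300-301")
})
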
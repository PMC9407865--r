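test_that("identical sequences align with no SV-sized gaps", {
  bait <- locus_sequence("bait", random_seq(6000, 21))
  q <- locus_sequence("q", bait$seq, breed = "q")
  chain <- align_locus(bait, q)
  expect_length(extract_svs(chain), 0)
})

test_that("a planted insertion is recovered with exact length and breakpoint", {
  cfg <- clean_cfg(seed = 31, tsd_len = 0L, divergence = 0, snp = 0, indel = 0)
  loc <- make_locus(cfg)
  asm <- make_assemblies(loc$bait, loc$model, loc$library, cfg)
  chain <- align_locus(loc$bait, asm$assemblies[[1]])
  svs <- extract_svs(chain)
  expect_length(svs, 1)
  expect_equal(svs[[1]]$sv_type, "INS")
  expect_equal(svs[[1]]$length, 286L)
  expect_equal(svs[[1]]$bait_pos, asm$truth$bait_pos[1])
  # with a TSD the raw SV grows by the duplicated word
  cfg2 <- clean_cfg(seed = 31, tsd_len = 12L, divergence = 0, snp = 0, indel = 0)
  loc2 <- make_locus(cfg2)
  asm2 <- make_assemblies(loc2$bait, loc2$model, loc2$library, cfg2)
  svs2 <- extract_svs(align_locus(loc2$bait, asm2$assemblies[[1]]))
  expect_equal(svs2[[1]]$length, 286L + 12L)
})

test_that("the SV length threshold is a sharp >= boundary", {
  bait <- locus_sequence("bait", random_seq(5000, 22))
  ins49 <- random_seq(49, 23); ins50 <- random_seq(50, 24)
  mk <- function(ins) locus_sequence("q", paste0(substr(bait$seq, 1, 2500),
                                                 ins,
                                                 substr(bait$seq, 2501, 5000)),
                                     breed = "q")
  expect_length(extract_svs(align_locus(bait, mk(ins49))), 0)
  svs <- extract_svs(align_locus(bait, mk(ins50)))
  expect_length(svs, 1)
  expect_equal(svs[[1]]$length, 50L)
})

test_that("deletions are called and bait/query swapping mirrors INS <-> DEL", {
  bait <- locus_sequence("bait", random_seq(6000, 25))
  del <- locus_sequence("q", paste0(substr(bait$seq, 1, 3000),
                                    substr(bait$seq, 3101, 6000)), breed = "q")
  svs <- extract_svs(align_locus(bait, del))
  expect_length(svs, 1)
  expect_equal(svs[[1]]$sv_type, "DEL")
  expect_equal(svs[[1]]$length, 100L)
  expect_equal(svs[[1]]$seq, substr(bait$seq, svs[[1]]$bait_pos + 1,
                                    svs[[1]]$bait_pos + 100))
  # swap roles: the deletion becomes an insertion of the same sequence
  swapped <- extract_svs(align_locus(del, locus_sequence("bait", bait$seq,
                                                         breed = "ref")))
  expect_length(swapped, 1)
  expect_equal(swapped[[1]]$sv_type, "INS")
  expect_equal(swapped[[1]]$length, 100L)
  expect_equal(swapped[[1]]$seq, svs[[1]]$seq)
})

test_that("raising min_sv_len never increases the number of reported SVs", {
  cfg <- sim_config(seed = 77)
  loc <- make_locus(cfg)
  asm <- make_assemblies(loc$bait, loc$model, loc$library, cfg)
  chain <- align_locus(loc$bait, asm$assemblies[[1]])
  counts <- vapply(c(10L, 50L, 120L, 300L, 400L), function(m) {
    length(extract_svs(chain, discovery_params(min_sv_len = m)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering matches a brute-force transitive-closure oracle", {
  params <- discovery_params(min_sources = 1L)
  set.seed(42)
  for (rep in 1:5) {
    true_pos <- sample(1000:9000, 4)
    true_len <- sample(c(120L, 286L, 800L, 1500L), 4)
    svs <- list()
    for (i in 1:4) {
      for (b in sample(LETTERS[1:6], sample(1:5, 1))) {
        svs[[length(svs) + 1L]] <- candidate_sv(
          "INS", true_pos[i] + sample(-8:8, 1),
          random_seq(true_len[i] + sample(-5:5, 1), length(svs) + rep * 100),
          sources = b)
      }
    }
    got <- cluster_svs(svs, params)
    # oracle: adjacency + boolean closure, then component count
    n <- length(svs)
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n) {
      a <- svs[[i]]; b <- svs[[j]]
      adj[i, j] <- a$sv_type == b$sv_type &&
        abs(a$bait_pos - b$bait_pos) <= params$cluster_pos_tol &&
        abs(a$length - b$length) <= params$cluster_len_tol * max(a$length, b$length)
    }
    repeat {
      nxt <- adj | (adj %*% adj > 0)
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    comp <- unique(apply(adj, 1, function(r) min(which(r))))
    expect_equal(length(got), length(comp))
    # representative is the longest member and sources are the breed union
    for (g in got) {
      members <- Filter(function(s) abs(s$bait_pos - g$bait_pos) <= 20 &&
                          abs(s$length - g$length) <= 0.1 * max(s$length, g$length),
                        svs)
      expect_equal(g$length, max(vapply(members, `[[`, 0L, "length")))
    }
  }
})

test_that("clusters respect min_sources and the length tolerance", {
  one <- candidate_sv("INS", 1000L, random_seq(286, 61), sources = "only")
  expect_length(cluster_svs(list(one), discovery_params(min_sources = 2L)), 0)
  expect_length(cluster_svs(list(one), discovery_params(min_sources = 1L)), 1)
  a <- candidate_sv("INS", 1000L, random_seq(286, 62), sources = "A")
  b <- candidate_sv("INS", 1000L, random_seq(800, 63), sources = "B")
  got <- cluster_svs(list(a, b), discovery_params(min_sources = 1L))
  expect_length(got, 2)
})

test_that("reverse-complemented assemblies are rescued by the revcomp retry", {
  cfg <- clean_cfg(seed = 33, tsd_len = 0L, divergence = 0, snp = 0, indel = 0)
  loc <- make_locus(cfg)
  asm <- make_assemblies(loc$bait, loc$model, loc$library, cfg)
  flipped <- locus_sequence("flip", revcomp(asm$assemblies[[1]]$seq),
                            breed = "carrier2")
  expect_error(align_locus(loc$bait, flipped), "no anchors|no collinear")
  svs <- discover_rips(loc$bait, list(asm$assemblies[[1]], flipped),
                       discovery_params(min_sources = 2L))
  expect_length(svs, 1)
  expect_equal(svs[[1]]$length, 286L)
  expect_setequal(svs[[1]]$sources, c("carrier", "carrier2"))
})

test_that("in-silico PCR sizes products across insertion haplotypes", {
  bait <- random_seq(2000, 71)
  fwd <- substr(bait, 801, 820)
  rev_primer <- revcomp(substr(bait, 1181, 1200))
  expect_equal(insilico_pcr(bait, fwd, rev_primer), 400L)
  with_ins <- paste0(substr(bait, 1, 1000), random_seq(286, 72),
                     substr(bait, 1001, 2000))
  expect_equal(insilico_pcr(with_ins, fwd, rev_primer), 400L + 286L)
  expect_equal(insilico_pcr(bait, revcomp(substr(random_seq(40, 73), 1, 20)),
                            rev_primer), integer(0))
  expect_error(insilico_pcr(bait, "ACGTACGT", rev_primer), ">= 15")
})
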
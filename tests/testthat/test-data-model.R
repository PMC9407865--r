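test_that("FASTA round-trip preserves names, breeds and sequences", {
  seqs <- list(locus_sequence("locus1", random_seq(120, 1), breed = "Meishan"),
               locus_sequence("locus2", random_seq(80, 2)))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_length(back, 2)
  expect_equal(vapply(back, `[[`, "", "name"), c("locus1", "locus2"))
  expect_equal(vapply(back, `[[`, "", "breed"), c("Meishan", "locus2"))
  expect_equal(vapply(back, `[[`, "", "seq"), vapply(seqs, `[[`, "", "seq"))
})

test_that("read_fasta uppercases, validates symbols, keeps file order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", ">y breed=Bama", "NNAC"), f)
  recs <- read_fasta(f)
  expect_equal(recs[[1]]$seq, "ACGT")
  expect_equal(nchar(recs[[1]]$seq), 4L)
  expect_equal(recs[[2]]$breed, "Bama")

  writeLines(c(">bad", "ACGX"), f)
  expect_error(read_fasta(f), "X")
  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "no such file")
})

test_that("label_feature maps breakpoints to exons, introns and flanks", {
  m <- toy_model("+")
  expect_equal(label_feature(25L, m), "Intron1")
  expect_equal(label_feature(35L, m), "Exon2")
  expect_equal(label_feature(3L, m), "upstream")
  expect_equal(label_feature(70L, m), "downstream")
  expect_equal(label_feature(45L, m), "Intron2")
})

test_that("minus-strand labels mirror plus-strand labels in transcription order", {
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(2:8, 1)
    starts <- cumsum(sample(20:60, k, replace = TRUE))
    ends <- starts + sample(5:15, k, replace = TRUE)
    plus <- gene_model("g", cbind(starts, ends), "+")
    minus <- gene_model("g", cbind(starts, ends), "-")
    for (bp in sample(0:(max(ends) + 30), 12)) {
      lp <- label_feature(bp, plus)
      lm <- label_feature(bp, minus)
      if (grepl("^Exon", lp)) {
        expect_equal(lm, paste0("Exon", k + 1 - as.integer(sub("Exon", "", lp))))
      } else if (grepl("^Intron", lp)) {
        expect_equal(lm, paste0("Intron", k - as.integer(sub("Intron", "", lp))))
      } else {
        expect_equal(lm, setdiff(c("upstream", "downstream"), lp))
      }
    }
  }
})

test_that("rip table, BED and VCF coordinates are mutually consistent", {
  bait <- locus_sequence("bait", random_seq(500, 3), chrom = "6",
                         offset = 146978000L)
  # breakpoint between locus bases 73 and 74 = chromosome 146978072/146978073
  sv <- candidate_sv("INS", 73L, random_seq(286, 4), sources = c("A", "B"))
  cls <- list(family = "SINEA1", class = "SINE", direction = "-",
              identity = 0.98, insertion_coverage = 0.96)
  rec <- build_rip_record(sv, cls, "", toy_model("+"), bait)
  expect_equal(rec$chrom_span, "6:146978072-146978073")
  expect_equal(rec$feature_label, "downstream")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_rip_table(list(rec), tsv, bed = bed, vcf = vcf)

  tab <- read.delim(tsv)
  expect_equal(tab$length_bp, 286L)
  expect_equal(tab$direction, "-")
  expect_equal(tab$type, "SINEA1")
  expect_equal(tab$insertion_in, "downstream")

  bd <- read.delim(bed, header = FALSE)
  # bed_start = report_start - 1 (here report coordinates are locus-frame)
  expect_equal(bd$V2, sv$bait_pos - 1L)
  expect_equal(bd$V3, bd$V2 + 1L)
  expect_equal(bd$V6, "-")

  vl <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCFv4.2$", vl)))
  body <- vl[!grepl("^#", vl)]
  expect_length(body, 1)
  fields <- strsplit(body, "\t")[[1]]
  expect_length(fields, 8)
  expect_equal(fields[5], "<INS>")
  expect_match(fields[8], "SVLEN=286")
})

test_that("empty record lists yield a header-only table and bait_pos 0 clamps BED", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_rip_table(list(), tsv, bed = bed)
  expect_equal(length(readLines(tsv)), 1L)

  bait <- locus_sequence("bait", random_seq(400, 5))
  sv <- candidate_sv("INS", 0L, random_seq(60, 6), sources = "A")
  rec <- build_rip_record(sv, list(family = "unclassified", class = "none",
                                   direction = ".", identity = 0.3,
                                   insertion_coverage = 0.4),
                          "", toy_model("+"), bait)
  write_rip_table(list(rec), tsv, bed = bed)
  bd <- read.delim(bed, header = FALSE)
  expect_equal(bd$V2, 0L)
  expect_equal(bd$V3, 1L)
})

test_that("constructors enforce their invariants", {
  expect_error(locus_sequence("x", ""), "empty")
  expect_error(locus_sequence("x", "ACGU"), "U")
  expect_error(gene_model("g", rbind(c(10, 20), c(15, 30))), "non-overlapping")
  expect_error(repeat_consensus("s", "SINE", "ACGN"), "no N")
  expect_error(candidate_sv("INS", -1, "ACGT"), "bait_pos")
  expect_error(candidate_sv("INV", 1, "ACGT"), "INS or DEL")
  expect_error(genotype_counts("b", 0, 0, 0), "total")
  gm <- gene_model("g", cbind(10, 20))
  expect_error(ripkit:::resolve_breakpoint(list(intron = 1), gm, 100), "interval|intron|no introns")
})
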
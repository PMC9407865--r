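# Shared fixture helpers; everything is generated in code under fixed seeds.

# a small clean simulation: one insertion, no background noise
clean_cfg <- function(seed = 101, tsd_len = 12L, divergence = 0,
                      len = 286L, strand = "-", snp = 0, indel = 0) {
  sim_config(
    seed = seed, locus_len = 8000, n_exons = 4, exon_len = 150,
    intron_len = 600, gene_start = 1500,
    insertions = list(list(consensus = sprintf("SINEA1_%d", len),
                           length = len, class = "SINE", strand = strand,
                           intron = 1L, tsd_len = tsd_len,
                           divergence = divergence)),
    breeds = list(
      list(name = "carrier", carries = 1L, snp_rate = snp, indel_rate = indel),
      list(name = "carrier2", carries = 1L, snp_rate = snp, indel_rate = indel),
      list(name = "empty", carries = integer(), snp_rate = snp, indel_rate = indel)))
}

# three-exon toy gene on a plus or minus strand
toy_model <- function(strand = "+") {
  gene_model("toy", rbind(c(10, 20), c(30, 40), c(50, 60)), strand = strand)
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# point-mutate a sequence at `k` positions
mutate_seq <- function(s, k, seed) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

expected_pic_rows <- function() {
  # printed 3-decimal PIC per (locus, breed); the Sujiang LEPR-SINE-RIP1 row
  # is excluded (its printed PIC exceeds the biallelic maximum of the formula)
  d <- rip_genotype_counts()
  printed <- c(
    "LEPROT-SINE-RIP.Large White" = 0.374, "LEPROT-SINE-RIP.Duroc" = 0.373,
    "LEPROT-SINE-RIP.Landrace" = 0.258, "LEPROT-SINE-RIP.Sujiang" = 0.375,
    "LEPROT-SINE-RIP.Jiangquhai" = 0.317, "LEPROT-SINE-RIP.Jinhua" = 0.305,
    "LEPROT-SINE-RIP.Rongchang" = 0.353,
    "LEPR-SINE-RIP1.Large White" = 0.282, "LEPR-SINE-RIP1.Duroc" = 0.291,
    "LEPR-SINE-RIP1.Jiangquhai" = 0.141, "LEPR-SINE-RIP1.Jinhua" = 0.258,
    "LEPR-SINE-RIP2.Large White" = 0.338, "LEPR-SINE-RIP2.Duroc" = 0.359,
    "LEPR-SINE-RIP2.Landrace" = 0.375, "LEPR-SINE-RIP2.Sujiang" = 0.346,
    "LEPR-SINE-RIP2.Bama" = 0.371, "LEPR-SINE-RIP2.Jiangquhai" = 0.239,
    "LEPR-SINE-RIP2.Erhualian" = 0.077, "LEPR-SINE-RIP2.Jinhua" = 0.258,
    "LEPR-SINE-RIP2.Wuzhishan" = 0.373)
  d$key <- paste(d$locus, d$breed, sep = ".")
  d <- d[d$key %in% names(printed), ]
  d$printed_pic <- printed[d$key]
  d
}
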
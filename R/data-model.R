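# Core record types, coordinate conventions, and file IO.
#
# Coordinates: all internal breakpoints are 0-based between-base offsets on the
# bait (an insertion at bait_pos = k sits between bait bases k and k+1, 1-based).
# Human-facing report columns are 1-based inclusive; BED output is 0-based
# half-open.

#' Construct a locus sequence record
#'
#' A named DNA sequence with an optional chromosomal coordinate frame, the unit
#' every pipeline stage exchanges. Sequences are uppercased on construction.
#'
#' @param name Sequence identifier.
#' @param seq DNA string over `A,C,G,T,N`.
#' @param breed Breed or source label (defaults to `name`).
#' @param offset 1-based chromosomal position of the first base; 0 if unplaced.
#' @param chrom Chromosome label, or `""`.
#' @return An object of class `locus_sequence`.
#' @export
locus_sequence <- function(name, seq, breed = name, offset = 0L, chrom = "") {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("locus_sequence: empty sequence for '", name, "'")
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop("locus_sequence: non-DNA symbol '", substr(bad, 1, 1), "' in '", name, "'")
  }
  if (offset < 0) stop("locus_sequence: offset must be >= 0")
  structure(
    list(name = name, breed = breed, seq = seq,
         offset = as.integer(offset), chrom = chrom),
    class = "locus_sequence"
  )
}

#' @export
print.locus_sequence <- function(x, ...) {
  cat(sprintf("<locus_sequence> %s (breed %s): %d bp%s\n", x$name, x$breed,
              nchar(x$seq),
              if (x$offset > 0) sprintf(" at %s:%d", x$chrom, x$offset) else ""))
  invisible(x)
}

#' Construct a gene model
#'
#' Exon intervals on the locus coordinate frame; introns are the gaps between
#' consecutive exons, numbered in transcription order (respecting `strand`).
#'
#' @param gene_name Gene symbol.
#' @param exons Two-column matrix or data.frame of 1-based inclusive
#'   `(start, end)` exon intervals, sorted, non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_name, exons, strand = "+") {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1) stop("gene_model: at least one exon required")
  if (!strand %in% c("+", "-")) stop("gene_model: strand must be '+' or '-'")
  if (any(exons[, 1] > exons[, 2])) stop("gene_model: exon start > end")
  if (is.unsorted(exons[, 1], strictly = TRUE) ||
      (nrow(exons) > 1 && any(exons[-nrow(exons), 2] >= exons[-1, 1]))) {
    stop("gene_model: exons must be sorted and non-overlapping")
  }
  structure(list(gene_name = gene_name, strand = strand, exons = exons),
            class = "gene_model")
}

#' Construct a repeat consensus entry
#'
#' @param name Consensus name (unique within a library).
#' @param class One of `"SINE"`, `"LINE"`, `"ERV"`.
#' @param seq Consensus DNA (no `N`).
#' @return An object of class `repeat_consensus`.
#' @export
repeat_consensus <- function(name, class, seq) {
  seq <- toupper(seq)
  if (!class %in% c("SINE", "LINE", "ERV")) {
    stop("repeat_consensus: class must be SINE, LINE or ERV")
  }
  if (!nzchar(seq) || grepl("[^ACGT]", seq)) {
    stop("repeat_consensus: consensus must be non-empty A/C/G/T (no N)")
  }
  structure(list(name = name, class = class, seq = seq),
            class = "repeat_consensus")
}

#' Construct a candidate structural variant
#'
#' An insertion or deletion relative to the bait, expressed in the bait frame.
#'
#' @param sv_type `"INS"` or `"DEL"`.
#' @param bait_pos 0-based between-base breakpoint on the bait (for `DEL`, the
#'   offset just before the first deleted base).
#' @param seq Inserted (INS) or deleted (DEL) sequence.
#' @param sources Character vector of supporting breed labels.
#' @param bait_len Optional bait length for the breakpoint range check.
#' @return An object of class `candidate_sv`.
#' @export
candidate_sv <- function(sv_type, bait_pos, seq, sources = character(),
                         bait_len = NULL) {
  if (!sv_type %in% c("INS", "DEL")) stop("candidate_sv: sv_type must be INS or DEL")
  seq <- toupper(seq)
  if (nchar(seq) < 1) stop("candidate_sv: empty sequence")
  if (bait_pos < 0) stop("candidate_sv: bait_pos must be >= 0")
  if (!is.null(bait_len) && bait_pos > bait_len) {
    stop("candidate_sv: bait_pos beyond bait end")
  }
  structure(
    list(sv_type = sv_type, bait_pos = as.integer(bait_pos),
         length = nchar(seq), seq = seq, sources = unique(sources)),
    class = "candidate_sv"
  )
}

#' Construct per-breed genotype counts for a biallelic insertion marker
#'
#' @param breed Breed label.
#' @param n_ins_ins,n_ins_del,n_del_del Counts of the `+/+`, `+/-`, `-/-`
#'   genotypes.
#' @return An object of class `genotype_counts`.
#' @export
genotype_counts <- function(breed, n_ins_ins, n_ins_del, n_del_del) {
  n <- c(n_ins_ins, n_ins_del, n_del_del)
  if (any(n < 0) || any(n != round(n))) stop("genotype_counts: counts must be non-negative integers")
  if (sum(n) < 1) stop("genotype_counts: total must be >= 1")
  structure(list(breed = breed, n_ins_ins = as.integer(n_ins_ins),
                 n_ins_del = as.integer(n_ins_del),
                 n_del_del = as.integer(n_del_del),
                 total = as.integer(sum(n))),
            class = "genotype_counts")
}

# ---------------------------------------------------------------- FASTA IO --

#' Read a FASTA file of locus sequences
#'
#' Sequences are uppercased; the breed label is taken from a `breed=` token in
#' the header if present, else from the first header word.
#'
#' @param path FASTA file.
#' @return List of [locus_sequence()] records in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("read_fasta: empty FASTA: ", path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    s <- toupper(as.character(set[[i]]))
    bad <- gsub("[ACGTN]", "", s)
    if (nzchar(bad)) {
      stop(sprintf("read_fasta: record '%s' contains non-DNA symbol '%s'",
                   header, substr(bad, 1, 1)))
    }
    name <- strsplit(header, "\\s+")[[1]][1]
    breed <- if (grepl("breed=", header)) {
      sub(".*breed=([^ \t]+).*", "\\1", header)
    } else name
    locus_sequence(name, s, breed = breed)
  })
}

#' Write locus sequences to FASTA
#'
#' @param seqs List of [locus_sequence()] records.
#' @param path Output file.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "locus_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "seq"))
  names(set) <- vapply(seqs, function(s) {
    if (identical(s$breed, s$name)) s$name else paste0(s$name, " breed=", s$breed)
  }, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ------------------------------------------------------------------ TSV IO --

read_tsv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  d
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene model from an exon TSV
#'
#' Columns: `gene`, `strand`, `start`, `end` (1-based inclusive exon intervals).
#'
#' @param path TSV file.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path) {
  d <- read_tsv_strict(path, c("gene", "strand", "start", "end"))
  gene_model(d$gene[1], cbind(d$start, d$end), strand = d$strand[1])
}

#' Write a gene model to an exon TSV
#'
#' @param model A [gene_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  write_tsv(data.frame(gene = model$gene_name, strand = model$strand,
                       start = model$exons[, 1], end = model$exons[, 2]),
            path)
}

#' Read per-breed genotype counts
#'
#' Columns: `breed`, `locus`, `n_ins_ins`, `n_ins_del`, `n_del_del`.
#'
#' @param path TSV file.
#' @return Data frame of counts.
#' @export
read_genotype_counts <- function(path) {
  read_tsv_strict(path, c("breed", "locus", "n_ins_ins", "n_ins_del", "n_del_del"))
}

#' Bundled genotype counts for the three LEPROT/LEPR SINE RIPs
#'
#' Genotype counts of the `+/+`, `+/-` and `-/-` classes for the three SINE
#' insertion polymorphisms in the pig LEPROT and LEPR genes across nine breeds
#' (commercial, Chinese native and crossbred populations).
#'
#' @return Data frame with columns `locus`, `breed`, `n_ins_ins`, `n_ins_del`,
#'   `n_del_del`.
#' @export
rip_genotype_counts <- function() {
  read_genotype_counts(system.file("extdata", "rip_genotype_counts.tsv",
                                   package = "ripkit", mustWork = TRUE))
}

# --------------------------------------------------------- feature labeling --

#' Label the gene feature hit by a breakpoint
#'
#' Returns `"ExonK"`, `"IntronK"` (K counted in transcription order, so
#' Intron1 is adjacent to the transcription start on either strand),
#' `"upstream"` or `"downstream"`.
#'
#' @param sv A [candidate_sv()] or a 0-based between-base breakpoint.
#' @param model A [gene_model()].
#' @return Feature label string.
#' @export
label_feature <- function(sv, model) {
  bp <- if (inherits(sv, "candidate_sv")) sv$bait_pos else as.integer(sv)
  ex <- model$exons
  k <- nrow(ex)
  # breakpoint between 1-based bases bp and bp+1; use the midpoint bp + 0.5
  pos <- bp + 0.5
  if (pos < ex[1, 1]) {
    return(if (model$strand == "+") "upstream" else "downstream")
  }
  if (pos > ex[k, 2]) {
    return(if (model$strand == "+") "downstream" else "upstream")
  }
  for (i in seq_len(k)) {
    if (pos >= ex[i, 1] && pos <= ex[i, 2]) {
      idx <- if (model$strand == "+") i else k - i + 1
      return(paste0("Exon", idx))
    }
    if (i < k && pos > ex[i, 2] && pos < ex[i + 1, 1]) {
      idx <- if (model$strand == "+") i else k - i
      return(paste0("Intron", idx))
    }
  }
  "downstream" # unreachable
}

# -------------------------------------------------------------- RIP report --

#' Write annotated RIP records as a report table (plus optional BED/VCF)
#'
#' The TSV reproduces the classic RIP report layout (locus name, gene feature,
#' length, direction, repeat type, chromosome span) extended with identity,
#' insertion coverage and TSD columns. The optional BED6 file uses 0-based
#' half-open coordinates (point insertions become 1-bp features); the optional
#' minimal VCF 4.2 uses symbolic `<INS>`/`<DEL>` ALT alleles.
#'
#' @param records List of RIP records from [build_rip_record()]/[annotate_rips()].
#' @param path Output TSV path.
#' @param bed,vcf Optional BED6 / VCF output paths.
#' @return `path`, invisibly.
#' @export
write_rip_table <- function(records, path, bed = NULL, vcf = NULL) {
  d <- rip_table(records)
  write_tsv(d, path)
  if (!is.null(bed)) {
    bd <- do.call(rbind, lapply(records, function(r) {
      # 0-based half-open 1-bp feature on the base preceding the breakpoint,
      # so bed_start = report_start - 1 (clamped at the locus start)
      start0 <- max(0L, r$sv$bait_pos - 1L)
      data.frame(chrom = if (nzchar(r$chrom)) r$chrom else r$locus_name,
                 start = start0, end = start0 + 1L, name = r$rip_name,
                 score = round(r$identity * 1000), strand = r$direction)
    }))
    if (is.null(bd)) bd <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), name = character(),
                                      score = integer(), strand = character())
    utils::write.table(bd, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(vcf)) {
    con <- file(vcf, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##ALT=<ID=INS,Description=\"Insertion relative to bait\">",
                 "##ALT=<ID=DEL,Description=\"Deletion relative to bait\">",
                 "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
                 "##INFO=<ID=FAMILY,Number=1,Type=String,Description=\"Repeat family\">",
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", sep = "\t")), con)
    for (r in records) {
      pos1 <- r$sv$bait_pos # 1-based position of the base before the breakpoint
      if (pos1 < 1) pos1 <- 1L
      sign_len <- if (r$sv$sv_type == "INS") r$length else -r$length
      writeLines(paste(if (nzchar(r$chrom)) r$chrom else r$locus_name,
                       r$report_pos %||% pos1, r$rip_name, "N",
                       paste0("<", r$sv$sv_type, ">"), ".", "PASS",
                       sprintf("SVLEN=%d;FAMILY=%s", sign_len, r$family),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Tabulate RIP records
#'
#' @param records List of RIP records.
#' @return Data frame in the report column layout.
#' @export
rip_table <- function(records) {
  if (length(records) == 0) {
    return(data.frame(loci = character(), insertion_in = character(),
                      length_bp = integer(), direction = character(),
                      type = character(), chromosome = character(),
                      identity = numeric(), coverage = numeric(),
                      tsd = character(), sources = character()))
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(loci = r$rip_name, insertion_in = r$feature_label,
               length_bp = r$length, direction = r$direction,
               type = r$family, chromosome = r$chrom_span,
               identity = round_half_up(r$identity, 3),
               coverage = round_half_up(r$insertion_coverage, 3),
               tsd = r$tsd, sources = paste(r$sv$sources, collapse = ","))
  }))
}
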
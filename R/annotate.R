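# Insertion classification against a repeat consensus library, TSD detection,
# and assembly of report records.

#' Annotation parameters
#'
#' @param min_identity Minimum alignment identity for a family assignment.
#' @param min_insertion_coverage Minimum fraction of the insertion aligned.
#' @param match,mismatch,gap_open,gap_extend Local-alignment scores
#'   (gap penalties given as negative numbers).
#' @param tsd_min,tsd_max Candidate TSD length range (bp).
#' @param tsd_max_mismatch Internal mismatches tolerated in a TSD (the
#'   boundary column of the duplication must still match exactly).
#' @param tsd_search_window Flank window searched around the breakpoint (bp).
#' @return An object of class `annotation_params`.
#' @export
annotation_params <- function(min_identity = 0.70, min_insertion_coverage = 0.80,
                              match = 2, mismatch = -3, gap_open = -5,
                              gap_extend = -1, tsd_min = 5L, tsd_max = 20L,
                              tsd_max_mismatch = 1L, tsd_search_window = 30L) {
  if (min_identity <= 0 || min_identity > 1) {
    stop("annotation_params: min_identity must be in (0, 1]")
  }
  if (tsd_min > tsd_max) stop("annotation_params: tsd_min > tsd_max")
  structure(list(min_identity = min_identity,
                 min_insertion_coverage = min_insertion_coverage,
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, tsd_min = as.integer(tsd_min),
                 tsd_max = as.integer(tsd_max),
                 tsd_max_mismatch = as.integer(tsd_max_mismatch),
                 tsd_search_window = as.integer(tsd_search_window)),
            class = "annotation_params")
}

#' Classify an insertion against a repeat consensus library
#'
#' Smith-Waterman local alignment of the inserted sequence against each
#' consensus and its reverse complement; the best-scoring hit wins. Identity
#' is matches over alignment columns; insertion coverage is the fraction of
#' inserted bases inside the aligned region. A hit is accepted only if both
#' thresholds are met, otherwise the insertion is `"unclassified"` with
#' direction `"."`.
#'
#' @param sv A [candidate_sv()] with `sv_type == "INS"`.
#' @param library List of [repeat_consensus()].
#' @param params An [annotation_params()].
#' @return List with `family`, `class`, `direction`, `identity`,
#'   `insertion_coverage`.
#' @export
classify_insertion <- function(sv, library, params = annotation_params()) {
  if (!inherits(sv, "candidate_sv") || sv$sv_type != "INS") {
    stop("classify_insertion: sv must be an INS candidate_sv")
  }
  if (length(library) == 0) stop("classify_insertion: empty library")
  submat <- dna_submat(params$match, params$mismatch)
  pat <- Biostrings::DNAString(sv$seq)
  best <- list(score = -Inf, family = "unclassified", class = "none",
               direction = ".", identity = 0, insertion_coverage = 0)
  for (cons in library) {
    for (dir in c("+", "-")) {
      cseq <- if (dir == "+") cons$seq else revcomp(cons$seq)
      aln <- Biostrings::pairwiseAlignment(
        pat, Biostrings::DNAString(cseq), type = "local",
        substitutionMatrix = submat, gapOpening = -params$gap_open,
        gapExtension = -params$gap_extend)
      sc <- Biostrings::score(aln)
      if (sc <= best$score) next
      patstr <- as.character(Biostrings::pattern(aln))
      cols <- nchar(patstr)
      ident <- if (cols > 0) Biostrings::nmatch(aln) / cols else 0
      cov <- nchar(gsub("-", "", patstr)) / sv$length
      best <- list(score = sc, family = cons$name, class = cons$class,
                   direction = dir, identity = ident,
                   insertion_coverage = cov)
    }
  }
  if (best$identity < params$min_identity ||
      best$insertion_coverage < params$min_insertion_coverage) {
    return(list(family = "unclassified", class = "none", direction = ".",
                identity = best$identity,
                insertion_coverage = best$insertion_coverage))
  }
  best[c("family", "class", "direction", "identity", "insertion_coverage")]
}

#' Detect the target site duplication of an insertion
#'
#' Searches for the longest duplicated word of length in
#' `[tsd_min, tsd_max]` flush at the insertion junctions, in both equivalent
#' placements of a left-normalised insertion: the word may appear at the
#' start of the inserted sequence and immediately 3' of the breakpoint on the
#' bait, or at the end of the inserted sequence and immediately 5' of the
#' breakpoint. Exact duplications take precedence; only when no exact
#' duplication of at least `tsd_min` exists are up to `tsd_max_mismatch`
#' internal mismatches tolerated, and the boundary columns of a duplication
#' must always match exactly (an unanchored mismatch budget would extend past
#' the true duplication by chance). Ties between placements break toward the
#' 3' placement.
#'
#' @param bait Bait [locus_sequence()] (or DNA string).
#' @param sv A [candidate_sv()] insertion with a bait-frame breakpoint.
#' @param params An [annotation_params()].
#' @return The duplicated word, or `""` if none.
#' @export
detect_tsd <- function(bait, sv, params = annotation_params()) {
  if (sv$sv_type != "INS") stop("detect_tsd: sv must be an insertion")
  bs <- if (inherits(bait, "locus_sequence")) bait$seq else toupper(bait)
  bp <- sv$bait_pos
  ins <- sv$seq
  n <- nchar(ins)
  lmax <- min(params$tsd_max, n, params$tsd_search_window)
  best_exact <- ""
  best_fuzzy <- ""
  for (l in seq_len(lmax)) {
    if (l < params$tsd_min) next
    cand <- list()
    # placement A: word starts the insertion and follows the breakpoint
    if (bp + l <= nchar(bs)) {
      cand[[length(cand) + 1L]] <- c(substr(ins, 1, l), substr(bs, bp + 1, bp + l))
    }
    # placement B: word ends the insertion and precedes the breakpoint
    if (bp - l >= 0 && l <= n) {
      cand[[length(cand) + 1L]] <- c(substr(ins, n - l + 1, n),
                                     substr(bs, bp - l + 1, bp))
    }
    for (cc in cand) {
      mm <- tsd_mismatches(cc[1], cc[2])
      if (is.na(mm)) next
      if (mm == 0L) {
        if (l > nchar(best_exact)) best_exact <- cc[1]
      } else if (mm <= params$tsd_max_mismatch) {
        if (l > nchar(best_fuzzy)) best_fuzzy <- cc[1]
      }
    }
  }
  if (nzchar(best_exact)) best_exact else best_fuzzy
}

# mismatch count of a candidate duplication; NA if a boundary column
# mismatches (the duplication must be flush at both ends)
tsd_mismatches <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  if (av[length(av)] != bv[length(bv)] || av[1] != bv[1]) return(NA_integer_)
  sum(av != bv)
}

#' Assemble an annotated RIP record
#'
#' Combines a clustered insertion, its classification, TSD and the gene model
#' into one report row. The reported element length excludes one copy of the
#' detected TSD (the duplication is target sequence, not element sequence).
#' The chromosome span is the 2-bp interval flanking the breakpoint when the
#' insertion is absent from the reference frame, and the full inserted span
#' otherwise.
#'
#' @param sv A [candidate_sv()] insertion.
#' @param classification Result of [classify_insertion()].
#' @param tsd TSD string from [detect_tsd()] (or `""`).
#' @param model A [gene_model()].
#' @param locus Bait [locus_sequence()] (supplies the coordinate frame).
#' @param serial Serial number of this RIP within its gene and repeat class;
#'   `NULL` for a gene's only RIP (name ends in `-RIP`), an integer otherwise
#'   (`-RIP2`, ...).
#' @param in_reference Is the insertion present in the reference frame? If
#'   `FALSE` (default: the bait lacks the insertion) the span is the 2-bp
#'   breakpoint interval.
#' @return A list of class `rip_record`.
#' @export
build_rip_record <- function(sv, classification, tsd, model, locus,
                             serial = NULL, in_reference = FALSE) {
  stopifnot(inherits(sv, "candidate_sv"))
  elem_len <- sv$length - nchar(tsd)
  base <- paste0(model$gene_name, "-",
                 if (classification$class == "none") "SV" else classification$class,
                 "-RIP")
  rip_name <- if (is.null(serial)) base else paste0(base, serial)
  chrom <- locus$chrom
  off <- if (locus$offset > 0) locus$offset else 1L
  left <- off + sv$bait_pos - 1L # 1-based base just before the breakpoint
  span <- if (in_reference) {
    sprintf("%s:%d-%d", if (nzchar(chrom)) chrom else locus$name,
            left + 1L, left + sv$length)
  } else {
    sprintf("%s:%d-%d", if (nzchar(chrom)) chrom else locus$name, left, left + 1L)
  }
  structure(list(
    rip_name = rip_name, sv = sv, family = classification$family,
    repeat_class = classification$class, direction = classification$direction,
    identity = classification$identity,
    insertion_coverage = classification$insertion_coverage, tsd = tsd,
    length = elem_len, feature_label = label_feature(sv, model),
    chrom_span = span, locus_name = locus$name, chrom = chrom,
    report_pos = left), class = "rip_record")
}

#' @export
print.rip_record <- function(x, ...) {
  cat(sprintf("<rip_record> %s: %s, %d bp, %s, %s, %s%s\n", x$rip_name,
              x$feature_label, x$length, x$direction, x$family, x$chrom_span,
              if (nzchar(x$tsd)) paste0(", TSD ", x$tsd) else ""))
  invisible(x)
}

#' Annotate clustered insertions into RIP records
#'
#' Classifies each insertion cluster, detects TSDs, and assembles named
#' report records (serials increment in breakpoint order within each gene and
#' repeat class; a class's only RIP carries no serial).
#'
#' @param clusters List of [candidate_sv()] from [cluster_svs()]/[discover_rips()].
#' @param library List of [repeat_consensus()].
#' @param model A [gene_model()].
#' @param bait Bait [locus_sequence()].
#' @param params An [annotation_params()].
#' @return List of `rip_record` objects.
#' @export
annotate_rips <- function(clusters, library, model, bait,
                          params = annotation_params()) {
  ins <- Filter(function(s) s$sv_type == "INS", clusters)
  ins <- ins[order(vapply(ins, `[[`, 0L, "bait_pos"))]
  cls <- lapply(ins, classify_insertion, library = library, params = params)
  tsds <- vapply(seq_along(ins), function(i) detect_tsd(bait, ins[[i]], params), "")
  classes <- vapply(cls, `[[`, "", "class")
  tab <- table(classes)
  counter <- stats::setNames(integer(length(tab)), names(tab))
  lapply(seq_along(ins), function(i) {
    cl <- classes[i]
    counter[cl] <<- counter[cl] + 1L
    serial <- if (tab[[cl]] == 1L) NULL else counter[[cl]]
    build_rip_record(ins[[i]], cls[[i]], tsds[i], model, bait, serial = serial)
  })
}
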
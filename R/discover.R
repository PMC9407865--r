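# Large-indel discovery by pairwise anchor chaining.
#
# Each assembly-derived locus is aligned to the bait by exact unique k-mer
# anchoring: k-mers unique in both sequences become anchors, maximal
# co-diagonal anchor runs are chained by a collinear dynamic programme
# (with overlap trimming), and the unanchored gap segments between chained
# runs carry the candidate indels. A gap whose net length difference reaches
# the SV threshold yields one insertion or deletion; flank-anchored prefix
# matching places the event and preserves the net length exactly, and
# breakpoints are left-normalised (VCF convention). Cross-genome recurrence
# is restored by clustering per-genome calls.

#' Discovery parameters
#'
#' @param k Anchor k-mer size (>= 11).
#' @param min_sv_len Minimum net indel length called as an SV (bp).
#' @param cluster_pos_tol Breakpoint tolerance when clustering across genomes (bp).
#' @param cluster_len_tol Relative length tolerance when clustering.
#' @param min_sources Minimum number of distinct supporting breeds per cluster.
#' @param band Maximum gap side length resolved by flank matching (bp); larger
#'   or highly asymmetric gaps are passed through as raw length-difference
#'   segments.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (used by
#'   downstream classification; kept here so one object carries every tunable).
#' @return An object of class `discovery_params`.
#' @export
discovery_params <- function(k = 31L, min_sv_len = 50L, cluster_pos_tol = 20L,
                             cluster_len_tol = 0.1, min_sources = 2L,
                             band = 5000L, match = 2, mismatch = -3,
                             gap_open = -5, gap_extend = -1) {
  if (k < 11) stop("discovery_params: k must be >= 11")
  if (min_sv_len < 1) stop("discovery_params: min_sv_len must be >= 1")
  if (min_sources < 1) stop("discovery_params: min_sources must be >= 1")
  structure(list(k = as.integer(k), min_sv_len = as.integer(min_sv_len),
                 cluster_pos_tol = as.integer(cluster_pos_tol),
                 cluster_len_tol = cluster_len_tol,
                 min_sources = as.integer(min_sources),
                 band = as.integer(band), match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "discovery_params")
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1), k:n)
}

#' Align an assembly locus to the bait by unique k-mer anchor chaining
#'
#' @param bait,query [locus_sequence()] records.
#' @param params A [discovery_params()].
#' @return An `anchor_chain`: chained anchor blocks and the gap segments
#'   between them (1-based inclusive intervals on both sequences; empty
#'   intervals have `start > end`).
#' @export
align_locus <- function(bait, query, params = discovery_params()) {
  k <- params$k
  bs <- bait$seq; qs <- query$seq
  if (!nzchar(bs) || !nzchar(qs)) stop("align_locus: empty sequence")
  bk <- kmer_set(bs, k); qk <- kmer_set(qs, k)
  b_uni <- !(duplicated(bk) | duplicated(bk, fromLast = TRUE))
  q_uni <- !(duplicated(qk) | duplicated(qk, fromLast = TRUE))
  m <- match(qk, bk)
  keep <- which(q_uni & !is.na(m) & b_uni[m])
  if (length(keep) == 0) {
    stop(sprintf("align_locus: no anchors between '%s' and '%s'",
                 bait$name, query$name))
  }
  qpos <- keep
  bpos <- m[keep]
  # collapse anchors into maximal co-diagonal runs of consecutive positions
  off <- bpos - qpos
  brk <- c(TRUE, diff(qpos) != 1L | diff(off) != 0L)
  run <- cumsum(brk)
  blocks <- data.frame(
    bstart = tapply(bpos, run, min), bend = tapply(bpos, run, max) + k - 1L,
    qstart = tapply(qpos, run, min), qend = tapply(qpos, run, max) + k - 1L)
  blocks <- blocks[order(blocks$bstart, blocks$qstart), , drop = FALSE]
  if (nrow(blocks) > 5000L) { # defensive cap: keep the longest runs
    len <- blocks$bend - blocks$bstart
    blocks <- blocks[order(len, decreasing = TRUE)[1:5000], , drop = FALSE]
    blocks <- blocks[order(blocks$bstart, blocks$qstart), , drop = FALSE]
  }
  chain <- chain_blocks(blocks)
  if (nrow(chain) == 0) {
    stop(sprintf("align_locus: no collinear chain between '%s' and '%s'",
                 bait$name, query$name))
  }
  gaps <- chain_gaps(chain, nchar(bs), nchar(qs))
  structure(list(bait = bait, query = query, anchors = chain, gaps = gaps,
                 params = params), class = "anchor_chain")
}

# collinear chaining with overlap trimming: maximise total anchored length
chain_blocks <- function(blocks) {
  m <- nrow(blocks)
  len <- blocks$bend - blocks$bstart + 1L
  score <- as.numeric(len)
  prev <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    for (i in seq_len(j - 1L)) {
      if (blocks$bstart[j] <= blocks$bstart[i]) next
      if (blocks$qstart[j] <= blocks$qstart[i]) next
      ob <- max(0L, blocks$bend[i] - blocks$bstart[j] + 1L)
      oq <- max(0L, blocks$qend[i] - blocks$qstart[j] + 1L)
      o <- max(ob, oq)
      if (o >= len[j]) next
      s <- score[i] + len[j] - o
      if (s > score[j]) { score[j] <- s; prev[j] <- i }
    }
  }
  j <- which.max(score)
  path <- integer()
  while (!is.na(j)) { path <- c(j, path); j <- prev[j] }
  sel <- blocks[path, , drop = FALSE]
  # trim each block's start by its overlap with the predecessor (both
  # coordinates move together, staying on the block diagonal)
  if (nrow(sel) > 1) {
    for (j in 2:nrow(sel)) {
      o <- max(0L, sel$bend[j - 1] - sel$bstart[j] + 1L,
               sel$qend[j - 1] - sel$qstart[j] + 1L)
      sel$bstart[j] <- sel$bstart[j] + o
      sel$qstart[j] <- sel$qstart[j] + o
    }
  }
  rownames(sel) <- NULL
  sel
}

# gap segments tiling the space between consecutive chained blocks,
# including the unanchored termini
chain_gaps <- function(chain, blen, qlen) {
  nb <- nrow(chain)
  gb_start <- c(1L, chain$bend + 1L)
  gb_end <- c(chain$bstart - 1L, blen)
  gq_start <- c(1L, chain$qend + 1L)
  gq_end <- c(chain$qstart - 1L, qlen)
  data.frame(bstart = gb_start, bend = gb_end,
             qstart = gq_start, qend = gq_end)
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}

# shift an insertion breakpoint to its leftmost equivalent position
left_normalize_ins <- function(bait, bp0, seq) {
  bv <- strsplit(bait, "")[[1]]
  sv <- strsplit(seq, "")[[1]]
  n <- length(sv)
  while (bp0 >= 1L && bv[bp0] == sv[n]) {
    sv <- c(bv[bp0], sv[-n])
    bp0 <- bp0 - 1L
  }
  list(bait_pos = bp0, seq = paste(sv, collapse = ""))
}

left_normalize_del <- function(bait, bp0, len) {
  bv <- strsplit(bait, "")[[1]]
  while (bp0 >= 1L && bv[bp0] == bv[bp0 + len]) bp0 <- bp0 - 1L
  list(bait_pos = bp0, seq = paste(bv[(bp0 + 1L):(bp0 + len)], collapse = ""))
}

#' Extract large indels from an anchor chain
#'
#' Every gap segment whose net length difference reaches `min_sv_len` yields
#' one SV: an insertion if the query side is longer (the extra query bases,
#' placed by longest-common-prefix matching against the bait side so the net
#' length is preserved exactly), otherwise a deletion. Breakpoints are
#' left-normalised. Substitution-only gaps and indels below the threshold are
#' discarded.
#'
#' @param chain An `anchor_chain` from [align_locus()].
#' @param params A [discovery_params()].
#' @return List of [candidate_sv()] records, sorted by breakpoint.
#' @export
extract_svs <- function(chain, params = discovery_params()) {
  stopifnot(inherits(chain, "anchor_chain"))
  bs <- chain$bait$seq; qs <- chain$query$seq
  out <- list()
  for (i in seq_len(nrow(chain$gaps))) {
    g <- chain$gaps[i, ]
    blen <- max(0L, g$bend - g$bstart + 1L)
    qlen <- max(0L, g$qend - g$qstart + 1L)
    net <- qlen - blen
    if (abs(net) < params$min_sv_len) next
    bseg <- if (blen > 0) substr(bs, g$bstart, g$bend) else ""
    qseg <- if (qlen > 0) substr(qs, g$qstart, g$qend) else ""
    if (net > 0) { # insertion: extra query bases
      p <- min(longest_common_prefix(bseg, qseg), blen)
      seq <- substr(qs, g$qstart + p, g$qend - (blen - p))
      nz <- left_normalize_ins(bs, g$bstart - 1L + p, seq)
      out[[length(out) + 1L]] <- candidate_sv(
        "INS", nz$bait_pos, nz$seq, sources = chain$query$breed,
        bait_len = nchar(bs))
    } else {       # deletion: extra bait bases
      p <- min(longest_common_prefix(bseg, qseg), qlen)
      nz <- left_normalize_del(bs, g$bstart - 1L + p, -net)
      out[[length(out) + 1L]] <- candidate_sv(
        "DEL", nz$bait_pos, nz$seq, sources = chain$query$breed,
        bait_len = nchar(bs))
    }
  }
  out[order(vapply(out, `[[`, 0L, "bait_pos"))]
}

#' Cluster per-genome SV calls into candidate RIP loci
#'
#' SVs of identical type whose breakpoints differ by at most
#' `cluster_pos_tol` and whose lengths differ by at most `cluster_len_tol`
#' (relative to the longer member) merge transitively into one cluster.
#' Surviving clusters must be supported by at least `min_sources` distinct
#' breeds; the representative is the member with the longest sequence and the
#' sources are the union of the supporting breeds.
#'
#' @param per_genome Named list (breed -> list of [candidate_sv()]) or a flat
#'   list of [candidate_sv()] with `sources` set.
#' @param params A [discovery_params()].
#' @return List of merged [candidate_sv()] records, sorted by breakpoint.
#' @export
cluster_svs <- function(per_genome, params = discovery_params()) {
  svs <- if (length(per_genome) && inherits(per_genome[[1]], "candidate_sv")) {
    per_genome
  } else {
    unlist(per_genome, recursive = FALSE)
  }
  n <- length(svs)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- svs[[i]]; b <- svs[[j]]
      if (a$sv_type != b$sv_type) next
      if (abs(a$bait_pos - b$bait_pos) > params$cluster_pos_tol) next
      if (abs(a$length - b$length) >
          params$cluster_len_tol * max(a$length, b$length)) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- list()
  for (r in unique(roots)) {
    members <- svs[roots == r]
    sources <- unique(unlist(lapply(members, `[[`, "sources")))
    if (length(sources) < params$min_sources) next
    rep <- members[[which.max(vapply(members, `[[`, 0L, "length"))]]
    rep$sources <- sort(sources)
    out[[length(out) + 1L]] <- rep
  }
  out[order(vapply(out, `[[`, 0L, "bait_pos"))]
}

#' Discover candidate RIP loci across a set of assemblies
#'
#' Aligns each assembly to the bait (retrying on the reverse complement if no
#' forward collinear chain exists), extracts large indels, and clusters them
#' across genomes.
#'
#' @param bait Bait [locus_sequence()].
#' @param assemblies List of [locus_sequence()] records.
#' @param params A [discovery_params()].
#' @return List of clustered [candidate_sv()] records.
#' @export
discover_rips <- function(bait, assemblies, params = discovery_params()) {
  per <- lapply(assemblies, function(q) {
    chain <- tryCatch(align_locus(bait, q, params), error = function(e) {
      rc <- locus_sequence(q$name, revcomp(q$seq), breed = q$breed)
      align_locus(bait, rc, params)
    })
    extract_svs(chain, params)
  })
  cluster_svs(per, params)
}

#' In-silico PCR product sizing
#'
#' Finds forward-primer hits and reverse-complemented reverse-primer hits on
#' one haplotype sequence and returns all product lengths up to `max_len`.
#' Genotyping a heterozygote by running both haplotypes yields two products
#' differing by the insertion length.
#'
#' @param haplotype A [locus_sequence()] or DNA string.
#' @param fwd,rev Primer sequences (>= 15 bp), written 5'->3'.
#' @param max_mismatch Mismatches tolerated per primer (default 0).
#' @param max_len Maximum product length reported (bp).
#' @return Integer vector of product lengths (empty if no product).
#' @export
insilico_pcr <- function(haplotype, fwd, rev, max_mismatch = 0L,
                         max_len = 5000L) {
  seq <- if (inherits(haplotype, "locus_sequence")) haplotype$seq else toupper(haplotype)
  if (nchar(fwd) < 15 || nchar(rev) < 15) {
    stop("insilico_pcr: primers must be >= 15 bp")
  }
  subj <- Biostrings::DNAString(seq)
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(toupper(fwd)), subj,
                                    max.mismatch = max_mismatch)
  rhits <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(rev))), subj,
    max.mismatch = max_mismatch)
  if (length(fhits) == 0 || length(rhits) == 0) return(integer())
  lens <- integer()
  for (f in Biostrings::start(fhits)) {
    for (r in Biostrings::end(rhits)) {
      L <- r - f + 1L
      if (L >= nchar(fwd) + nchar(rev) && L <= max_len) lens <- c(lens, L)
    }
  }
  sort(unique(lens))
}
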
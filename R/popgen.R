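# Per-breed population-genetic summaries of a biallelic insertion marker:
# allele/genotype frequencies, Hardy-Weinberg chi-square, and polymorphic
# information content (PIC).

#' Allele frequencies from genotype counts
#'
#' `p_ins = (2 n_ins_ins + n_ins_del) / (2 N)`; full precision is retained
#' (report formatting rounds to 2-decimal percent).
#'
#' @param counts A [genotype_counts()].
#' @return Named numeric vector `c(p_ins, p_del)`.
#' @export
allele_frequencies <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  p <- (2 * counts$n_ins_ins + counts$n_ins_del) / (2 * counts$total)
  c(p_ins = p, p_del = 1 - p)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square of the observed genotype counts against the
#' Hardy-Weinberg expectation `(p^2, 2pq, q^2) * N`, with 1 degree of freedom
#' and no continuity correction (the convention of the classic population
#' genetics packages). A monomorphic sample is flagged and returns
#' `chi2 = 0, p = 1`.
#'
#' @param counts A [genotype_counts()].
#' @return List with `chi2`, `df`, `p`, `monomorphic`.
#' @export
hwe_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  p <- allele_frequencies(counts)[["p_ins"]]
  if (p <= 0 || p >= 1) {
    return(list(chi2 = 0, df = 1L, p = 1, monomorphic = TRUE))
  }
  q <- 1 - p
  obs <- c(counts$n_ins_ins, counts$n_ins_del, counts$n_del_del)
  exp <- c(p^2, 2 * p * q, q^2) * counts$total
  chi2 <- sum((obs - exp)^2 / exp)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Exact Hardy-Weinberg test for a biallelic marker
#'
#' Full-enumeration conditional exact test (probability of the observed
#' heterozygote count given the allele counts; the p-value sums all
#' configurations no more probable than the observed one). Offered as an
#' alternative to the chi-square convention; not the default.
#'
#' @param counts A [genotype_counts()].
#' @return List with `p`, `monomorphic`.
#' @export
hwe_exact_test <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$total
  nA <- 2L * counts$n_ins_ins + counts$n_ins_del
  if (nA == 0L || nA == 2L * n) return(list(p = 1, monomorphic = TRUE))
  hets <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  logp <- vapply(hets, function(h) {
    a <- (nA - h) %/% 2L
    b <- n - a - h
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, 0)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(counts$n_ins_del, hets)]
  list(p = min(1, sum(pr[pr <= obs + 1e-12])), monomorphic = FALSE)
}

#' Polymorphic information content
#'
#' `PIC = 1 - sum_i P_i^2 - sum_{i<j} 2 P_i^2 P_j^2` for allele frequencies
#' `P`, evaluated in closed form (`1 - s2 - (s2^2 - s4)` with
#' `s2 = sum P^2`, `s4 = sum P^4`). Maximum 0.375 for a biallelic marker.
#'
#' @param p Numeric vector of allele frequencies (>= 0, summing to 1).
#' @return PIC value at full precision.
#' @export
pic <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("pic: frequencies must be non-negative and sum to 1")
  }
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Population-genetic summary table for a set of breeds
#'
#' One row per (locus, breed): genotype and allele frequencies (percent),
#' Hardy-Weinberg chi-square p-value (printed `<0.01` below 0.01, `-` for
#' monomorphic samples) and PIC, with a polymorphism note (`low` below PIC
#' 0.25, `moderate` for 0.25-0.5).
#'
#' @param rows Data frame as returned by [read_genotype_counts()] /
#'   [rip_genotype_counts()] (columns `breed`, `locus`, `n_ins_ins`,
#'   `n_ins_del`, `n_del_del`).
#' @return An object of class `popgen_table`: a data frame with numeric
#'   columns at full precision plus formatted report columns.
#' @export
popgen_table <- function(rows) {
  if (nrow(rows) < 1) stop("popgen_table: need at least one row")
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    gc <- genotype_counts(rows$breed[i], rows$n_ins_ins[i], rows$n_ins_del[i],
                          rows$n_del_del[i])
    af <- allele_frequencies(gc)
    hw <- hwe_test(gc)
    pv <- pic(af)
    gf <- c(gc$n_ins_ins, gc$n_ins_del, gc$n_del_del) / gc$total
    data.frame(
      locus = if ("locus" %in% names(rows)) rows$locus[i] else "locus",
      breed = gc$breed, n = gc$total,
      geno_ins_ins = gf[1], geno_ins_del = gf[2], geno_del_del = gf[3],
      p_ins = af[["p_ins"]], p_del = af[["p_del"]],
      hwe_chi2 = hw$chi2, hwe_df = hw$df, hwe_p = hw$p,
      monomorphic = hw$monomorphic, pic = pv,
      geno_freq_pct = paste(fmt_num(100 * gf, 2), collapse = " "),
      allele_freq_pct = paste(fmt_num(100 * af, 2), collapse = " "),
      hwe_report = if (hw$monomorphic) "-" else if (hw$p < 0.01) "<0.01" else fmt_num(hw$p, 2),
      pic_report = fmt_num(pv, 3),
      polymorphism = if (pv < 0.25) "low polymorphism" else "moderate polymorphism",
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("popgen_table", "data.frame")
  out
}

#' @export
print.popgen_table <- function(x, ...) {
  d <- data.frame(locus = x$locus, breed = x$breed, n = x$n,
                  `geno % (+/+ +/- -/-)` = x$geno_freq_pct,
                  `allele % (+ -)` = x$allele_freq_pct,
                  HWE = x$hwe_report, PIC = x$pic_report,
                  note = x$polymorphism, check.names = FALSE)
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}
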
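# Genotype-phenotype association: one-way ANOVA with Tukey HSD across the
# insertion genotypes, compact letter displays at two alpha levels, and the
# age-at-100-kg adjustment hook.

#' Adjust recorded age to the age at 100 kg body weight
#'
#' Pluggable adjustment; the packaged default is the linear extrapolation
#' `adjusted_age = age + (100 - weight) * (age / weight) * c`. This default is
#' an explicit stand-in for the breeding-scheme adjustment formulae used by
#' national genetic evaluation programmes (which are scheme-specific);
#' every association report states which adjustment was applied.
#'
#' @param age_days Recorded age (days, > 0).
#' @param weight_kg Recorded body weight (kg, > 0).
#' @param c Extrapolation coefficient (default 1; 0 disables the adjustment).
#' @return Adjusted age in days.
#' @export
adjust_age_100kg <- function(age_days, weight_kg, c = 1) {
  if (any(age_days <= 0) || any(weight_kg <= 0)) {
    stop("adjust_age_100kg: age and weight must be positive")
  }
  age_days + (100 - weight_kg) * (age_days / weight_kg) * c
}

#' One-way ANOVA with Tukey HSD across genotype groups
#'
#' Standard one-way ANOVA (F and p), Tukey HSD adjusted pairwise p-values
#' via the studentized range with pooled within-group variance
#' (Tukey-Kramer for unbalanced groups, as provided by [stats::TukeyHSD()]),
#' and compact letter displays at `alpha = 0.05` (lowercase) and
#' `alpha = 0.01` (uppercase): groups sharing no letter differ at that level.
#'
#' @param table Data frame with a `genotype` column (or the column named by
#'   `group`) and the trait column.
#' @param trait Name of the trait column.
#' @param group Name of the grouping column (default `"genotype"`).
#' @param adjustment Optional note describing any trait adjustment applied.
#' @return An object of class `rip_assoc`: per-group `n`, `mean`, `sem`,
#'   letters at both levels; `F`, `df`, `p`; the Tukey table.
#' @export
anova_tukey <- function(table, trait, group = "genotype", adjustment = "none") {
  if (!trait %in% names(table)) stop("anova_tukey: no trait column '", trait, "'")
  g <- factor(table[[group]])
  y <- table[[trait]]
  ns <- table(g)
  if (length(ns) < 2) stop("anova_tukey: need at least two groups")
  small <- names(ns)[ns < 2]
  if (length(small)) {
    stop("anova_tukey: group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  groups <- levels(g)
  pmat <- matrix(1, length(groups), length(groups),
                 dimnames = list(groups, groups))
  # TukeyHSD names pairs "Lj-Li"; genotype labels contain '-', so rebuild the
  # names instead of splitting them
  cmb <- utils::combn(length(groups), 2)
  rn <- paste(groups[cmb[2, ]], groups[cmb[1, ]], sep = "-")
  idx <- match(rn, rownames(tk))
  for (j in seq_along(rn)) {
    a <- groups[cmb[1, j]]; b <- groups[cmb[2, j]]
    pmat[a, b] <- pmat[b, a] <- tk[idx[j], "p adj"]
  }
  means <- tapply(y, g, mean)
  ord <- order(means, decreasing = TRUE)
  let05 <- letter_display(pmat, 0.05, ord, lower = TRUE)
  let01 <- letter_display(pmat, 0.01, ord, lower = FALSE)
  res <- list(
    trait = trait, adjustment = adjustment,
    groups = data.frame(
      group = groups, n = as.integer(ns),
      mean = as.numeric(means),
      sem = as.numeric(tapply(y, g, stats::sd) / sqrt(ns)),
      letters_05 = let05[groups], letters_01 = let01[groups],
      stringsAsFactors = FALSE),
    F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
    p = an[1, "Pr(>F)"], tukey = tk)
  class(res) <- "rip_assoc"
  res
}

# Compact letter display from a symmetric matrix of adjusted p-values:
# letters are the maximal cliques of the "not significantly different" graph,
# ordered by the best group mean they contain. Invariant under relabeling.
letter_display <- function(pmat, alpha, ord, lower = TRUE) {
  k <- nrow(pmat)
  adj <- pmat > alpha
  diag(adj) <- TRUE
  cliques <- maximal_cliques(adj)
  # order cliques by the rank (in `ord`) of their best group
  rank_of <- match(seq_len(k), ord)
  cliques <- cliques[order(vapply(cliques, function(cl) min(rank_of[cl]), 0))]
  alphabet <- if (lower) letters else LETTERS
  out <- stats::setNames(rep("", k), rownames(pmat))
  for (i in seq_along(cliques)) {
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], alphabet[i])
  }
  out
}

# Bron-Kerbosch maximal clique enumeration on a small adjacency matrix
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- FALSE # neighbourhoods exclude the vertex itself
  res <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      res[[length(res) + 1L]] <<- sort(r)
      return()
    }
    for (v in p) {
      nb <- which(adj[v, ])
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(), seq_len(n), integer())
  res
}

#' @export
print.rip_assoc <- function(x, ...) {
  cat(sprintf("One-way ANOVA for '%s' (adjustment: %s)\n", x$trait, x$adjustment))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$df[1], x$df[2], x$F, x$p))
  print(summary_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.rip_assoc <- function(object, ...) {
  cat(sprintf("One-way ANOVA for '%s' (adjustment: %s)\n", object$trait,
              object$adjustment))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", object$df[1], object$df[2],
              object$F, object$p))
  print(summary_table(object), row.names = FALSE)
  cat("\nTukey HSD adjusted pairwise comparisons:\n")
  print(object$tukey)
  invisible(object)
}

#' Format an association result as report rows
#'
#' `mean +/- sem` strings (half-up rounding to 2 decimals) with compact
#' letter superscripts: lowercase for `alpha = 0.05`, uppercase for
#' `alpha = 0.01`. When every group shares a letter at a level, that level's
#' superscripts are omitted.
#'
#' @param result A `rip_assoc` from [anova_tukey()].
#' @return Data frame with `group`, `n`, `value` (formatted string).
#' @export
summary_table <- function(result) {
  stopifnot(inherits(result, "rip_assoc"))
  g <- result$groups
  drop05 <- length(unique(g$letters_05)) == 1
  drop01 <- length(unique(g$letters_01)) == 1
  val <- vapply(seq_len(nrow(g)), function(i) {
    sup <- paste0(if (drop05) "" else g$letters_05[i],
                  if (drop01) "" else g$letters_01[i])
    paste0(fmt_num(g$mean[i], 2), " ± ", fmt_num(g$sem[i], 2),
           if (nzchar(sup)) paste0(" ", sup) else "")
  }, "")
  data.frame(group = g$group, n = g$n, value = val, stringsAsFactors = FALSE)
}
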
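# Relative expression (2^-ddCt) and dual-luciferase relative reporter
# activity, with group comparisons.
#
# Statistical tests are performed on the log scale (ddCt, log ratios), where
# normality is plausible; results are displayed as fold changes.

#' Relative expression by the 2^-ddCt method
#'
#' Per-sample `dCt = ct_target - ct_reference`; `ddCt = dCt - mean(dCt)` of
#' the calibrator group (Livak convention: the calibrator group's mean fold
#' is exactly 1, individual calibrator samples scatter around 1); per-sample
#' fold change `2^-ddCt`. Groups are compared on the ddCt scale by one-way
#' ANOVA with Tukey HSD (3+ groups) or a two-sided t-test (2 groups).
#'
#' @param table Data frame with columns `sample_id`, `group`, `ct_target`,
#'   `ct_reference` (as from [make_ct_table()]).
#' @param calibrator Calibrator group label.
#' @return An object of class `rip_expr`: per-sample values, per-group mean
#'   fold and SEM, pairwise p-values.
#' @export
ddct <- function(table, calibrator) {
  need <- c("group", "ct_target", "ct_reference")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("ddct: missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(table$ct_target)) || any(!is.finite(table$ct_reference))) {
    stop("ddct: missing or non-finite Ct value")
  }
  if (!calibrator %in% table$group) {
    stop("ddct: calibrator group '", calibrator, "' not present")
  }
  d <- table
  d$dct <- d$ct_target - d$ct_reference
  cal_mean <- mean(d$dct[d$group == calibrator])
  d$ddct <- d$dct - cal_mean
  d$fold <- 2^-d$ddct
  groups <- unique(d$group)
  gstat <- do.call(rbind, lapply(groups, function(g) {
    f <- d$fold[d$group == g]
    data.frame(group = g, n = length(f), mean_fold = mean(f),
               sem_fold = stats::sd(f) / sqrt(length(f)),
               stringsAsFactors = FALSE)
  }))
  pw <- pairwise_log_tests(d$ddct, d$group)
  structure(list(samples = d, groups = gstat, calibrator = calibrator,
                 pairwise = pw$table, method = pw$method),
            class = "rip_expr")
}

#' Dual-luciferase relative reporter activity
#'
#' Per-well `ratio = firefly / renilla`; relative activity is the ratio
#' normalised to the control construct's mean ratio (so the control's mean
#' relative activity is exactly 1), computed within each cell line when a
#' `cell_line` column is present. Constructs are compared pairwise by
#' two-sided t-tests on log ratios.
#'
#' @param table Data frame with columns `construct`, `firefly`, `renilla`
#'   and optionally `cell_line`.
#' @param control Control construct label.
#' @return An object of class `rip_luc`: per-well values, per-construct
#'   summaries, pairwise p-values per cell line.
#' @export
luciferase_relative <- function(table, control) {
  need <- c("construct", "firefly", "renilla")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("luciferase_relative: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(table$renilla <= 0)) {
    stop("luciferase_relative: renilla readings must be positive")
  }
  if (!control %in% table$construct) {
    stop("luciferase_relative: control construct '", control, "' not present")
  }
  d <- table
  if (!"cell_line" %in% names(d)) d$cell_line <- "cells"
  d$ratio <- d$firefly / d$renilla
  out_samples <- list(); out_groups <- list(); out_pw <- list()
  for (cl in unique(d$cell_line)) {
    dd <- d[d$cell_line == cl, ]
    ctrl_mean <- mean(dd$ratio[dd$construct == control])
    dd$relative <- dd$ratio / ctrl_mean
    gs <- do.call(rbind, lapply(unique(dd$construct), function(cs) {
      r <- dd$relative[dd$construct == cs]
      data.frame(cell_line = cl, construct = cs, n = length(r),
                 mean_relative = mean(r), sem_relative = stats::sd(r) / sqrt(length(r)),
                 stringsAsFactors = FALSE)
    }))
    pw <- pairwise_log_tests(log(dd$ratio), dd$construct, always_t = TRUE)
    pw$table$cell_line <- cl
    out_samples[[cl]] <- dd; out_groups[[cl]] <- gs; out_pw[[cl]] <- pw$table
  }
  structure(list(samples = do.call(rbind, out_samples),
                 groups = do.call(rbind, out_groups),
                 pairwise = do.call(rbind, out_pw), control = control),
            class = "rip_luc")
}

# pairwise group comparisons on a log-scale response: Tukey HSD when 3+
# groups (unless always_t), two-sided Welch t-tests otherwise
pairwise_log_tests <- function(y, group, always_t = FALSE) {
  g <- factor(group)
  k <- nlevels(g)
  lev <- levels(g)
  if (k < 2) {
    return(list(table = data.frame(group1 = character(), group2 = character(),
                                   p = numeric()), method = "none"))
  }
  if (k >= 3 && !always_t) {
    fit <- stats::aov(y ~ g)
    tk <- stats::TukeyHSD(fit)$g
    cmb <- utils::combn(k, 2)
    rn <- paste(lev[cmb[2, ]], lev[cmb[1, ]], sep = "-")
    tab <- data.frame(group1 = lev[cmb[1, ]], group2 = lev[cmb[2, ]],
                      p = tk[match(rn, rownames(tk)), "p adj"],
                      stringsAsFactors = FALSE)
    return(list(table = tab, method = "anova_tukey"))
  }
  cmb <- utils::combn(k, 2)
  tab <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    a <- y[g == lev[cmb[1, j]]]; b <- y[g == lev[cmb[2, j]]]
    # degenerate zero-variance data: identical means are indistinguishable
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) {
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    })
    data.frame(group1 = lev[cmb[1, j]], group2 = lev[cmb[2, j]], p = p,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, method = "t_test")
}

#' @export
print.rip_expr <- function(x, ...) {
  cat(sprintf("2^-ddCt relative expression (calibrator: %s)\n", x$calibrator))
  g <- x$groups
  g$mean_fold <- round_half_up(g$mean_fold, 3)
  g$sem_fold <- round_half_up(g$sem_fold, 3)
  print.data.frame(g, row.names = FALSE)
  cat(sprintf("Pairwise comparisons on ddCt (%s):\n", x$method))
  pw <- x$pairwise; pw$p <- signif(pw$p, 3)
  print.data.frame(pw, row.names = FALSE)
  invisible(x)
}

#' @export
print.rip_luc <- function(x, ...) {
  cat(sprintf("Dual-luciferase relative activity (control: %s)\n", x$control))
  g <- x$groups
  g$mean_relative <- round_half_up(g$mean_relative, 3)
  g$sem_relative <- round_half_up(g$sem_relative, 3)
  print.data.frame(g, row.names = FALSE)
  cat("Pairwise t-tests on log ratios:\n")
  pw <- x$pairwise; pw$p <- signif(pw$p, 3)
  print.data.frame(pw, row.names = FALSE)
  invisible(x)
}
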
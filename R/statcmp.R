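# Group-comparison statistics with a normality/homoscedasticity gate:
# ANOVA when every group is compatible with normal, equal-variance data,
# Kruskal-Wallis with Dunn pairwise comparisons otherwise (Mann-Whitney
# for two groups).

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("`groups` must be a list of at least two samples")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 3L))
    stopf("every group needs n >= 3 (got %s)", paste(ns, collapse = ", "))
  lapply(groups, as.numeric)
}

#' Choose the omnibus test for a set of groups
#'
#' ANOVA is selected iff every group passes a Shapiro-Wilk normality test
#' and the set passes a Levene homoscedasticity test at level `alpha`;
#' otherwise the nonparametric Kruskal-Wallis branch is used. A group
#' with zero variance cannot be normal and routes to the nonparametric
#' branch.
#'
#' @param groups named list of numeric samples, each with n >= 3.
#' @param alpha gate level (default 0.05).
#' @param center centering statistic of the Levene test (`"median"` is
#'   the robust Brown-Forsythe variant).
#' @return `"ANOVA"` or `"KW"`, with attributes `normality_p` (per
#'   group) and `levene_p`.
#' @export
choose_test <- function(groups, alpha = 0.05,
                        center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- check_groups(groups)
  norm_p <- vapply(groups, function(x) {
    if (pop_sd(x) == 0) return(0)  # degenerate: reject normality
    if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }, numeric(1))
  vals <- unlist(groups)
  grp <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  lev_p <- if (any(vapply(groups, pop_sd, numeric(1)) == 0)) 0 else
    car::leveneTest(vals ~ grp,
                    center = if (center == "median") stats::median else mean)[1, "Pr(>F)"]
  out <- if (all(norm_p > alpha) && lev_p > alpha) "ANOVA" else "KW"
  attr(out, "normality_p") <- norm_p
  attr(out, "levene_p") <- lev_p
  out
}

#' Dunn's rank-based pairwise comparisons after Kruskal-Wallis
#'
#' For groups i, j the statistic is
#' `z = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i + 1/n_j))`
#' with tie correction `T = sum(t^3 - t) / (12 (N - 1))` over tie groups;
#' two-sided p-values from the normal distribution, adjusted for
#' multiplicity (Holm by default).
#'
#' @param groups named list of numeric samples.
#' @param p_adjust adjustment method passed to [stats::p.adjust()]
#'   (`"none"` for the unadjusted comparisons).
#' @return data.frame with columns `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_test <- function(groups, p_adjust = "holm") {
  groups <- check_groups(groups)
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  rbar <- tapply(r, rep(seq_len(k), ns), mean)
  ties <- table(vals)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    z <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / ns[i] + 1 / ns[j]))
    out[[length(out) + 1L]] <- data.frame(
      group1 = names(groups)[i], group2 = names(groups)[j],
      z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))))
  }
  out <- do.call(rbind, out)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Compare groups with the gated omnibus test plus pairwise follow-up
#'
#' Runs [choose_test()] and then either one-way ANOVA with pairwise
#' pooled-SD t tests, or Kruskal-Wallis with Dunn pairwise comparisons
#' (exact Mann-Whitney for exactly two groups on the nonparametric
#' branch). Pairwise p-values carry a multiplicity adjustment (Holm).
#'
#' @param groups named list of numeric samples, each n >= 3.
#' @param alpha gate level for the normality/homoscedasticity checks.
#' @param p_adjust multiplicity adjustment for pairwise comparisons.
#' @param force optional `"ANOVA"` or `"KW"` to bypass the gate.
#' @return object of class `group_comparison`: chosen `test`,
#'   `omnibus_stat`, `omnibus_p`, `pairwise` data.frame (`group1`,
#'   `group2`, `p`, `p_adj`, and `z` on the Dunn branch), plus the gate
#'   diagnostics.
#' @export
compare_groups <- function(groups, alpha = 0.05, p_adjust = "holm",
                           force = NULL) {
  groups <- check_groups(groups)
  chosen <- if (is.null(force)) choose_test(groups, alpha) else
    match.arg(force, c("ANOVA", "KW"))
  vals <- unlist(groups)
  ns <- vapply(groups, length, integer(1))
  grp <- factor(rep(names(groups), ns), levels = names(groups))
  k <- length(groups)
  if (identical(pop_sd(vals), 0)) {
    # no variation anywhere: no evidence against the null
    omnibus_stat <- 0; omnibus_p <- 1
    pw <- expand_pairs(names(groups))
    pw$p <- 1; pw$p_adj <- 1
  } else if (chosen == "ANOVA") {
    fit <- stats::aov(vals ~ grp)
    an <- summary(fit)[[1]]
    omnibus_stat <- an[1, "F value"]; omnibus_p <- an[1, "Pr(>F)"]
    pt <- stats::pairwise.t.test(vals, grp, p.adjust.method = "none")$p.value
    pw <- expand_pairs(names(groups))
    pw$p <- vapply(seq_len(nrow(pw)), function(r) {
      pick_pair_p(pt, pw$group1[r], pw$group2[r])
    }, numeric(1))
    pw$p_adj <- stats::p.adjust(pw$p, method = p_adjust)
  } else {
    kw <- stats::kruskal.test(vals, grp)
    omnibus_stat <- unname(kw$statistic); omnibus_p <- kw$p.value
    if (k == 2L) {
      mw <- stats::wilcox.test(groups[[1]], groups[[2]], exact = TRUE)
      pw <- data.frame(group1 = names(groups)[1], group2 = names(groups)[2],
                       p = mw$p.value, p_adj = mw$p.value)
    } else {
      dn <- dunn_test(groups, p_adjust = p_adjust)
      pw <- dn[, c("group1", "group2", "z", "p", "p_adj")]
    }
  }
  structure(list(test = as.character(chosen),
                 omnibus_stat = omnibus_stat, omnibus_p = omnibus_p,
                 pairwise = pw,
                 normality_p = attr(chosen, "normality_p"),
                 levene_p = attr(chosen, "levene_p"),
                 alpha = alpha, n = ns),
            class = "group_comparison")
}

expand_pairs <- function(nm) {
  k <- length(nm)
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    out[[length(out) + 1L]] <- data.frame(group1 = nm[i], group2 = nm[j])
  do.call(rbind, out)
}

pick_pair_p <- function(pt, g1, g2) {
  if (g1 %in% rownames(pt) && g2 %in% colnames(pt) && !is.na(pt[g1, g2]))
    return(pt[g1, g2])
  if (g2 %in% rownames(pt) && g1 %in% colnames(pt) && !is.na(pt[g2, g1]))
    return(pt[g2, g1])
  NA_real_
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison (%s): omnibus p = %.4g (stat %.4g)\n",
              x$test, x$omnibus_p, x$omnibus_stat))
  if (!is.null(x$pairwise) && nrow(x$pairwise)) {
    cat("pairwise (adjusted):\n")
    for (r in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s: p_adj = %.4g\n", x$pairwise$group1[r],
                  x$pairwise$group2[r], x$pairwise$p_adj[r]))
  }
  invisible(x)
}

#' Read a long-format group CSV (unit, group, value)
#'
#' @param path CSV file with columns `group` and `value` (extra columns
#'   such as `unit` are carried along but unused).
#' @return named list of numeric samples, suitable for
#'   [compare_groups()].
#' @export
read_group_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "value") %in% names(df)))
    stopf("CSV must have `group` and `value` columns")
  split(as.numeric(df$value), df$group)
}
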
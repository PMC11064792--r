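#' Aligned rank transform alignment for one effect
#'
#' Subtracts the estimated contributions of all other effects (computed from
#' unweighted cell means) from each observation, leaving the residual plus
#' the estimated effect of interest; the aligned values are then ranked and
#' analysed with a parametric ANOVA.
#'
#' @param y Response vector.
#' @param A,B Factors.
#' @param effect One of `"A"`, `"B"`, `"AB"`.
#' @return Aligned response vector.
#' @keywords internal
art_align <- function(y, A, B, effect = c("A", "B", "AB")) {
  effect <- match.arg(effect)
  A <- factor(A); B <- factor(B)
  cm <- tapply(y, list(A, B), mean)
  if (any(is.na(cm)))
    stop("design error: empty cell(s) in the A x B layout")
  grand <- mean(cm)
  Am <- rowMeans(cm); Bm <- colMeans(cm)
  cell <- cm[cbind(A, B)]
  resid <- y - cell
  est <- switch(effect,
                A = Am[A] - grand,
                B = Bm[B] - grand,
                AB = cell - Am[A] - Bm[B] + grand)
  as.numeric(resid + est)
}

# F, p and partial eta^2 of `term` in a rank ANOVA, type III SS with
# sum-to-zero contrasts (reduces to the plain ANOVA when B has one level)
.rank_anova_effect <- function(r, A, B, term) {
  if (nlevels(B) < 2 && term != "A")
    stop("factor B has a single level; only the A effect is estimable")
  if (nlevels(B) < 2) {
    fit <- stats::lm(r ~ A)
    tab <- stats::anova(fit)
    ss_eff <- tab["A", "Sum Sq"]; ss_res <- tab["Residuals", "Sum Sq"]
    return(list(F = tab["A", "F value"], p = tab["A", "Pr(>F)"],
                df1 = tab["A", "Df"], df2 = tab["Residuals", "Df"],
                partial_eta2 = ss_eff / (ss_eff + ss_res)))
  }
  fit <- stats::lm(r ~ A * B,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  tab <- car::Anova(fit, type = 3)
  row <- switch(term, A = "A", B = "B", AB = "A:B")
  ss_eff <- tab[row, "Sum Sq"]; ss_res <- tab["Residuals", "Sum Sq"]
  list(F = tab[row, "F value"], p = tab[row, "Pr(>F)"],
       df1 = tab[row, "Df"], df2 = tab["Residuals", "Df"],
       partial_eta2 = ss_eff / (ss_eff + ss_res))
}

#' Nonparametric two-way ANOVA via the aligned rank transform
#'
#' For each effect (two main effects and their interaction), the response is
#' aligned for that effect, mid-ranked (average ranks for ties), and a
#' fixed-effects factorial ANOVA (type III sums of squares, sum-to-zero
#' contrasts) is run on the ranks; only that effect's statistic is reported.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`. F statistics
#' are invariant to strictly monotone transforms of the response.
#'
#' @param table data.frame with the response and both factor columns.
#' @param response Response column name (e.g. `"trt_s"`).
#' @param factor1,factor2 Factor column names (default `"group"`,
#'   `"age_band"`).
#' @return data.frame of class `art_anova`: one row per effect with
#'   `effect, df1, df2, F, p, partial_eta2`.
#' @export
art_anova_two_way <- function(table, response, factor1 = "group",
                              factor2 = "age_band") {
  y <- table[[response]]
  A <- factor(table[[factor1]]); B <- factor(table[[factor2]])
  if (nlevels(A) < 2) stop("factor '", factor1, "' needs >= 2 levels")
  effects <- if (nlevels(B) >= 2) c("A", "B", "AB") else "A"
  rows <- lapply(effects, function(e) {
    r <- rank(art_align(y, A, B, e))
    res <- .rank_anova_effect(r, A, B, e)
    lab <- switch(e, A = factor1, B = factor2,
                  AB = paste0(factor1, ":", factor2))
    data.frame(effect = lab, df1 = res$df1, df2 = res$df2, F = res$F,
               p = res$p, partial_eta2 = res$partial_eta2,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("art_anova", "data.frame"))
}

#' ART-C pairwise contrasts with Bonferroni correction
#'
#' Post-hoc contrasts on a factor after an aligned rank transform: the
#' response is aligned for the contrasted factor; for each pair of levels the
#' aligned values of the two levels are re-ranked jointly and compared with a
#' pooled-variance t test. p values are Bonferroni-adjusted over the family
#' of all pairwise comparisons within the factor. Cohen's d is computed on
#' the raw response (first level minus second level; factor levels are
#' honoured, so an `ASD, TD` factor yields ASD - TD).
#'
#' @param table data.frame with response and factor columns.
#' @param response Response column name.
#' @param factor Factor to contrast.
#' @param other The other design factor (used for alignment); NULL collapses
#'   to a single pseudo-level.
#' @return data.frame of class `art_posthoc` with one row per contrast:
#'   `contrast, t, df, p_adjusted, cohens_d`.
#' @export
artc_posthoc <- function(table, response, factor = "group",
                         other = "age_band") {
  y <- table[[response]]
  A <- factor(table[[factor]])
  if (nlevels(A) < 2) stop("factor '", factor, "' needs >= 2 levels")
  B <- if (is.null(other) || is.null(table[[other]]))
    factor(rep("all", length(y))) else factor(table[[other]])
  aligned <- if (nlevels(B) >= 2) art_align(y, A, B, "A") else y
  pairs <- utils::combn(levels(A), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    sel <- A %in% pr
    g <- droplevels(A[sel])
    rr <- rank(aligned[sel])
    tt <- stats::t.test(rr[g == pr[1]], rr[g == pr[2]], var.equal = TRUE)
    d <- cohens_d(y[sel][g == pr[1]], y[sel][g == pr[2]])
    data.frame(contrast = paste(pr[1], "-", pr[2]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_adjusted = min(1, tt$p.value * length(pairs)),
               cohens_d = d, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("art_posthoc", "data.frame"))
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_p`,
#' `s_p = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @return Unitless effect size (sign follows `a - b`).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs >= 2 observations")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("degenerate samples: pooled sd is 0")
  (mean(a) - mean(b)) / sp
}

#' Spearman correlation screen between metrics and clinical scores
#'
#' Spearman's rho (average-rank ties, t-approximation p values) for every
#' metric-by-score pair, with no multiplicity adjustment. Pairs with fewer
#' than 4 complete observations are reported as NA.
#'
#' @param features data.frame containing metric columns and an id column.
#' @param scores data.frame containing score columns and the same id column.
#' @param metrics Character vector of metric column names.
#' @param score_cols Character vector of score column names.
#' @param by Id column used for the join (default `"participant_id"` in
#'   `features`, `"id"` in `scores`).
#' @return List of matrices `rho`, `p`, `n` (metrics x scores).
#' @export
spearman_matrix <- function(features, scores,
                            metrics = c("trt_s", "roa_deg", "symmetry"),
                            score_cols = setdiff(names(scores), "id"),
                            by = c("participant_id", "id")) {
  merged <- merge(features, scores, by.x = by[1], by.y = by[2])
  rho <- p <- n <- matrix(NA_real_, length(metrics), length(score_cols),
                          dimnames = list(metrics, score_cols))
  for (m in metrics) for (s in score_cols) {
    ok <- stats::complete.cases(merged[[m]], merged[[s]])
    n[m, s] <- sum(ok)
    if (sum(ok) >= 4) {
      ct <- suppressWarnings(
        stats::cor.test(merged[[m]][ok], merged[[s]][ok],
                        method = "spearman", exact = FALSE))
      rho[m, s] <- unname(ct$estimate)
      p[m, s] <- ct$p.value
    }
  }
  list(rho = rho, p = p, n = n)
}

#' Pearson chi-square test of independence
#'
#' Expected counts from the margins, no continuity correction,
#' `df = (r-1)(c-1)`.
#'
#' @param counts Integer matrix (r x c contingency table).
#' @return List with `chi2`, `p`, `df`, `expected`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(res$expected <= 0)) stop("degenerate table: non-positive expected count")
  list(chi2 = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter), expected = res$expected)
}
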
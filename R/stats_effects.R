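#' Repeated-measures ANOVA with partial eta-squared
#'
#' Classical univariate within-subject ANOVA for one or two within factors,
#' with subject as blocking factor and a separate effect-by-subject
#' interaction error term per effect. Degrees of freedom are uncorrected (no
#' sphericity correction by default); partial eta-squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error term.
#'
#' @param data either a wide numeric matrix/data.frame (`subjects x
#'   conditions`, one within factor named from the column names), or a long
#'   data.frame with columns named by `dv`, `subject` and `within`.
#' @param dv,subject column names in long format (defaults `"value"`,
#'   `"subject"`).
#' @param within character vector of one or two within-factor column names
#'   in long format (default `"condition"`).
#' @return An object of class `"rm_anova"`: a data.frame with one row per
#'   effect and columns `effect`, `F`, `df_num`, `df_den`, `p`,
#'   `partial_eta_sq`, `ss_effect`, `ss_error`.
#' @details The design must be complete and balanced (every subject measured
#'   in every cell); missing cells are an error — no imputation is done.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(1, 3, 3, 6))
#' rm_anova(m)
#' @export
rm_anova <- function(data, dv = "value", subject = "subject",
                     within = "condition") {
  if (is.matrix(data) || (is.data.frame(data) &&
                          all(vapply(data, is.numeric, logical(1))) &&
                          !all(c(dv, subject) %in% names(data)))) {
    m <- as.matrix(data)
    if (is.null(colnames(m)))
      colnames(m) <- paste0("c", seq_len(ncol(m)))
    long <- data.frame(
      value = as.vector(m),
      subject = factor(rep(seq_len(nrow(m)), times = ncol(m))),
      condition = factor(rep(colnames(m), each = nrow(m))))
    dv <- "value"; subject <- "subject"; within <- "condition"
    data <- long
  }
  stopifnot(is.data.frame(data), dv %in% names(data),
            subject %in% names(data), all(within %in% names(data)),
            length(within) %in% 1:2)
  if (anyNA(data[[dv]])) stop("missing values in the response; no imputation")
  df <- data.frame(value = data[[dv]],
                   subject = factor(data[[subject]]))
  for (i in seq_along(within)) df[[within[i]]] <- factor(data[[within[i]]])
  cells <- table(df[c("subject", within)])
  if (any(cells != 1L))
    stop("design not complete/balanced: every subject must appear exactly ",
         "once per cell (missing or duplicated cells found)")
  if (nlevels(df$subject) < 2L) stop("need >= 2 subjects")

  rhs <- paste(within, collapse = " * ")
  err <- paste0("Error(subject/(", rhs, "))")
  form <- stats::as.formula(paste("value ~", rhs, "+", err))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)

  # aov leaves ~1e-30 rounding noise in exactly-degenerate strata; treat
  # sums of squares below a relative tolerance as zero
  ss_tot <- sum((df$value - mean(df$value))^2)
  tol <- 1e-10 * max(ss_tot, .Machine$double.eps)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms <- trimws(rownames(tab))
    res_i <- which(terms == "Residuals")
    if (!length(res_i)) next
    ss_err <- tab[res_i, "Sum Sq"]
    df_den <- tab[res_i, "Df"]
    if (ss_err < tol) ss_err <- 0
    for (i in setdiff(seq_len(nrow(tab)), res_i)) {
      eff <- terms[i]
      ss_eff <- tab[i, "Sum Sq"]
      df_num <- tab[i, "Df"]
      if (ss_eff < tol) ss_eff <- 0
      Fv <- if (ss_eff == 0) 0
            else if (ss_err == 0) Inf
            else (ss_eff / df_num) / (ss_err / df_den)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff, F = Fv, df_num = df_num, df_den = df_den,
        p = if (is.infinite(Fv)) 0
            else stats::pf(Fv, df_num, df_den, lower.tail = FALSE),
        partial_eta_sq = if (ss_eff == 0) 0
                         else ss_eff / (ss_eff + ss_err),
        ss_effect = ss_eff, ss_error = ss_err)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Paired follow-up t-tests with Bonferroni correction and Cohen's d
#'
#' Paired t-tests for a set of condition contrasts, Bonferroni-corrected for
#' the family size, with Cohen's d computed on the paired differences
#' (`d = mean(diff) / sd(diff)`).
#'
#' @param data wide numeric matrix/data.frame, subjects in rows and
#'   conditions in (named) columns.
#' @param comparisons list of length-2 character/index vectors naming the
#'   condition pairs to test; default all pairwise comparisons.
#' @param m Bonferroni family size; default `length(comparisons)`.
#' @return data.frame with one row per contrast: `a`, `b`, `t`, `df`,
#'   `p_raw`, `p_bonf`, `cohens_d`, `mean_diff`.
#' @export
paired_tests <- function(data, comparisons = NULL, m = NULL) {
  x <- as.matrix(data)
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  if (nrow(x) < 2L) stop("need >= 2 paired observations")
  if (anyNA(x)) stop("missing values in paired data")
  if (is.null(comparisons))
    comparisons <- utils::combn(colnames(x), 2L, simplify = FALSE)
  if (is.null(m)) m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    a <- x[, cmp[[1L]]]; b <- x[, cmp[[2L]]]
    d <- a - b
    if (stats::sd(d) == 0) {
      # degenerate: constant differences (t.test refuses these)
      if (mean(d) == 0) { tv <- 0; p <- 1; cd <- 0 }
      else { tv <- sign(mean(d)) * Inf; p <- 0; cd <- tv }
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      tv <- unname(tt$statistic); p <- tt$p.value
      cd <- mean(d) / stats::sd(d)
    }
    data.frame(a = as.character(cmp[[1L]]), b = as.character(cmp[[2L]]),
               t = tv, df = length(d) - 1L, p_raw = p,
               p_bonf = min(1, m * p),
               cohens_d = cd,
               mean_diff = mean(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson or Spearman correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] used to relate fatigue measures
#' (e.g. force slope vs EMG slope, or vs perceived-exertion ratings, where
#' the rank-based Spearman form is the appropriate choice).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r` (correlation estimate), `p`, `n`, `method`.
#' @export
correlations <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined: zero variance in x or y")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}
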
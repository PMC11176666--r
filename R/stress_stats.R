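#' Proportional change score between two sample points
#'
#' The change of a measurement from reference point j to point i expressed
#' as a signed proportion of the reference: `(x_i - x_j) / x_j`. A value of
#' 0.10 means a 10% increase over the reference sample.
#'
#' @param x_i Value(s) at the later / compared sample point.
#' @param x_j Value(s) at the reference sample point; must be nonzero.
#' @param na_undefined If `TRUE`, a zero reference yields `NA` with a
#'   warning instead of an error, so callers can treat the dyad or subject
#'   as missing.
#' @return Numeric vector of signed proportions.
#' @export
change_score <- function(x_i, x_j, na_undefined = FALSE) {
  stopifnot(length(x_i) == length(x_j) || length(x_i) == 1 || length(x_j) == 1)
  zero <- !is.na(x_j) & x_j == 0
  if (any(zero)) {
    if (!na_undefined) {
      stop("undefined change score: reference value is zero", call. = FALSE)
    }
    warning(sum(zero), " change score(s) undefined (zero reference); set NA",
            call. = FALSE)
  }
  out <- (x_i - x_j) / x_j
  out[rep_len(zero, length(out))] <- NA_real_
  out
}

## orthonormal contrasts spanning the space orthogonal to the constant
orthonormal_contrasts <- function(t) {
  C <- stats::contr.helmert(t)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Split-plot (two-way mixed) repeated-measures ANOVA
#'
#' One within-subjects factor (e.g., Time) crossed with one between-subjects
#' factor (e.g., HR/LR class or dyad type), every unit measured at every
#' within level. Produces the classical univariate F tests for the within
#' main effect, the between main effect, and their interaction, with
#' partial eta-squared per effect, Mauchly's test of sphericity on the
#' within-subject covariance, and the Greenhouse-Geisser epsilon. When
#' Mauchly's p falls below `gg_alpha` and the within factor has more than
#' two levels, the within and interaction degrees of freedom are scaled by
#' epsilon and the corrected p-values are reported.
#'
#' With `between = NULL` the design collapses to a one-way repeated-measures
#' ANOVA (within effect only).
#'
#' Units with any missing value are dropped listwise with a warning.
#'
#' @param data Long-format data frame.
#' @param value,unit,within,between Column names (strings) for the
#'   measurement, the experimental unit, the within factor, and the
#'   between factor (`NULL` for none).
#' @param gg_alpha Mauchly significance level that triggers the
#'   Greenhouse-Geisser correction (default 0.05).
#' @return An `anova_table`: data frame with one row per effect
#'   (`within`, `between`, `within:between`) carrying `SS, df_num, df_den,
#'   F, p, partial_eta_sq, p_gg`, with attributes `mauchly_W`, `mauchly_p`,
#'   `epsilon`, `gg_applied`, `n_units`, `within_levels`.
#' @export
mixed_anova <- function(data, value = "value", unit = "unit",
                        within = "within", between = NULL,
                        gg_alpha = 0.05) {
  v <- data[[value]]; u <- as.character(data[[unit]])
  wl <- as.character(data[[within]])
  b <- if (is.null(between)) rep("all", length(v)) else
    as.character(data[[between]])
  keep_na <- !is.na(v)
  if (!all(keep_na)) {
    bad_units <- unique(u[!keep_na])
    warning("dropping unit(s) with missing values (listwise): ",
            paste(bad_units, collapse = ", "), call. = FALSE)
    drop <- u %in% bad_units
    v <- v[!drop]; u <- u[!drop]; wl <- wl[!drop]; b <- b[!drop]
  }
  w_levels <- unique(wl); t <- length(w_levels)
  units <- unique(u); n <- length(units)
  tab <- table(u, wl)
  if (any(tab != 1L)) {
    stop("unbalanced design: every unit must be observed exactly once at ",
         "every within level", call. = FALSE)
  }
  unit_group <- tapply(b, u, function(x) unique(x))
  if (any(lengths(unit_group) != 1)) {
    stop("each unit must belong to exactly one between level", call. = FALSE)
  }
  unit_group <- unlist(unit_group)[units]
  g_levels <- unique(unit_group); g <- length(g_levels)
  n_k <- table(factor(unit_group, levels = g_levels))
  if (any(n_k < 2)) {
    stop("every between level needs at least 2 units", call. = FALSE)
  }

  ## wide unit x within matrix of responses
  Y <- matrix(NA_real_, n, t, dimnames = list(units, w_levels))
  Y[cbind(match(u, units), match(wl, w_levels))] <- v

  m <- mean(Y)
  m_s <- rowMeans(Y)                                  # subject means
  m_t <- colMeans(Y)                                  # within-level means
  m_k <- tapply(m_s, unit_group, mean)[g_levels]      # group means
  cell <- rowsum(Y, unit_group)[g_levels, , drop = FALSE] /
    as.vector(n_k)                                    # group x within means

  ss_total <- sum((Y - m)^2)
  ss_between_subj <- t * sum((m_s - m)^2)
  ss_group <- t * sum(as.vector(n_k) * (m_k - m)^2)
  ss_err_between <- ss_between_subj - ss_group
  ss_time <- n * sum((m_t - m)^2)
  ss_inter <- sum(as.vector(n_k) *
                  (cell - outer(m_k, rep(1, t)) -
                   outer(rep(1, g), m_t) + m)^2)
  ss_err_within <- ss_total - ss_between_subj - ss_time - ss_inter

  df_group <- g - 1; df_err_b <- n - g
  df_time <- t - 1; df_inter <- (g - 1) * (t - 1)
  df_err_w <- (n - g) * (t - 1)

  ## sphericity of the within-subject covariance (pooled over groups)
  if (t > 2) {
    resid <- Y - cell[match(unit_group, g_levels), , drop = FALSE]
    S <- crossprod(resid) / (n - g)
    C <- orthonormal_contrasts(t)
    Sc <- t(C) %*% S %*% C
    tr <- sum(diag(Sc))
    if (tr <= .Machine$double.eps) {
      eps <- 1; mauchly_W <- NA_real_; mauchly_p <- NA_real_
    } else {
      eps <- tr^2 / ((t - 1) * sum(Sc * Sc))
      p_dim <- t - 1
      mauchly_W <- det(Sc) / (tr / p_dim)^p_dim
      ## Box's second-order chi-square approximation to the null of W
      n_d <- n - g
      chi_df <- p_dim * (p_dim + 1) / 2 - 1
      rho <- 1 - (2 * p_dim^2 + p_dim + 2) / (6 * p_dim * n_d)
      w2 <- (p_dim + 2) * (p_dim - 1) * (p_dim - 2) *
        (2 * p_dim^3 + 6 * p_dim^2 + 3 * p_dim + 2) /
        (288 * (n_d * p_dim * rho)^2)
      mauchly_p <- if (mauchly_W > 0) {
        z <- -n_d * rho * log(mauchly_W)
        pr1 <- stats::pchisq(z, chi_df, lower.tail = FALSE)
        pr2 <- stats::pchisq(z, chi_df + 4, lower.tail = FALSE)
        pr1 + w2 * (pr2 - pr1)
      } else 0
    }
  } else {
    eps <- 1; mauchly_W <- 1; mauchly_p <- NA_real_
  }
  gg_applied <- t > 2 && !is.na(mauchly_p) && mauchly_p < gg_alpha

  f_of <- function(ss_e, df1, ss_err, df2) {
    if (ss_e <= .Machine$double.eps^0.5 * max(1, ss_total)) return(0)
    if (ss_err <= 0) return(Inf)
    (ss_e / df1) / (ss_err / df2)
  }
  p_of <- function(F, df1, df2) {
    if (F == 0) return(1)
    stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  peta <- function(ss_e, ss_err) {
    if (ss_e + ss_err <= 0) return(0)
    ss_e / (ss_e + ss_err)
  }

  F_time <- f_of(ss_time, df_time, ss_err_within, df_err_w)
  F_inter <- f_of(ss_inter, df_inter, ss_err_within, df_err_w)
  F_group <- f_of(ss_group, df_group, ss_err_between, df_err_b)

  rows <- data.frame(
    effect = c("within", "between", "within:between"),
    SS = c(ss_time, ss_group, ss_inter),
    df_num = c(df_time, df_group, df_inter),
    df_den = c(df_err_w, df_err_b, df_err_w),
    F = c(F_time, F_group, F_inter),
    p = c(p_of(F_time, df_time, df_err_w),
          p_of(F_group, df_group, df_err_b),
          p_of(F_inter, df_inter, df_err_w)),
    partial_eta_sq = c(peta(ss_time, ss_err_within),
                       peta(ss_group, ss_err_between),
                       peta(ss_inter, ss_err_within)),
    stringsAsFactors = FALSE)
  ## GG-corrected p for the within-subject effects
  rows$p_gg <- rows$p
  if (gg_applied) {
    for (i in c(1L, 3L)) {
      if (rows$F[i] > 0 && is.finite(rows$F[i])) {
        rows$p_gg[i] <- stats::pf(rows$F[i], eps * rows$df_num[i],
                                  eps * rows$df_den[i], lower.tail = FALSE)
      }
    }
  }
  if (is.null(between)) rows <- rows[1, , drop = FALSE]

  structure(rows, class = c("anova_table", "data.frame"),
            mauchly_W = mauchly_W, mauchly_p = mauchly_p, epsilon = eps,
            gg_applied = gg_applied, n_units = n, within_levels = t,
            error_SS = c(within = ss_err_within, between = ss_err_between))
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA (%d units, %d within levels)\n",
              attr(x, "n_units"), attr(x, "within_levels")))
  cat(sprintf("Mauchly W = %s (p = %s); Greenhouse-Geisser epsilon = %.4f%s\n",
              format(attr(x, "mauchly_W"), digits = 4),
              format(attr(x, "mauchly_p"), digits = 4),
              attr(x, "epsilon"),
              if (attr(x, "gg_applied")) " [correction applied]" else ""))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Holm step-down adjustment of a p-value family
#'
#' Sorted ascending, the k-th smallest p is multiplied by (m - k + 1), a
#' running maximum enforces monotonicity, values are capped at 1, and the
#' result is returned in the original order.
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) < 1) stop("empty p-value family", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Paired post hoc contrasts between within-factor levels
#'
#' Two-tailed paired t-tests between levels of the within factor, with
#' Holm adjustment over the contrast family. By default all level pairs
#' are tested; contrasts are labeled `"<j>vs<i>"` by level position (so a
#' three-point schedule yields `2vs1`, `3vs1`, `3vs2`), matching the
#' "Sample 2vs1" style of longitudinal stress reports.
#'
#' @inheritParams mixed_anova
#' @param family Optional character vector of contrast labels to restrict
#'   the family (e.g., `c("2vs1", "3vs1")`); adjustment is within the
#'   requested family only.
#' @param level_order Optional explicit ordering of within levels; defaults
#'   to order of first appearance.
#' @return Data frame with columns `contrast, level_i, level_j, n, t, df,
#'   p_raw, p_holm` (contrast j vs i tests `x_j - x_i`).
#' @export
posthoc_time_contrasts <- function(data, value = "value", unit = "unit",
                                   within = "within", family = NULL,
                                   level_order = NULL) {
  v <- data[[value]]; u <- as.character(data[[unit]])
  wl <- as.character(data[[within]])
  levels_w <- if (is.null(level_order)) unique(wl) else level_order
  t_n <- length(levels_w)
  if (t_n < 2) stop("need at least two within levels", call. = FALSE)
  pairs <- utils::combn(t_n, 2)
  labels <- paste0(pairs[2, ], "vs", pairs[1, ])
  if (!is.null(family)) {
    unknown <- setdiff(family, labels)
    if (length(unknown) > 0) {
      stop("unknown contrast label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    sel <- labels %in% family
    pairs <- pairs[, sel, drop = FALSE]; labels <- labels[sel]
  }
  res <- lapply(seq_along(labels), function(k) {
    li <- levels_w[pairs[1, k]]; lj <- levels_w[pairs[2, k]]
    xi <- v[wl == li][match(unique(u), u[wl == li])]
    xj <- v[wl == lj][match(unique(u), u[wl == lj])]
    ok <- !is.na(xi) & !is.na(xj)
    if (sum(ok) < 2) {
      stop("contrast ", labels[k], ": fewer than 2 paired units",
           call. = FALSE)
    }
    d <- xj[ok] - xi[ok]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = 0, parameter = sum(ok) - 1,
                 p.value = if (all(d == 0)) 1 else NA_real_)
    } else {
      tt <- stats::t.test(xj[ok], xi[ok], paired = TRUE)
    }
    data.frame(contrast = labels[k], level_i = li, level_j = lj,
               n = sum(ok), t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p_raw)
  out
}

## two-tailed p from the t-transform of a correlation
cor_p_value <- function(r, df) {
  if (df < 1) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

cor_result <- function(r, p, n, method) {
  structure(list(r = r, p = p, n = n, method = method), class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f, p = %.4g, n = %d\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}

#' Rank-collapsed correlation across groups
#'
#' A non-parametric correlation built to absorb colony-level differences:
#' both variables are converted to within-group average ranks (ties
#' averaged), the ranked data are pooled across groups, and a two-tailed
#' Pearson correlation is computed on the pooled ranks. With a single
#' group and no ties this is exactly Spearman's rho.
#'
#' @param x,y Numeric vectors, one entry per subject (or dyad).
#' @param group Group membership vector aligned with `x` and `y`; a single
#'   group is allowed.
#' @return A `cor_result` (method `"RANK_COLLAPSED"`). Pairs with a missing
#'   value in either variable are dropped before ranking, with a warning.
#' @export
rank_collapse_correlation <- function(x, y, group = rep("all", length(x))) {
  stopifnot(length(x) == length(y), length(group) == length(x))
  ok <- !is.na(x) & !is.na(y)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " incomplete pair(s) before ranking",
            call. = FALSE)
    x <- x[ok]; y <- y[ok]; group <- group[ok]
  }
  if (length(x) < 4) stop("insufficient data: pooled n < 4", call. = FALSE)
  rx <- stats::ave(x, group, FUN = rank)
  ry <- stats::ave(y, group, FUN = rank)
  const_x <- all(tapply(x, group, function(v) length(unique(v)) == 1))
  const_y <- all(tapply(y, group, function(v) length(unique(v)) == 1))
  if (const_x || const_y || stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: a variable is constant within every group",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  n <- length(x)
  cor_result(r, cor_p_value(r, n - 2), n, "RANK_COLLAPSED")
}

#' Two-tailed Pearson correlation
#'
#' Thin wrapper returning the package's `cor_result` container, with the
#' p-value from the t-transform on n - 2 degrees of freedom. Incomplete
#' pairs are dropped pairwise with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A `cor_result` (method `"PEARSON"`).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " incomplete pair(s)", call. = FALSE)
    x <- x[ok]; y <- y[ok]
  }
  if (length(x) < 3) stop("insufficient data: n < 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y)
  cor_result(r, cor_p_value(r, length(x) - 2), length(x), "PEARSON")
}

#' First-order partial correlation
#'
#' Correlation between x and y controlling for z:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with the
#' two-tailed p-value on n - 3 degrees of freedom.
#'
#' @param x,y Variables of interest.
#' @param z Control variable.
#' @return A `cor_result` (method `"PARTIAL"`).
#' @export
partial_correlation <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  ok <- !is.na(x) & !is.na(y) & !is.na(z)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " incomplete triple(s)", call. = FALSE)
    x <- x[ok]; y <- y[ok]; z <- z[ok]
  }
  n <- length(x)
  if (n < 4) stop("insufficient data: n < 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("degenerate control: z is collinear with x or y", call. = FALSE)
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  cor_result(r, cor_p_value(r, n - 3), n, "PARTIAL")
}
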
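#' Two-sided p-value of the Mann-Whitney U statistic, normal approximation
#'
#' `z = (U - n1 n2 / 2) / sqrt(n1 n2 (n1 + n2 + 1 - T) / 12)` where `T` is
#' the tie adjustment `sum(t^3 - t) / ((n1+n2)(n1+n2-1))`; the two-sided
#' p-value is `2 Phi(-|z|)`. No continuity correction is applied (the
#' convention of classic commercial statistics packages, which the printed
#' values of interest follow: e.g. U = 20 with n1 = 9, n2 = 10 gives
#' p = 0.041, where the corrected variant would give 0.046).
#'
#' @param U the U statistic (half-integers allowed under ties).
#' @param n1,n2 group sizes.
#' @param tie_term the tie adjustment `T` above (0 when all pooled values
#'   are distinct).
#' @export
mwu_p_from_U <- function(U, n1, n2, tie_term = 0) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  if (U < 0 || U > n1 * n2) stop("U must lie in [0, n1*n2]")
  v <- n1 * n2 * (n1 + n2 + 1 - tie_term) / 12
  if (v <= 0) return(1)
  z <- (U - n1 * n2 / 2) / sqrt(v)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Mann-Whitney U test with normal approximation
#'
#' Midranks for ties; `U` is the smaller of the two group statistics; the
#' p-value uses the tie-corrected normal approximation without continuity
#' correction, see [mwu_p_from_U()].
#'
#' @param x,y numeric samples.
#' @return list of class `mwu` with `U`, `n1`, `n2`, `z`, `p_two_sided`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U <- min(U1, n1 * n2 - U1)
  N <- n1 + n2
  t <- table(c(x, y))
  tie_term <- sum(t^3 - t) / (N * (N - 1))
  v <- n1 * n2 * (N + 1 - tie_term) / 12
  z <- if (v > 0) (U - n1 * n2 / 2) / sqrt(v) else 0
  structure(list(U = U, n1 = n1, n2 = n2, z = z,
                 p_two_sided = mwu_p_from_U(U, n1, n2, tie_term)),
            class = "mwu")
}

#' @export
print.mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, n1 = %d, n2 = %d, z = %.3f, p = %.4g\n",
              x$U, x$n1, x$n2, x$z, x$p_two_sided))
  invisible(x)
}

## closed-form critical value of Cochran's C for k groups with nu df each
.cochran_crit <- function(alpha, k, nu)
  1 / (1 + (k - 1) / stats::qf(alpha / k, nu, (k - 1) * nu,
                               lower.tail = FALSE))

#' Variance-homogeneity battery with the square-root-transform rule
#'
#' Runs Cochran's C (`max s^2 / sum s^2`), Hartley's Fmax
#' (`max s^2 / min s^2`), Bartlett's chi-square and the mean-centered
#' Levene test on the groups. Cochran and Hartley pass/fail comes from
#' critical values valid for equal group sizes only (Cochran via the exact
#' closed form behind the published tables, Hartley via a conservative
#' Bonferroni bound over pairwise variance ratios); with unequal sizes
#' those two report the statistic with `pass = NA`. The battery passes
#' when every test with an available decision passes at `alpha`.
#'
#' The decision route mirrors common practice for measurement tables:
#' pass leads to ANOVA; failure leads to a square-root transformation and
#' a retest; a second failure leads to the Mann-Whitney test.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor (>= 2 groups, each n >= 2).
#' @param alpha significance level of the battery.
#' @param transform internal; marks which transform produced `values`.
#' @return object of class `homogeneity_report`: list with `tests` (data
#'   frame `test, statistic, p, pass`), `pass`, `transform_applied` and
#'   `recommendation` (`"anova"` or `"mann_whitney"`), recursing once into
#'   the sqrt-transformed data via `sqrt_report` when the raw battery
#'   fails.
#' @export
homogeneity_battery <- function(values, groups, alpha = 0.05,
                                transform = "none") {
  groups <- factor(groups)
  n <- tapply(values, groups, length)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(n < 2)) stop("every group needs n >= 2")
  k <- nlevels(groups)
  v <- tapply(values, groups, stats::var)
  equal_n <- length(unique(n)) == 1

  C <- max(v) / sum(v)
  Fmax <- max(v) / min(v)
  if (equal_n) {
    nu <- n[1] - 1
    c_pass <- C <= .cochran_crit(alpha, k, nu)
    ## Bonferroni bound over the k(k-1)/2 pairwise two-sided ratios
    fmax_p <- min(1, k * (k - 1) *
                    stats::pf(Fmax, nu, nu, lower.tail = FALSE))
    f_pass <- fmax_p > alpha
  } else {
    c_pass <- NA
    fmax_p <- NA_real_
    f_pass <- NA
  }
  bart <- stats::bartlett.test(values, groups)
  lev <- car::leveneTest(values, groups, center = mean)
  tests <- data.frame(
    test = c("cochran_c", "hartley_fmax", "bartlett", "levene"),
    statistic = c(C, Fmax, unname(bart$statistic), lev$`F value`[1]),
    p = c(NA, fmax_p, bart$p.value, lev$`Pr(>F)`[1]),
    pass = c(c_pass, f_pass, bart$p.value > alpha,
             lev$`Pr(>F)`[1] > alpha),
    stringsAsFactors = FALSE)
  pass <- all(tests$pass[!is.na(tests$pass)])
  rep <- list(tests = tests, pass = pass, transform_applied = transform,
              recommendation = if (pass) "anova" else "mann_whitney")
  if (!pass && transform == "none" && all(values >= 0)) {
    sq <- homogeneity_battery(sqrt(values), groups, alpha,
                              transform = "sqrt")
    rep$sqrt_report <- sq
    rep$recommendation <- if (sq$pass) "anova" else "mann_whitney"
    rep$transform_applied <- if (sq$pass) "sqrt" else "none"
  }
  class(rep) <- "homogeneity_report"
  rep
}

#' @export
print.homogeneity_report <- function(x, ...) {
  cat("Variance-homogeneity battery (transform:", x$transform_applied,
      ")\n")
  print(x$tests, row.names = FALSE)
  cat("overall:", if (x$pass) "PASS" else "FAIL",
      "-> recommended analysis:", x$recommendation, "\n")
  invisible(x)
}

#' Two-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Fits `values ~ treatment * time`, reports Type II sums of squares
#' (robust to the mild imbalance of 9 vs 10 animals per cell) and the
#' pooled-MSE cell means, then computes unadjusted pairwise t-tests
#' between all cells using the pooled mean square error and its degrees
#' of freedom (Fisher's least significant difference).
#'
#' @param values numeric response.
#' @param treatment,time crossed factors; every cell must be nonempty.
#' @return object of class `anova_lsd`: list with `anova` (data frame
#'   `term, F, df1, df2, p`), `mse`, `df_error`, `cell_means`
#'   (`treatment, time, mean, n`) and `lsd` (data frame of pairwise cell
#'   comparisons with `diff, t, p`).
#' @export
anova_lsd <- function(values, treatment, time) {
  treatment <- factor(treatment)
  time <- factor(time)
  if (any(table(treatment, time) == 0)) stop("empty design cell")
  ## a single-level factor collapses the model to a one-way ANOVA
  fit <- if (nlevels(time) < 2) stats::lm(values ~ treatment)
         else if (nlevels(treatment) < 2) stats::lm(values ~ time)
         else stats::lm(values ~ treatment * time)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)[rownames(a2) != "Residuals"]
  df_err <- a2["Residuals", "Df"]
  mse <- a2["Residuals", "Sum Sq"] / df_err
  atab <- data.frame(term = terms,
                     F = a2[terms, "F value"],
                     df1 = a2[terms, "Df"],
                     df2 = df_err,
                     p = a2[terms, "Pr(>F)"],
                     stringsAsFactors = FALSE)
  cm <- stats::aggregate(values,
                         list(treatment = treatment, time = time), mean)
  cn <- stats::aggregate(values,
                         list(treatment = treatment, time = time), length)
  cells <- data.frame(treatment = cm$treatment, time = cm$time,
                      mean = cm$x, n = cn$x, stringsAsFactors = FALSE)
  lab <- paste(cells$treatment, cells$time, sep = ".")
  pairs <- utils::combn(nrow(cells), 2)
  lsd <- data.frame(
    cell1 = lab[pairs[1, ]], cell2 = lab[pairs[2, ]],
    diff = cells$mean[pairs[1, ]] - cells$mean[pairs[2, ]],
    stringsAsFactors = FALSE)
  se <- sqrt(mse * (1 / cells$n[pairs[1, ]] + 1 / cells$n[pairs[2, ]]))
  lsd$t <- lsd$diff / se
  lsd$p <- 2 * stats::pt(-abs(lsd$t), df_err)
  structure(list(anova = atab, mse = mse, df_error = df_err,
                 cell_means = cells, lsd = lsd), class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat("Two-way ANOVA (Type II)\n")
  with(x$anova, for (i in seq_along(term))
    cat(sprintf("  %-16s F(%d,%d) = %.2f, p = %.4g\n",
                term[i], df1[i], df2[i], F[i], p[i])))
  cat(sprintf("  MSE = %.4g on %d df\n", x$mse, x$df_error))
  invisible(x)
}

#' Upper-tail probabilities
#'
#' `f_tail` gives `P(F >= f)` for an F distribution; `normal_tail` gives
#' `P(Z >= z)` for a standard normal.
#'
#' @param f,df1,df2 F statistic (>= 0) and its degrees of freedom.
#' @export
f_tail <- function(f, df1, df2) {
  if (any(f < 0) || df1 <= 0 || df2 <= 0) stop("invalid F or df")
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' @rdname f_tail
#' @param z standard normal deviate.
#' @export
normal_tail <- function(z) stats::pnorm(z, lower.tail = FALSE)

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  stats::cor(x, y)
}
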
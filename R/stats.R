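#' Mixed-design 2 x 2 x 2 ANOVA with partial eta squared
#'
#' One between-subject factor (group) crossed with two two-level
#' within-subject factors (hemisphere, region). Sums of squares follow
#' the classical mixed-model strata: subjects-within-group error for the
#' between effect; the subject x factor interaction stratum for each
#' within effect. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error_stratum)` with a 90% confidence
#' interval from noncentral-F inversion. With two levels per within
#' factor no sphericity correction is needed.
#'
#' @param frame long tibble with columns `subject_id`, `group`,
#'   `hemisphere`, `region`, `value`; the within design must be complete
#'   and the groups balanced (see [make_feature_frame()]).
#' @return Tibble of class `alpha_anova`, one row per effect:
#'   `effect`, `df_num`, `df_den`, `statistic` (F), `p_value`, `ss`,
#'   `ss_error` and `stratum` (the effect's sum of squares, its error
#'   stratum's sum of squares and stratum index), `peta2`, `peta2_lo`,
#'   `peta2_hi`.
#' @export
mixed_anova_222 <- function(frame) {
  frame <- as.data.frame(frame)
  frame$subject_id <- factor(frame$subject_id)
  frame$group <- factor(frame$group)
  frame$hemisphere <- factor(frame$hemisphere)
  frame$region <- factor(frame$region)
  tab <- table(frame$subject_id, frame$hemisphere, frame$region)
  if (any(tab != 1))
    stop("incomplete design: each subject needs exactly one value per ",
         "hemisphere x region cell")
  if (length(unique(table(frame$group) / 4)) != 1)
    stop("unbalanced design: groups must have equal sizes")
  fit <- stats::aov(value ~ group * hemisphere * region +
                      Error(subject_id / (hemisphere * region)),
                    data = frame)
  sm <- summary(fit)
  rows <- list()
  stratum_id <- 0L
  for (stratum in sm) {
    st <- stratum[[1]]
    terms <- trimws(rownames(st))
    resid_i <- which(terms == "Residuals")
    ss_err <- st[resid_i, "Sum Sq"]; df_err <- st[resid_i, "Df"]
    stratum_id <- stratum_id + 1L
    for (i in seq_len(nrow(st))[-resid_i]) {
      Fv <- st[i, "F value"]
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = gsub(":", " x ", terms[i]),
        df_num = st[i, "Df"], df_den = df_err,
        statistic = Fv, p_value = st[i, "Pr(>F)"],
        ss = st[i, "Sum Sq"], ss_error = ss_err,
        stratum = stratum_id,
        peta2 = st[i, "Sum Sq"] / (st[i, "Sum Sq"] + ss_err))
    }
  }
  out <- dplyr::bind_rows(rows)
  ci <- t(mapply(peta2_ci, out$statistic, out$df_num, out$df_den))
  out$peta2_lo <- ci[, 1]; out$peta2_hi <- ci[, 2]
  class(out) <- c("alpha_anova", class(out))
  out
}

# 90% CI for partial eta squared by inverting the noncentral F CDF.
peta2_ci <- function(F_obs, df1, df2, level = 0.90) {
  if (!is.finite(F_obs)) return(c(NA_real_, NA_real_))
  lo_p <- (1 + level) / 2; hi_p <- (1 - level) / 2
  ncp_for <- function(target) {
    if (stats::pf(F_obs, df1, df2, ncp = 0) < target) return(0)
    stats::uniroot(function(ncp) stats::pf(F_obs, df1, df2, ncp = ncp) - target,
                   interval = c(0, 10 * (df1 * F_obs + df1 + df2 + 100)),
                   tol = 1e-9)$root
  }
  ncp <- c(ncp_for(lo_p), ncp_for(hi_p))
  ncp / (ncp + df1 + df2 + 1)
}

#' t test with Cohen's d and noncentral-t confidence interval
#'
#' Pooled-variance independent or paired t test (via [stats::t.test()])
#' augmented with Cohen's d computed from the t statistic
#' (`d = t * sqrt(1/n1 + 1/n2)` independent, `d = t / sqrt(n)` paired)
#' and its 90% CI from noncentral-t inversion. The direction of a
#' one-tailed test is a required argument, never inferred from the data.
#'
#' @param a,b numeric samples (`b` is the second group, or the paired
#'   counterpart of `a`).
#' @param design `"independent"` or `"paired"`.
#' @param alternative `"two.sided"`, `"greater"` (a > b) or `"less"`.
#' @return One-row tibble of class `alpha_ttest`: `statistic` (t), `df`,
#'   `p_value`, `tail`, `design`, `cohens_d`, `d_lo`, `d_hi`.
#' @export
group_ttest <- function(a, b, design = c("independent", "paired"),
                        alternative = c("two.sided", "greater", "less")) {
  design <- match.arg(design)
  alternative <- match.arg(alternative)
  paired <- design == "paired"
  if (paired && length(a) != length(b))
    stop("paired design needs equal lengths")
  ht <- stats::t.test(a, b, paired = paired, var.equal = TRUE,
                      alternative = alternative)
  t <- unname(ht$statistic); df <- unname(ht$parameter)
  scale <- if (paired) 1 / sqrt(length(a)) else
    sqrt(1 / length(a) + 1 / length(b))
  d <- t * scale
  ci <- d_ci(t, df, scale)
  tibble::tibble(statistic = t, df = df, p_value = ht$p.value,
                 tail = if (alternative == "two.sided") "two" else "one",
                 design = design, cohens_d = d,
                 d_lo = ci[1], d_hi = ci[2]) |>
    structure(class = c("alpha_ttest", class(tibble::tibble())))
}

# 90% CI for d via noncentral-t inversion of the observed t.
d_ci <- function(t_obs, df, scale, level = 0.90) {
  probs <- c((1 + level) / 2, (1 - level) / 2)
  ncp <- vapply(probs, function(p) {
    lim <- abs(t_obs) + 50
    suppressWarnings(  # pnt tail-precision warnings
      stats::uniroot(function(nc) stats::pt(t_obs, df, ncp = nc) - p,
                     interval = c(-lim, lim), tol = 1e-9)$root)
  }, numeric(1))
  sort(ncp * scale)
}

#' Dunn-Sidak corrected per-comparison threshold
#'
#' `1 - (1 - alpha)^(1/k)`: the per-test p-value threshold controlling
#' the family-wise error rate over `k` comparisons.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param k number of comparisons (>= 1).
#' @return Corrected threshold.
#' @export
dunn_sidak_threshold <- function(alpha = 0.05, k) {
  stopifnot(k >= 1, alpha > 0, alpha < 1)
  1 - (1 - alpha)^(1 / k)
}

#' Group-level statistical report on a cohort feature table
#'
#' Runs the inferential battery on a feature table: 2x2x2 mixed ANOVAs
#' on IAF and amplitude, the planned group comparison of right posterior
#' IAF (one-tailed, low > high), two-tailed group comparisons of right
#' posterior amplitude and of the three wPLI and three TLI features,
#' with Dunn-Sidak thresholds (4 comparisons for alpha activity, 3 for
#' connectivity).
#'
#' @param features cohort feature tibble.
#' @return List with `anova_iaf`, `anova_amp` (class `alpha_anova`) and
#'   `tests` (tibble, one row per planned comparison with its corrected
#'   threshold and pass flag).
#' @export
stat_report <- function(features) {
  hs <- features[features$group == "HSG", ]
  ls <- features[features$group == "LSG", ]
  planned <- list(
    list(name = "iaf_posterior_R: LSG > HSG", col = "iaf_posterior_R",
         alternative = "greater", family = "alpha", flip = TRUE),
    list(name = "amp_posterior_R: LSG vs HSG", col = "amp_posterior_R",
         alternative = "two.sided", family = "alpha", flip = TRUE),
    list(name = "wpli_intra_R: LSG vs HSG", col = "wpli_intra_R",
         alternative = "two.sided", family = "conn", flip = TRUE),
    list(name = "wpli_intra_L: LSG vs HSG", col = "wpli_intra_L",
         alternative = "two.sided", family = "conn", flip = TRUE),
    list(name = "tli_intra_R: HSG vs LSG", col = "tli_intra_R",
         alternative = "two.sided", family = "conn", flip = FALSE)
  )
  thr <- c(alpha = dunn_sidak_threshold(0.05, 4),
           conn = dunn_sidak_threshold(0.05, 3))
  tests <- dplyr::bind_rows(lapply(planned, function(pl) {
    x1 <- if (pl$flip) ls[[pl$col]] else hs[[pl$col]]
    x2 <- if (pl$flip) hs[[pl$col]] else ls[[pl$col]]
    tt <- group_ttest(x1, x2, "independent", pl$alternative)
    tt$comparison <- pl$name
    tt$threshold <- unname(thr[pl$family])
    tt$significant <- tt$p_value < tt$threshold
    tt
  }))
  list(anova_iaf = mixed_anova_222(make_feature_frame(features, "iaf")),
       anova_amp = mixed_anova_222(make_feature_frame(features, "amp")),
       tests = tests[, c("comparison", "statistic", "df", "p_value",
                         "tail", "cohens_d", "d_lo", "d_hi",
                         "threshold", "significant")])
}
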
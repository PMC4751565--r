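.check_hybrid_balance <- function(d) {
  tab <- table(d$whole_plot, d$hybrid)
  wp_trt <- tapply(as.character(d$treatment), d$whole_plot,
                   function(x) length(unique(x)))
  if (any(wp_trt != 1)) stop("a whole plot spans more than one treatment")
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("unbalanced split-plot design; cell counts != 1 for ",
         nrow(bad), " (whole plot, hybrid) cell(s)")
  }
  n_wp <- table(tapply(as.character(d$treatment), d$whole_plot, unique))
  if (length(n_wp) != 2 || any(n_wp != 4))
    stop("design must have 4 whole plots in each of 2 treatments; got ",
         paste(names(n_wp), n_wp, sep = "=", collapse = ", "))
  invisible(TRUE)
}

#' Split-plot analysis of variance of the isogenic hybrid trial
#'
#' The Al treatment is applied at the whole-plot level (completely
#' randomized, 4 whole plots per treatment) and the 8 hybrids (2 females x
#' 4 males) at the sub-plot level. The treatment effect is tested against
#' the whole-plot error (between whole plots within treatment, df 6); the
#' hybrid decomposition (female df 1, male df 3, female x male df 3), the
#' treatment x hybrid interaction (df 7) and everything else are tested
#' against the sub-plot error (df 42). Least significant differences at
#' `alpha` use the error stratum appropriate to the factor:
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 MS_error / n_per_mean)`.
#'
#' @param plots Data frame with columns `whole_plot`, `treatment`,
#'   `hybrid`, `female`, `male`, `yield` (and optionally `dosage`).
#' @param alpha Two-sided level for the LSDs.
#' @return A `split_plot_fit` list: `anova` (source, df, ss, ms, f, p),
#'   `means` (marginal means for treatment, female, male, hybrid), `lsd`,
#'   and the error mean squares.
#' @export
split_plot_anova <- function(plots, alpha = 0.05) {
  need <- c("whole_plot", "treatment", "hybrid", "female", "male", "yield")
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(whole_plot = factor(plots$whole_plot),
                  treatment = factor(plots$treatment),
                  hybrid = factor(plots$hybrid),
                  female = factor(plots$female),
                  male = factor(plots$male),
                  yield = as.numeric(plots$yield))
  .check_hybrid_balance(d)
  fit <- stats::aov(yield ~ treatment + female + male + female:male +
                      treatment:hybrid + Error(whole_plot), data = d)
  s <- summary(fit)
  wp <- as.data.frame(s[["Error: whole_plot"]][[1]])
  sub <- as.data.frame(s[["Error: Within"]][[1]])
  row_of <- function(tab, pattern) {
    i <- grep(pattern, trimws(rownames(tab)))[1]
    unname(unlist(tab[i, c("Df", "Sum Sq", "Mean Sq", "F value", "Pr(>F)")]))
  }
  rows <- rbind(
    treatment = row_of(wp, "^treatment$"),
    whole_plot_error = row_of(wp, "^Residuals$"),
    female = row_of(sub, "^female$"),
    male = row_of(sub, "^male$"),
    `female:male` = row_of(sub, "^female:male$"),
    `treatment:hybrid` = row_of(sub, "^treatment:hybrid$"),
    subplot_error = row_of(sub, "^Residuals$"))
  anova_tab <- data.frame(source = rownames(rows), df = rows[, 1],
                          ss = rows[, 2], ms = rows[, 3], f = rows[, 4],
                          p = rows[, 5], stringsAsFactors = FALSE)
  rownames(anova_tab) <- NULL
  ms_wp <- anova_tab$ms[anova_tab$source == "whole_plot_error"]
  ms_sub <- anova_tab$ms[anova_tab$source == "subplot_error"]
  df_wp <- anova_tab$df[anova_tab$source == "whole_plot_error"]
  df_sub <- anova_tab$df[anova_tab$source == "subplot_error"]
  marg <- function(f) tapply(d$yield, f, mean)
  n_trt <- nrow(d) / nlevels(d$treatment)
  n_fem <- nrow(d) / nlevels(d$female)
  n_mal <- nrow(d) / nlevels(d$male)
  n_hyb <- nrow(d) / nlevels(d$hybrid)
  tcrit_wp <- stats::qt(1 - alpha / 2, df_wp)
  tcrit_sub <- stats::qt(1 - alpha / 2, df_sub)
  lsd <- c(treatment = tcrit_wp * sqrt(2 * ms_wp / n_trt),
           female = tcrit_sub * sqrt(2 * ms_sub / n_fem),
           male = tcrit_sub * sqrt(2 * ms_sub / n_mal),
           hybrid = tcrit_sub * sqrt(2 * ms_sub / n_hyb))
  structure(list(anova = anova_tab,
                 means = list(treatment = marg(d$treatment),
                              female = marg(d$female),
                              male = marg(d$male),
                              hybrid = marg(d$hybrid)),
                 lsd = lsd, ms_whole_plot = ms_wp, ms_subplot = ms_sub,
                 alpha = alpha),
            class = "split_plot_fit")
}

#' @export
print.split_plot_fit <- function(x, ...) {
  cat("Split-plot analysis of variance\n")
  tab <- x$anova
  tab$ss <- round(tab$ss, 4); tab$ms <- round(tab$ms, 4)
  tab$f <- round(tab$f, 2); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("\nMarginal means (LSD at alpha =", x$alpha, "):\n")
  for (nm in names(x$means)) {
    cat(sprintf("  %-10s %s   LSD = %.3f\n", nm,
                paste(sprintf("%s %.3f", names(x$means[[nm]]),
                              x$means[[nm]]), collapse = "  "),
                x$lsd[[nm]]))
  }
  invisible(x)
}

#' Allele-dosage covariate test for additive gene action
#'
#' Within the split-plot strata, replaces the female and male factors by the
#' linear count of tolerance (T) alleles carried by each hybrid: the model
#' absorbs whole plots (hence the treatment) as fixed blocks and regresses
#' yield on the dosage, so the covariate is tested against the sub-plot
#' error. Under purely additive gene action this per-copy coefficient
#' equals the average substitution effect from the factorial model (the
#' female marginal difference, since the two females differ by exactly one
#' T copy across every male); under dominance the two diverge, and the
#' divergence is reported.
#'
#' @param plots As in [split_plot_anova()], with a numeric `dosage` column
#'   in `{0, 1, 2}`.
#' @return List with `coefficient` (yield change per added T allele), `se`,
#'   `df`, `p`, `factor_effect` (female-difference average substitution
#'   effect) and `divergence`.
#' @export
dosage_covariate_test <- function(plots) {
  need <- c("whole_plot", "treatment", "female", "male", "dosage", "yield")
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(whole_plot = factor(plots$whole_plot),
                  female = factor(plots$female),
                  dosage = as.numeric(plots$dosage),
                  yield = as.numeric(plots$yield))
  if (stats::sd(d$dosage) == 0) stop("allele dosage is constant")
  fit <- stats::lm(yield ~ whole_plot + dosage, data = d)
  co <- summary(fit)$coefficients["dosage", ]
  fem_means <- tapply(d$yield, d$female, mean)
  if (length(fem_means) != 2) stop("expected exactly two female parents")
  factor_effect <- unname(fem_means[2] - fem_means[1])
  list(coefficient = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       df = fit$df.residual, p = unname(co["Pr(>|t|)"]),
       factor_effect = factor_effect,
       divergence = unname(co["Estimate"]) - factor_effect)
}
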
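#' Relative net root growth from hydroponic root measurements
#'
#' Per plant, the control net root growth is `crgr5d = fl_c - il_c` and the
#' growth under Al stress `Alrgr5d = fl_Al - il_Al`; the tolerance index is
#' `RNRG = (Alrgr5d / crgr5d) * 100` (percent). Plants whose control root
#' did not grow (`crgr5d <= 0`) are excluded with a logged count. Plant
#' values are averaged within (line, block) and the block mean is
#' log10-transformed; non-positive block means are clamped to `floor`
#' (percent) first, since the logarithm is undefined there.
#'
#' @param records Data frame with columns `line`, `block`, `plant`, `il_c`,
#'   `fl_c`, `il_Al`, `fl_Al` (root lengths in cm).
#' @param floor Clamp value (percent) applied to non-positive block means
#'   before the log10 transform.
#' @return Data frame with one row per (line, block): `line`, `block`,
#'   `n_plants`, `rnrg_pct`, `rnrg_log10`; counts of excluded plants and
#'   clamped means as attributes `"excluded"` and `"clamped"`.
#' @export
compute_rnrg <- function(records, floor = 1) {
  need <- c("line", "block", "il_c", "fl_c", "il_Al", "fl_Al")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  crgr <- records$fl_c - records$il_c
  alrgr <- records$fl_Al - records$il_Al
  bad <- !(crgr > 0) | !is.finite(crgr) | !is.finite(alrgr)
  if (any(bad))
    message(sum(bad), " plant(s) excluded (non-growing control root)")
  rec <- records[!bad, , drop = FALSE]
  rnrg <- 100 * alrgr[!bad] / crgr[!bad]
  agg <- stats::aggregate(rnrg,
                          by = list(line = rec$line, block = rec$block),
                          FUN = mean)
  names(agg)[3] <- "rnrg_pct"
  n <- stats::aggregate(rnrg, by = list(line = rec$line, block = rec$block),
                        FUN = length)[[3]]
  clamped <- agg$rnrg_pct <= floor
  if (any(clamped))
    message(sum(clamped), " block mean(s) clamped to ", floor,
            "% before log transform")
  out <- data.frame(line = agg$line, block = agg$block, n_plants = n,
                    rnrg_pct = agg$rnrg_pct,
                    rnrg_log10 = log10(pmax(agg$rnrg_pct, floor)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$line, out$block), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- sum(bad)
  attr(out, "clamped") <- sum(clamped)
  out
}

# Assemble a variance-components record; the h2 identity holds by
# construction: h2 = sigma2_g / (sigma2_g + sigma2_e / r).
variance_components <- function(sigma2_g, sigma2_e, r, sigma2_b = NA_real_) {
  stopifnot(sigma2_g >= 0, sigma2_e >= 0, r >= 1)
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 sigma2_b = sigma2_b, r = r,
                 h2 = sigma2_g / (sigma2_g + sigma2_e / r)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma2_g = %.4f, sigma2_e = %.4f%s, r = %d, h2 = %.3f\n",
              x$sigma2_g, x$sigma2_e,
              if (is.na(x$sigma2_b)) "" else
                sprintf(", sigma2_b = %.4f", x$sigma2_b),
              as.integer(x$r), x$h2))
  invisible(x)
}

#' Randomized-complete-block mixed model (hydroponics stage 1)
#'
#' Fits `response = block + genotype + error` by REML with block fixed.
#' With genotype random it returns the genotypic and error variance
#' components and the line-mean heritability `h2 = sigma2_g / (sigma2_g +
#' sigma2_e / r)` with `r` the number of blocks; with genotype fixed it
#' returns BLUEs, the genotype means adjusted for block (equal to raw means
#' on balanced data). A variance estimate on the zero boundary is accepted
#' and reported, not an error.
#'
#' @param data Data frame with columns `line`, `block`, `value`.
#' @param genotype_random Fit genotype as random (variance components +
#'   heritability) or fixed (BLUEs)?
#' @return A `variance_components` object, or a named vector of BLUEs.
#' @export
fit_rcbd <- function(data, genotype_random = TRUE) {
  need <- c("line", "block", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(line = factor(data$line), block = factor(data$block),
                  value = as.numeric(data$value))
  r <- nlevels(d$block)
  if (r < 2) stop("heritability undefined with fewer than 2 blocks")
  if (genotype_random) {
    fit <- lme4::lmer(value ~ block + (1 | line), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sg <- vc$vcov[vc$grp == "line"]
    se <- vc$vcov[vc$grp == "Residual"]
    if (sg < 1e-12)
      message("genotypic variance estimated on the zero boundary")
    variance_components(sg, se, r)
  } else {
    fit <- stats::lm(value ~ line + block, data = d)
    grid <- expand.grid(line = levels(d$line), block = levels(d$block))
    pred <- stats::predict(fit, newdata = grid)
    blues <- tapply(pred, grid$line, mean)
    stats::setNames(as.numeric(blues), names(blues))
  }
}

#' Resolvable incomplete-block mixed model (field stage 1)
#'
#' Fits, for one environment, `yield = replicate + incomplete block within
#' replicate + genotype + error` by REML, with replicate fixed and the
#' incomplete block random. With genotype random, returns the genotypic,
#' block and error variances and the line-mean heritability (`r` =
#' replicate count); with genotype fixed, returns BLUEs. A duplicated check
#' entry (e.g. a parent repeated several times per replicate) simply
#' contributes all its plots to a single genotype level. Boundary variance
#' estimates (zero) are reported, not errors.
#'
#' @param data Data frame with columns `line`, `replicate`, `block`,
#'   `yield` for a single environment.
#' @param genotype_random Random genotype (variance components) or fixed
#'   (BLUEs)?
#' @return A `variance_components` object (with `sigma2_b`), or a named
#'   vector of BLUEs.
#' @export
fit_incomplete_block <- function(data, genotype_random = TRUE) {
  need <- c("line", "replicate", "block", "yield")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(line = factor(data$line),
                  replicate = factor(data$replicate),
                  block = factor(paste(data$replicate, data$block, sep = ":")),
                  yield = as.numeric(data$yield))
  r <- nlevels(d$replicate)
  if (genotype_random) {
    fit <- lme4::lmer(yield ~ replicate + (1 | block) + (1 | line),
                      data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sg <- vc$vcov[vc$grp == "line"]
    sb <- vc$vcov[vc$grp == "block"]
    se <- vc$vcov[vc$grp == "Residual"]
    if (min(sg, sb) < 1e-12)
      message("variance component estimated on the zero boundary")
    variance_components(sg, se, r, sigma2_b = sb)
  } else {
    fit <- lme4::lmer(yield ~ 0 + line + replicate + (1 | block), data = d,
                      REML = TRUE)
    fe <- lme4::fixef(fit)
    line_idx <- grep("^line", names(fe))
    rep_idx <- grep("^replicate", names(fe))
    blues <- fe[line_idx] + mean(c(0, fe[rep_idx]))
    names(blues) <- sub("^line", "", names(fe)[line_idx])
    blues
  }
}

#' Product-moment correlation of line means between two environments
#'
#' Reported as the (attenuated) proxy of the genotypic correlation between
#' treatments: stage-1 noise in each environment's BLUEs shrinks the
#' observable correlation toward `rho * sqrt(h2_1 * h2_2)`.
#'
#' @param blues_1,blues_2 Named BLUE vectors for the two environments.
#' @return The correlation over the shared line set.
#' @export
env_genetic_correlation <- function(blues_1, blues_2) {
  common <- intersect(names(blues_1), names(blues_2))
  if (length(common) < 3) stop("need at least 3 shared lines")
  x <- blues_1[common]; y <- blues_2[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one environment's means")
  message("note: stage-1 noise attenuates this correlation toward ",
          "rho * sqrt(h2_1 * h2_2)")
  stats::cor(x, y)
}

#' Assemble the multi-trait table of genotype means
#'
#' Inner-joins named BLUE vectors on line id; lines missing any trait are
#' dropped with their ids logged, and parental/check entries are excluded
#' (configurable) so the table holds the mapping population only.
#'
#' @param ... Named BLUE vectors, one per trait (names become trait names).
#' @param exclude Line ids removed from the table (parents and checks).
#' @return Matrix (lines x traits) with line ids as rownames.
#' @export
assemble_trait_table <- function(..., exclude = character(0)) {
  vecs <- list(...)
  if (length(vecs) == 1 && is.list(vecs[[1]]) && is.null(names(vecs)[1]))
    vecs <- vecs[[1]]
  if (is.null(names(vecs)) || any(!nzchar(names(vecs))))
    stop("every trait vector must be named")
  ids <- lapply(vecs, names)
  common <- Reduce(intersect, ids)
  common <- setdiff(common, exclude)
  if (!length(common)) stop("no lines shared across all traits")
  all_ids <- setdiff(unique(unlist(ids)), exclude)
  dropped <- setdiff(all_ids, common)
  if (length(dropped))
    message(length(dropped), " line(s) dropped (missing a trait): ",
            paste(utils::head(dropped, 10), collapse = ", "))
  out <- vapply(vecs, function(v) as.numeric(v[common]),
                numeric(length(common)))
  rownames(out) <- common
  out[order(rownames(out)), , drop = FALSE]
}
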
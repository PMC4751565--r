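#' Fit the base (polygenic-only) multi-trait model
#'
#' With one adjusted mean per line and trait, the polygenic background and
#' the stage-1 error are jointly unidentifiable, so the base model estimates
#' trait means and a single unstructured covariance of line deviations. If
#' per-trait error floors (the stage-1 `sigma_e^2 / r`) are supplied, the
#' genetic variance per trait is the diagonal minus the floor, bounded below
#' at zero; %GV calculations then refer to that genetic part.
#'
#' @param traits Numeric matrix (lines x traits) of genotype means (BLUEs),
#'   with line ids as rownames.
#' @param error_floors Optional named per-trait error variance floor.
#' @return A list with `means`, `sigma` (unstructured covariance),
#'   `genetic_var` (diagonal minus floor), `error_floors` and `n`.
#' @export
fit_base_model <- function(traits, error_floors = NULL) {
  traits <- as.matrix(traits)
  n <- nrow(traits); Tt <- ncol(traits)
  if (n < Tt + 2) stop("need at least trait-count + 2 lines")
  if (anyNA(traits)) stop("trait table must be complete (filter upstream)")
  mu <- colMeans(traits)
  S <- stats::cov(traits)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    ridge <- 1e-8 * sum(diag(S))
    S <- S + diag(ridge, Tt)
    message("singular trait covariance; ridge of ", signif(ridge, 3), " added")
  }
  floors <- rep(0, Tt)
  names(floors) <- colnames(traits)
  if (!is.null(error_floors)) {
    if (is.null(names(error_floors))) {
      stopifnot(length(error_floors) == Tt)
      floors[] <- error_floors
    } else floors[names(error_floors)] <- error_floors
  }
  list(means = mu, sigma = S, genetic_var = pmax(diag(S) - floors, 0),
       error_floors = floors, n = n)
}

# Multivariate least squares with identical regressors across traits:
# returns coefficients, residual covariance (df-corrected) and (X'X)^-1.
.mls_fit <- function(Y, X) {
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  XtXinv <- chol2inv(ch)
  B <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- nrow(Y) - ncol(X)
  if (df <= ncol(Y)) return(NULL)
  list(B = B, sigma = crossprod(res) / df, XtXinv = XtXinv, df = df, res = res)
}

# p-value of a multi-trait Wald statistic W with Tt traits and residual df m.
# "f" uses the exact Hotelling T^2 -> F calibration (for Tt = 1 this is the
# regression t-test); "chisq" is the large-sample chi-square reference.
.wald_p <- function(W, Tt, m, pvalue = c("f", "chisq")) {
  pvalue <- match.arg(pvalue)
  if (pvalue == "chisq") return(stats::pchisq(W, df = Tt, lower.tail = FALSE))
  fstat <- W * (m - Tt + 1) / (m * Tt)
  stats::pf(fstat, Tt, m - Tt + 1, lower.tail = FALSE)
}

#' Multi-trait Wald test of a putative QTL position
#'
#' Fits, for every trait jointly, `y_t = mu_t + sum_c gamma_ct x_c +
#' alpha_t x + e_t` where `x` holds the conditional QTL genotype
#' probabilities at the tested position and the `x_c` are cofactor scores.
#' Because the regressor set is identical across traits, generalized least
#' squares reduces to per-trait ordinary least squares; the residual
#' covariance across traits is unstructured and estimated from the
#' residuals. The Wald statistic `alpha' V(alpha)^-1 alpha` is referred to a
#' chi-square with trait-count degrees of freedom, or (default) to the exact
#' small-sample Hotelling T-squared / F calibration.
#'
#' @param traits Lines x traits matrix of genotype means.
#' @param x QTL genotype score column aligned to `rownames(traits)`.
#' @param cofactors Optional matrix of cofactor score columns.
#' @param pvalue `"f"` (small-sample calibration, default) or `"chisq"`.
#' @return List with `wald`, `df`, `p`, per-trait `effects` (B-class minus
#'   A-class difference) and `se`; or `NULL` when the position is untestable
#'   (constant score or collinear with a cofactor).
#' @export
wald_test <- function(traits, x, cofactors = NULL, pvalue = "f") {
  Y <- as.matrix(traits)
  n <- nrow(Y)
  if (stats::sd(x) < 1e-10) return(NULL)
  if (!is.null(cofactors) && ncol(as.matrix(cofactors))) {
    C <- as.matrix(cofactors)
    keep <- apply(C, 2, stats::sd) > 1e-10
    C <- C[, keep, drop = FALSE]
    if (ncol(C)) {
      r <- suppressWarnings(abs(stats::cor(x, C)))
      if (any(r > 0.999, na.rm = TRUE)) return(NULL)
      X <- cbind(1, C, x)
    } else X <- cbind(1, x)
  } else X <- cbind(1, x)
  fit <- .mls_fit(Y, X)
  if (is.null(fit)) return(NULL)
  k <- ncol(X)
  cxx <- fit$XtXinv[k, k]
  alpha <- fit$B[k, ]
  sol <- tryCatch(solve(fit$sigma, alpha), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  W <- sum(alpha * sol) / cxx
  Tt <- ncol(Y)
  list(wald = W, df = Tt, p = .wald_p(W, Tt, fit$df, pvalue),
       effects = alpha, se = sqrt(diag(fit$sigma) * cxx))
}

#' Genome scan by multi-trait Wald tests
#'
#' Evaluates [wald_test()] at every grid position of a conditional QTL
#' probability matrix. With `cofactors = NULL` this is the simple interval
#' mapping (SIM) round; with a candidate set supplied it is a composite
#' interval mapping (CIM) round in which any cofactor on the same chromosome
#' within `window` cM of the evaluated position is left out of the model.
#'
#' @param traits Lines x traits matrix of genotype means.
#' @param probs Conditional probability matrix from [qtl_genotype_probs()].
#' @param cofactors Optional data frame of candidate positions (columns
#'   `chromosome`, `position`) taken from the same grid.
#' @param window Cofactor exclusion window in centimorgan.
#' @param threshold Optional `-log10(p)` cutoff stored with the result.
#' @param pvalue Passed to [wald_test()].
#' @return A `scan_result` data frame with per-position `chromosome`,
#'   `position`, `wald`, `df`, `p` and `neglog10p` (`NA` at skipped
#'   positions), the threshold and cofactor set as attributes.
#' @export
mt_scan <- function(traits, probs, cofactors = NULL, window = 30,
                    threshold = NULL, pvalue = "f") {
  grid <- attr(probs, "grid")
  if (is.null(grid)) stop("probs must carry a 'grid' attribute")
  Y <- as.matrix(traits)
  stopifnot(nrow(Y) == nrow(probs))
  P <- nrow(grid)
  wald <- p <- rep(NA_real_, P)
  cof_idx <- integer(0)
  if (!is.null(cofactors) && nrow(cofactors)) {
    cof_idx <- grid_index(grid, cofactors)
    cof_chr <- grid$chromosome[cof_idx]
    cof_pos <- grid$position[cof_idx]
  }
  for (j in seq_len(P)) {
    C <- NULL
    if (length(cof_idx)) {
      use <- !(cof_chr == grid$chromosome[j] &
                 abs(cof_pos - grid$position[j]) <= window)
      if (any(use)) C <- probs[, cof_idx[use], drop = FALSE]
    }
    wt <- wald_test(Y, probs[, j], C, pvalue = pvalue)
    if (!is.null(wt)) { wald[j] <- wt$wald; p[j] <- wt$p }
  }
  out <- data.frame(chromosome = grid$chromosome, position = grid$position,
                    marker = grid$marker, wald = wald, df = ncol(Y), p = p,
                    neglog10p = -log10(p), stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "cofactors") <- if (length(cof_idx))
    data.frame(chromosome = cof_chr, position = cof_pos) else NULL
  attr(out, "pvalue") <- pvalue
  class(out) <- c("scan_result", "data.frame")
  out
}

#' @rdname mt_scan
#' @export
sim_scan <- function(traits, probs, threshold = NULL, pvalue = "f") {
  mt_scan(traits, probs, cofactors = NULL, threshold = threshold,
          pvalue = pvalue)
}

#' @rdname mt_scan
#' @param candidates Candidate QTL positions used as cofactors.
#' @export
cim_round <- function(traits, probs, candidates, window = 30,
                      threshold = NULL, pvalue = "f") {
  mt_scan(traits, probs, cofactors = candidates, window = window,
          threshold = threshold, pvalue = pvalue)
}

# Map (chromosome, position) rows to row indices of a scan grid.
grid_index <- function(grid, positions) {
  idx <- vapply(seq_len(nrow(positions)), function(i) {
    on_chr <- which(grid$chromosome == as.character(positions$chromosome[i]))
    if (!length(on_chr)) stop("position on chromosome ",
                              positions$chromosome[i], " not on grid")
    on_chr[which.min(abs(grid$position[on_chr] - positions$position[i]))]
  }, integer(1))
  idx
}

# Effective number of independent tests from a correlation-matrix spectrum
# (eigenvalue decomposition rule: integer part counts lambda >= 1, the
# fractional part is carried for every eigenvalue).
.meff_from_eigen <- function(lambda) {
  lambda <- pmax(lambda, 0)
  sum(as.numeric(lambda >= 1) + (lambda - floor(lambda)))
}

#' Genome-wide significance threshold from the effective number of tests
#'
#' Per chromosome, the eigenvalues of the marker-score correlation matrix
#' give the effective number of independent tests,
#' `M_eff = sum_i [ 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`; the
#' chromosome contributions are summed, and the comparisonwise cutoff that
#' holds the genome-wide level at `alpha` is the Sidak-type
#' `1 - (1 - alpha)^(1 / M_eff)`. A single-marker chromosome contributes
#' `M_eff = 1`. Markers with no variation are dropped from the correlation
#' matrix. Computed on marker (not grid) correlations, because interpolated
#' grid points carry no additional tests.
#'
#' @param geno A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @param alpha Genome-wide test level in `(0, 1)`.
#' @return List with `m_eff`, `per_chromosome`, `alpha`, `p_cutoff` and
#'   `neglog10` (the `-log10(p)` threshold).
#' @export
genomewide_threshold <- function(geno, map, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  chrs <- unique(map$chromosome)
  per_chr <- vapply(chrs, function(ch) {
    mi <- which(map$chromosome == ch)
    X <- geno[, mi, drop = FALSE]
    X <- X[, apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) > 0),
           drop = FALSE]
    m <- ncol(X)
    if (m <= 1L) return(1)
    R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    min(.meff_from_eigen(lambda), m)
  }, numeric(1))
  names(per_chr) <- chrs
  m_eff <- sum(per_chr)
  p_cut <- 1 - (1 - alpha)^(1 / m_eff)
  list(m_eff = m_eff, per_chromosome = per_chr, alpha = alpha,
       p_cutoff = p_cut, neglog10 = -log10(p_cut))
}

#' Select candidate QTL from a scan profile
#'
#' Per chromosome, positions that are local maxima of `-log10(p)` and exceed
#' the threshold are accepted greedily in decreasing significance, subject
#' to a pairwise separation of at least `min_separation` cM between accepted
#' candidates on the same chromosome. Ties in significance are broken toward
#' the lower cM position.
#'
#' @param scan A [mt_scan()] result.
#' @param threshold `-log10(p)` cutoff; defaults to the threshold stored in
#'   the scan.
#' @param min_separation Minimum distance between candidates on one
#'   chromosome, in centimorgan.
#' @return Data frame of candidate `chromosome`, `position`, `neglog10p`
#'   (possibly empty).
#' @export
select_candidates <- function(scan, threshold = NULL, min_separation = 30) {
  if (is.null(threshold)) threshold <- attr(scan, "threshold")
  if (is.null(threshold)) stop("no threshold given or stored in scan")
  picks <- list()
  for (ch in unique(scan$chromosome)) {
    sub <- scan[scan$chromosome == ch & !is.na(scan$p), , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$position), , drop = FALSE]
    y <- sub$neglog10p
    m <- length(y)
    is_max <- rep(TRUE, m)
    if (m > 1) {
      is_max <- c(y[1] >= y[2],
                  if (m > 2) y[2:(m - 1)] >= y[1:(m - 2)] &
                    y[2:(m - 1)] >= y[3:m] else NULL,
                  y[m] >= y[m - 1])
    }
    cand <- sub[is_max & y >= threshold, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[order(-cand$neglog10p, cand$position), , drop = FALSE]
    kept <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (!length(kept) ||
          all(abs(cand$position[kept] - cand$position[i]) >= min_separation))
        kept <- c(kept, i)
    }
    picks[[ch]] <- cand[kept, c("chromosome", "position", "neglog10p")]
  }
  if (!length(picks))
    return(data.frame(chromosome = character(0), position = numeric(0),
                      neglog10p = numeric(0)))
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out[order(match(out$chromosome, unique(scan$chromosome)), out$position), ,
      drop = FALSE]
}

#' Iterate composite interval mapping to a stable candidate set
#'
#' Starting from the SIM candidate set, rescans with the candidates as
#' cofactors and reselects, until the candidate set is unchanged or
#' `max_rounds` is reached (oscillating sets stop with a warning).
#'
#' @inheritParams mt_scan
#' @param candidates Initial candidate set (from SIM).
#' @param threshold `-log10(p)` cutoff for reselection.
#' @param min_separation Passed to [select_candidates()].
#' @param max_rounds Maximum number of CIM rounds.
#' @return List with the final `scan`, `candidates`, number of `rounds` and
#'   a `converged` flag.
#' @export
run_cim <- function(traits, probs, candidates, threshold, window = 30,
                    min_separation = 30, max_rounds = 5, pvalue = "f") {
  scan <- NULL
  converged <- FALSE
  rounds <- 0L
  for (it in seq_len(max_rounds)) {
    rounds <- it
    scan <- cim_round(traits, probs, candidates, window = window,
                      threshold = threshold, pvalue = pvalue)
    new <- select_candidates(scan, threshold, min_separation)
    same <- nrow(new) == nrow(candidates) &&
      (!nrow(new) || all(paste(new$chromosome, new$position) %in%
                           paste(candidates$chromosome, candidates$position)))
    candidates <- new
    if (same) { converged <- TRUE; break }
  }
  if (!converged)
    warning("candidate set did not stabilise within ", max_rounds,
            " CIM rounds")
  list(scan = scan, candidates = candidates, rounds = rounds,
       converged = converged)
}

# Joint multi-trait fit of a set of QTL score columns; returns per-QTL
# effects, ses, Wald statistics and p-values.
.joint_qtl_fit <- function(traits, scores, pvalue = "f") {
  Y <- as.matrix(traits)
  X <- cbind(1, scores)
  fit <- .mls_fit(Y, X)
  if (is.null(fit)) stop("joint QTL model is singular")
  k <- ncol(X)
  Tt <- ncol(Y)
  nq <- k - 1L
  eff <- fit$B[-1, , drop = FALSE]
  se <- w <- p <- NULL
  sig_inv <- solve(fit$sigma)
  se <- sqrt(outer(diag(fit$XtXinv)[-1], diag(fit$sigma)))
  w <- vapply(seq_len(nq), function(j) {
    a <- eff[j, ]
    sum(a * (sig_inv %*% a)) / fit$XtXinv[j + 1L, j + 1L]
  }, numeric(1))
  p <- .wald_p(w, Tt, fit$df, pvalue)
  list(effects = eff, se = se, wald = w, p = p, df = fit$df,
       sigma = fit$sigma, res = fit$res)
}

#' Backward elimination of redundant candidate QTL
#'
#' Fits all candidates jointly (`responses = QTL + polygenic effects +
#' errors`), repeatedly removes the candidate whose multi-trait Wald p-value
#' is largest among those above the comparisonwise threshold, and refits,
#' until every remaining candidate survives. May return an empty set.
#'
#' @param traits Lines x traits matrix of genotype means.
#' @param probs Conditional probability matrix carrying the scan grid.
#' @param candidates Candidate positions (columns `chromosome`, `position`).
#' @param p_cutoff Comparisonwise p-value threshold (e.g. from
#'   [genomewide_threshold()]).
#' @param pvalue Reference distribution, as in [wald_test()].
#' @return The surviving subset of `candidates`.
#' @export
backward_eliminate <- function(traits, probs, candidates, p_cutoff,
                               pvalue = "f") {
  grid <- attr(probs, "grid")
  cand <- candidates
  while (nrow(cand)) {
    idx <- grid_index(grid, cand)
    S <- probs[, idx, drop = FALSE]
    fit <- .joint_qtl_fit(traits, S, pvalue)
    worst <- which.max(fit$p)
    if (fit$p[worst] <= p_cutoff) break
    cand <- cand[-worst, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

#' Estimate per-trait effects of the final QTL set
#'
#' Joint fit of all retained QTL; effects are reported as the B-parent-class
#' minus A-parent-class difference per trait (the 0/1 genotype coding), with
#' standard errors and the high-value parent derived from the effect sign.
#'
#' @inheritParams backward_eliminate
#' @param final_set Final QTL positions.
#' @param map Optional [genetic_map()] used to report the nearest flanking
#'   markers of each QTL.
#' @param parents Names substituted for the A- and B-parent classes in the
#'   high-value-allele report.
#' @return A `qtl_model` list: `qtl` (positions with nearest flanking
#'   markers), `effects`, `se`, `high_value` matrices (QTL x trait), `wald`,
#'   `p`.
#' @export
estimate_qtl_effects <- function(traits, probs, final_set, map = NULL,
                                 parents = c(A = "A-parent", B = "B-parent"),
                                 pvalue = "f") {
  grid <- attr(probs, "grid")
  if (!nrow(final_set))
    return(structure(list(qtl = final_set, effects = NULL, se = NULL,
                          high_value = NULL, wald = numeric(0),
                          p = numeric(0)), class = "qtl_model"))
  idx <- grid_index(grid, final_set)
  S <- probs[, idx, drop = FALSE]
  fit <- .joint_qtl_fit(traits, S, pvalue)
  eff <- fit$effects
  dimnames(eff) <- list(NULL, colnames(traits))
  se <- fit$se
  dimnames(se) <- dimnames(eff)
  hv <- ifelse(eff > 0, parents[["B"]], parents[["A"]])
  qtl <- data.frame(chromosome = final_set$chromosome,
                    position = final_set$position,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    fl <- t(vapply(seq_len(nrow(qtl)), function(i) {
      sub <- map[map$chromosome == qtl$chromosome[i], , drop = FALSE]
      d <- sub$position - qtl$position[i]
      left <- sub$marker[d <= 1e-9]
      right <- sub$marker[d >= -1e-9]
      c(if (length(left)) left[length(left)] else NA_character_,
        if (length(right)) right[1] else NA_character_)
    }, character(2)))
    qtl$flank_left <- fl[, 1]; qtl$flank_right <- fl[, 2]
  }
  structure(list(qtl = qtl, effects = eff, se = se, high_value = hv,
                 wald = fit$wald, p = fit$p),
            class = "qtl_model")
}

#' Percentage of genetic variance explained by each QTL
#'
#' The %GV of QTL `q` for trait `t` is the relative drop in the model's
#' genetic (residual-minus-error-floor) variance when `q` is added to the
#' polygenic-only base model: `100 (G_base - V_+q) / G_base`. The per-trait
#' "Total" adds all QTL jointly. Negative drops are floored at zero.
#'
#' @inheritParams backward_eliminate
#' @param final_set Final QTL positions.
#' @param base A [fit_base_model()] result (determines the error floors).
#' @return List with `per_qtl` (QTL x trait matrix) and `total` (per trait).
#' @export
percent_genetic_variance <- function(traits, probs, final_set, base) {
  Y <- as.matrix(traits)
  Tt <- ncol(Y)
  floors <- base$error_floors
  G <- base$genetic_var
  if (!nrow(final_set))
    return(list(per_qtl = matrix(0, 0, Tt, dimnames = list(NULL, colnames(Y))),
                total = stats::setNames(rep(0, Tt), colnames(Y))))
  grid <- attr(probs, "grid")
  idx <- grid_index(grid, final_set)
  resid_gvar <- function(S) {
    X <- cbind(1, S)
    fit <- .mls_fit(Y, X)
    pmax(diag(fit$sigma) - floors, 0)
  }
  per <- t(vapply(seq_along(idx), function(j) {
    V <- resid_gvar(probs[, idx[j], drop = FALSE])
    100 * pmax(G - V, 0) / G
  }, numeric(Tt)))
  colnames(per) <- colnames(Y)
  V_all <- resid_gvar(probs[, idx, drop = FALSE])
  total <- 100 * pmax(G - V_all, 0) / G
  names(total) <- colnames(Y)
  per <- pmin(per, 100)
  total <- pmin(total, 100)
  list(per_qtl = per, total = total)
}

#' Full multi-trait QTL analysis
#'
#' Runs the complete stage-2 protocol on a table of genotype means: builds
#' the scan grid and conditional QTL probabilities, sets the genome-wide
#' threshold from the effective number of tests, performs a simple interval
#' mapping round, iterates composite interval mapping with the candidate set
#' as cofactors, removes redundant candidates by backward elimination, and
#' reports the final joint model with per-trait effects, standard errors,
#' high-value parents and the percentage of genetic variance explained.
#'
#' @param traits Lines x traits matrix of genotype means (rownames = lines).
#' @param geno A [genotype_matrix()] covering the same lines.
#' @param map The matching [genetic_map()].
#' @param step Scan grid step in centimorgan.
#' @param alpha Genome-wide test level.
#' @param min_separation Minimum distance between candidate QTL on one
#'   chromosome (cM).
#' @param window Cofactor exclusion window (cM).
#' @param max_rounds Maximum CIM rounds.
#' @param error_floors Optional per-trait stage-1 error floors
#'   (`sigma_e^2 / r`) separating genetic from error variance in %GV.
#' @param parents High-value-allele labels, see [estimate_qtl_effects()].
#' @param pvalue Reference distribution for p-values, see [wald_test()].
#' @return A `qtl_scan` list: `sim` and final `scan` profiles, `threshold`,
#'   `candidates`, `model` (the final [estimate_qtl_effects()] result),
#'   `pgv`, `base`, and the settings used.
#' @export
scan_qtl <- function(traits, geno, map, step = 2, alpha = 0.05,
                     min_separation = 30, window = 30, max_rounds = 5,
                     error_floors = NULL,
                     parents = c(A = "A-parent", B = "B-parent"),
                     pvalue = "f") {
  traits <- as.matrix(traits)
  common <- intersect(rownames(traits), rownames(geno))
  if (!length(common)) stop("no shared line ids between traits and genotypes")
  if (length(common) < nrow(traits) || length(common) < nrow(geno))
    message("aligning on ", length(common), " shared lines")
  traits <- traits[common, , drop = FALSE]
  geno <- geno[common, , drop = FALSE]
  grid <- build_scan_grid(map, step)
  probs <- qtl_genotype_probs(geno, map, grid)
  thr <- genomewide_threshold(geno, map, alpha)
  sim <- sim_scan(traits, probs, threshold = thr$neglog10, pvalue = pvalue)
  candidates <- select_candidates(sim, thr$neglog10, min_separation)
  if (nrow(candidates)) {
    cim <- run_cim(traits, probs, candidates, thr$neglog10, window,
                   min_separation, max_rounds, pvalue)
    scan <- cim$scan
    candidates <- cim$candidates
  } else scan <- sim
  final <- backward_eliminate(traits, probs, candidates, thr$p_cutoff, pvalue)
  base <- fit_base_model(traits, error_floors)
  model <- estimate_qtl_effects(traits, probs, final, map, parents, pvalue)
  pgv <- percent_genetic_variance(traits, probs, final, base)
  structure(list(sim = sim, scan = scan, threshold = thr,
                 candidates = final, model = model, pgv = pgv, base = base,
                 settings = list(step = step, alpha = alpha,
                                 min_separation = min_separation,
                                 window = window, max_rounds = max_rounds,
                                 pvalue = pvalue),
                 n = nrow(traits)),
            class = "qtl_scan")
}

#' @export
print.qtl_model <- function(x, ...) {
  if (is.null(x$effects) || !nrow(x$qtl)) {
    cat("Empty QTL model (no QTL retained)\n")
    return(invisible(x))
  }
  cat("Final multi-trait QTL model:", nrow(x$qtl), "QTL\n")
  for (i in seq_len(nrow(x$qtl))) {
    cat(sprintf("  chr %s @ %.1f cM  (Wald %.2f, p = %.3g)\n",
                x$qtl$chromosome[i], x$qtl$position[i], x$wald[i], x$p[i]))
    for (t in colnames(x$effects))
      cat(sprintf("    %-12s effect %+0.3f (se %.3f)  high-value: %s\n",
                  t, x$effects[i, t], x$se[i, t], x$high_value[i, t]))
  }
  invisible(x)
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("Multi-trait QTL scan: %d lines, %d grid positions, M_eff = %.1f, -log10(p) threshold = %.2f\n",
              x$n, nrow(x$scan), x$threshold$m_eff, x$threshold$neglog10))
  print(x$model)
  if (!is.null(x$pgv$per_qtl) && nrow(x$pgv$per_qtl)) {
    cat("Percent genetic variance explained (per QTL / total):\n")
    print(round(x$pgv$per_qtl, 2))
    cat("  Total:", paste(sprintf("%s %.2f", names(x$pgv$total),
                                  x$pgv$total), collapse = ", "), "\n")
  }
  invisible(x)
}
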
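#' altqtl: multi-trait QTL mapping for aluminum tolerance trials
#'
#' Two-stage analysis of biparental RIL trials for aluminum tolerance:
#' stage 1 turns raw hydroponic root measurements and field plot yields
#' into adjusted genotype means (BLUEs) with variance components and
#' line-mean heritability; stage 2 maps QTL jointly for the three traits
#' (hydroponic RNRG, grain yield in control and Al-toxic soil) with a
#' multi-trait Wald-test genome scan. A split-plot module analyses
#' isogenic-hybrid yield trials, and a calibrated simulator generates every
#' input format the pipeline consumes.
#'
#' @keywords internal
#' @importFrom stats aggregate aov cor cov lm pchisq pf predict qt rbinom
#'   rnorm sd setNames
"_PACKAGE"

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(out_dir, stage, seed = NULL, settings = NULL,
                           files = character(0)) {
  digests <- if (length(files))
    as.list(tools::md5sum(file.path(out_dir, files))) else list()
  names(digests) <- files
  manifest <- list(stage = stage,
                   package = "altqtl",
                   version = as.character(utils::packageVersion("altqtl")),
                   seed = seed, settings = settings, files = digests)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Generate and write the full synthetic dataset
#'
#' Writes every pipeline input (map, genotypes, hydroponics, field plots,
#' hybrid plots, true trait values) plus a manifest recording the seed and
#' file digests. Deterministic for a fixed seed.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed, or a full [sim_config()] via `config`.
#' @param config Optional [sim_config()] overriding `seed`.
#' @return The simulated dataset (invisibly).
#' @export
run_simulate <- function(out_dir, seed = 1, config = NULL) {
  if (is.null(config)) config <- sim_config(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config)
  write_genetic_map(sim$map, file.path(out_dir, "map.tsv"))
  write_genotypes(sim$geno, file.path(out_dir, "genotypes.tsv"))
  write_tsv(data.frame(line = rownames(sim$traits_true), sim$traits_true),
            file.path(out_dir, "traits_true.tsv"))
  write_tsv(sim$hydro, file.path(out_dir, "hydroponics.tsv"))
  write_tsv(sim$field, file.path(out_dir, "field.tsv"))
  write_tsv(sim$hybrid, file.path(out_dir, "hybrid.tsv"))
  write_manifest(out_dir, "simulate", seed = config$seed,
                 settings = list(n_lines = config$n_lines),
                 files = c("map.tsv", "genotypes.tsv", "traits_true.tsv",
                           "hydroponics.tsv", "field.tsv", "hybrid.tsv"))
  invisible(sim)
}

#' Stage-1 analysis: BLUEs, variance components and heritability
#'
#' Computes RNRG from the hydroponics file, fits the RCBD model (genotype
#' random for variance components and heritability, fixed for BLUEs), fits
#' the per-environment incomplete-block model to the field file the same
#' way, reports the between-environment correlation of yield BLUEs, and
#' assembles the three-trait table for QTL mapping (parents and checks
#' excluded).
#'
#' @param hydro_path Hydroponics file (`line, block, plant, il_c, fl_c,
#'   il_Al, fl_Al`).
#' @param field_path Field file (`line, environment, replicate, block,
#'   yield`).
#' @param out_dir Output directory.
#' @param exclude Entries dropped from the trait table (parents/checks).
#' @return Invisibly, a list with `traits` (the BLUE table), `vc` (variance
#'   component table), `h2`, `correlation` and `error_floors`.
#' @export
run_stage1 <- function(hydro_path, field_path, out_dir,
                       exclude = c("BR007", "SC283", "ATF10B", "ATF8B")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hydro <- utils::read.delim(hydro_path, stringsAsFactors = FALSE)
  field <- utils::read.delim(field_path, stringsAsFactors = FALSE)
  rnrg <- compute_rnrg(hydro)
  rcbd_dat <- data.frame(line = rnrg$line, block = rnrg$block,
                         value = rnrg$rnrg_log10)
  vc_h <- fit_rcbd(rcbd_dat, genotype_random = TRUE)
  blues_h <- fit_rcbd(rcbd_dat, genotype_random = FALSE)
  envs <- c(control = "Gy_control", Al = "Gy_Al")
  vc_f <- list(); blues_f <- list()
  for (env in names(envs)) {
    sub <- field[field$environment == env, , drop = FALSE]
    if (!nrow(sub)) stop("no field plots for environment ", env)
    vc_f[[env]] <- fit_incomplete_block(sub, genotype_random = TRUE)
    blues_f[[env]] <- fit_incomplete_block(sub, genotype_random = FALSE)
  }
  corr <- env_genetic_correlation(blues_f$control, blues_f$Al)
  traits <- assemble_trait_table(RNRG_log10 = blues_h,
                                 Gy_control = blues_f$control,
                                 Gy_Al = blues_f$Al,
                                 exclude = exclude)
  vc_tab <- data.frame(
    trait = c("RNRG_log10", "Gy_control", "Gy_Al"),
    design = c("rcbd", "incomplete_block", "incomplete_block"),
    sigma2_g = c(vc_h$sigma2_g, vc_f$control$sigma2_g, vc_f$Al$sigma2_g),
    sigma2_b = c(NA, vc_f$control$sigma2_b, vc_f$Al$sigma2_b),
    sigma2_e = c(vc_h$sigma2_e, vc_f$control$sigma2_e, vc_f$Al$sigma2_e),
    r = c(vc_h$r, vc_f$control$r, vc_f$Al$r))
  vc_tab$h2 <- c(vc_h$h2, vc_f$control$h2, vc_f$Al$h2)
  vc_tab$error_floor <- vc_tab$sigma2_e / vc_tab$r
  write_tsv(data.frame(line = rownames(traits), traits),
            file.path(out_dir, "blues.tsv"))
  write_tsv(vc_tab, file.path(out_dir, "variance_components.tsv"))
  jsonlite::write_json(
    list(h2 = as.list(setNames(vc_tab$h2, vc_tab$trait)),
         correlation_control_Al = corr,
         n_lines = nrow(traits),
         excluded = exclude,
         plants_excluded = attr(rnrg, "excluded"),
         block_means_clamped = attr(rnrg, "clamped")),
    file.path(out_dir, "stage1_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "stage1",
                 files = c("blues.tsv", "variance_components.tsv",
                           "stage1_summary.json"))
  invisible(list(traits = traits, vc = vc_tab,
                 h2 = setNames(vc_tab$h2, vc_tab$trait),
                 correlation = corr,
                 error_floors = setNames(vc_tab$error_floor, vc_tab$trait)))
}

#' Stage-2 analysis: the multi-trait genome scan
#'
#' Reads the BLUE table, map and genotypes, aligns line ids (misaligned ids
#' are listed), runs the full [scan_qtl()] protocol and writes the scan
#' profile, the QTL report (positions, flanking markers, per-trait effects
#' and standard errors, high-value allele, %GV) and a manifest.
#'
#' @param traits_path BLUE table (column `line` + one column per trait).
#' @param map_path Genetic map file.
#' @param geno_path Genotype file.
#' @param out_dir Output directory.
#' @param vc_path Optional stage-1 variance component table; its
#'   `error_floor` column supplies the per-trait error floors for %GV.
#' @param parents High-value-allele labels for the A and B classes.
#' @param ... Passed to [scan_qtl()] (`step`, `alpha`, `min_separation`,
#'   `window`, `max_rounds`, `pvalue`).
#' @return Invisibly, the [scan_qtl()] result.
#' @export
run_scan <- function(traits_path, map_path, geno_path, out_dir,
                     vc_path = NULL,
                     parents = c(A = "BR007", B = "SC283"), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- utils::read.delim(traits_path, stringsAsFactors = FALSE)
  traits <- as.matrix(tr[, -1, drop = FALSE])
  rownames(traits) <- tr[[1]]
  map <- read_genetic_map(map_path)
  geno <- read_genotypes(geno_path, map)
  only_t <- setdiff(rownames(traits), rownames(geno))
  only_g <- setdiff(rownames(geno), rownames(traits))
  if (length(only_t) || length(only_g))
    message("ids without a match - traits: ",
            paste(utils::head(only_t, 10), collapse = ", "),
            "; genotypes: ", paste(utils::head(only_g, 10), collapse = ", "))
  if (!length(intersect(rownames(traits), rownames(geno))))
    stop("no shared line ids between trait table and genotypes")
  floors <- NULL
  if (!is.null(vc_path)) {
    vc <- utils::read.delim(vc_path, stringsAsFactors = FALSE)
    floors <- setNames(vc$error_floor, vc$trait)[colnames(traits)]
  }
  res <- scan_qtl(traits, geno, map, error_floors = floors,
                  parents = parents, ...)
  prof <- res$scan
  prof$threshold <- res$threshold$neglog10
  write_tsv(prof, file.path(out_dir, "scan_profile.tsv"))
  write_tsv(qtl_report(res), file.path(out_dir, "qtl_report.tsv"))
  write_manifest(out_dir, "scan",
                 settings = c(res$settings,
                              list(m_eff = res$threshold$m_eff,
                                   p_cutoff = res$threshold$p_cutoff)),
                 files = c("scan_profile.tsv", "qtl_report.tsv"))
  invisible(res)
}

#' Tabulate a fitted QTL model, one row per QTL x trait
#'
#' @param res A [scan_qtl()] result.
#' @return Data frame mirroring the standard multi-trait QTL report:
#'   chromosome, position, flanking markers, trait, effect, standard error,
#'   high-value allele, %GV and the per-trait total %GV.
#' @export
qtl_report <- function(res) {
  m <- res$model
  if (is.null(m$effects) || !nrow(m$qtl))
    return(data.frame(qtl = character(0), chromosome = character(0),
                      position_cM = numeric(0), flank_left = character(0),
                      flank_right = character(0), trait = character(0),
                      effect = numeric(0), se = numeric(0),
                      high_value_allele = character(0), pgv = numeric(0),
                      total_pgv = numeric(0)))
  rows <- list()
  for (i in seq_len(nrow(m$qtl))) {
    for (t in colnames(m$effects)) {
      rows[[length(rows) + 1L]] <- data.frame(
        qtl = paste0("q", m$qtl$chromosome[i]),
        chromosome = m$qtl$chromosome[i],
        position_cM = m$qtl$position[i],
        flank_left = if ("flank_left" %in% names(m$qtl))
          m$qtl$flank_left[i] else NA,
        flank_right = if ("flank_right" %in% names(m$qtl))
          m$qtl$flank_right[i] else NA,
        trait = t,
        effect = m$effects[i, t],
        se = m$se[i, t],
        high_value_allele = m$high_value[i, t],
        pgv = res$pgv$per_qtl[i, t],
        total_pgv = res$pgv$total[[t]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split-plot analysis of a hybrid trial file
#'
#' Runs [split_plot_anova()] and [dosage_covariate_test()] on a hybrid plot
#' file and writes the ANOVA table, the marginal means with their LSDs and
#' the dosage-test summary.
#'
#' @param plots_path Hybrid plot file (`whole_plot, treatment, hybrid,
#'   female, male, dosage, yield`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `split_plot_fit` and the dosage test.
#' @export
run_hybrid_anova <- function(plots_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plots <- utils::read.delim(plots_path, stringsAsFactors = FALSE)
  fit <- split_plot_anova(plots)
  dosage <- if (length(unique(plots$dosage)) > 1)
    dosage_covariate_test(plots) else NULL
  write_tsv(fit$anova, file.path(out_dir, "anova.tsv"))
  means <- do.call(rbind, lapply(names(fit$means), function(nm)
    data.frame(factor = nm, level = names(fit$means[[nm]]),
               mean = as.numeric(fit$means[[nm]]),
               lsd = fit$lsd[[nm]], stringsAsFactors = FALSE)))
  write_tsv(means, file.path(out_dir, "means.tsv"))
  jsonlite::write_json(
    list(dosage_test = dosage,
         lsd = as.list(fit$lsd)),
    file.path(out_dir, "hybrid_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "hybrid-anova",
                 files = c("anova.tsv", "means.tsv", "hybrid_summary.json"))
  invisible(list(fit = fit, dosage = dosage))
}
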
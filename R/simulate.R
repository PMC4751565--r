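#' Simulation configuration for the full trial design
#'
#' Bundles every default the generator needs. The defaults emulate the
#' study conditions the pipeline is built for: 90 RILs genotyped at 344
#' markers on 10 chromosomes, two pleiotropic QTL (chromosome 3 at 184.2 cM
#' and chromosome 9 at 214.0 cM) with per-trait allele-substitution effects
#' `(0.71, 0.19, 0.61)` and `(0.34, -0.66, -0.36)` on the B-allele (SC283)
#' coding, a correlated polygenic background whose per-trait variances are
#' back-solved from the reported %GV arithmetic, a two-block seven-plant
#' hydroponic design, a three-replicate ten-incomplete-block field design
#' per environment (with the tolerant parent replicated nine times as a
#' check), and the 2 x 4 factorial isogenic-hybrid split-plot trial
#' calibrated so the expected marginal means are 3.46/3.96 t/ha for the two
#' females and 4.18/3.24 t/ha for the two environments. See the methods
#' vignette for the derivation of every default.
#'
#' @param seed Integer seed (mandatory); child seeds for each component are
#'   derived from it so stages can be regenerated in isolation.
#' @param n_lines Number of RILs.
#' @param ... Named overrides of any top-level default (e.g. `qtl`,
#'   `sigma_poly`, `field`, `hydro`, `hybrid`, `map`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_lines = 90, ...) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory")
  seed <- as.integer(seed)
  traits <- c("RNRG_log10", "Gy_control", "Gy_Al")
  effects <- rbind(c(0.71, 0.19, 0.61),
                   c(0.34, -0.66, -0.36))
  colnames(effects) <- traits
  sds <- sqrt(c(0.097, 0.135, 0.115))
  cors <- matrix(c(1, 0.1, 0.4,
                   0.1, 1, 0.5,
                   0.4, 0.5, 1), 3, 3, dimnames = list(traits, traits))
  sigma_poly <- diag(sds) %*% cors %*% diag(sds)
  dimnames(sigma_poly) <- list(traits, traits)
  cfg <- list(
    seed = seed,
    n_lines = n_lines,
    traits = traits,
    map = list(n_chr = 10,
               n_markers = c(45, 40, 40, 35, 35, 30, 30, 30, 34, 25),
               lengths = c(200, 190, 195, 160, 160, 140, 140, 140, 225, 110),
               anchor = data.frame(chromosome = c("3", "9"),
                                   position = c(184.2, 214.0))),
    qtl = list(chromosome = c("3", "9"), position = c(184.2, 214.0),
               effects = effects),
    mu = stats::setNames(c(1.05, 3.587, 2.221), traits),
    sigma_poly = sigma_poly,
    # stage-1 line-mean error floors: sigma_e^2 / r per trait
    error = list(hydro_plant_sd = 0.65, hydro_block_sd = 0.10,
                 field_sigma2_e = c(control = 0.185, Al = 0.22),
                 field_sigma2_b = 0.05, field_rep_sd = 0.15),
    hydro = list(n_blocks = 2, n_plants = 7, il_mean = 5, il_sd = 0.5,
                 crgr_mean = 6, crgr_sd = 1,
                 checks = c(ATF10B = 117, ATF8B = 12)),
    field = list(n_reps = 3, n_blocks = 10,
                 checks = c(BR007 = 1, SC283 = 9)),
    hybrid = list(base = 3.085,
                  treatment_effect = c(control = 0.47, Al = -0.47),
                  allele_effect = 0.5, al_extra_per_copy = 0,
                  male_effect = c(BR012R = 0, `BR012(SC566)` = 0,
                                  `BR012(SC549)` = 0, `BR012(CMS225)` = 0),
                  whole_plot_sd = 0.41, subplot_sd = 0.89))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
        !is.data.frame(over[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop("unknown config key(s): ",
             paste(paste(nm, bad, sep = "$"), collapse = ", "))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  ev <- eigen(cfg$sigma_poly, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("sigma_poly must be positive semi-definite")
  structure(cfg, class = "sim_config")
}

# Per-trait stage-1 line-mean error variance implied by the config
# (hydroponics: plant-level log10 variance averaged over plants and blocks;
# field: plot error variance over replicates).
config_error_floors <- function(config) {
  e <- config$error
  h <- config$hydro
  # block enters the RCBD model as a fixed effect, so the line-mean error is
  # the plant-level log10 variance averaged over plants, then blocks
  hydro_block_var <- e$hydro_plant_sd^2 / h$n_plants
  stats::setNames(
    c(hydro_block_var / h$n_blocks,
      e$field_sigma2_e[["control"]] / config$field$n_reps,
      e$field_sigma2_e[["Al"]] / config$field$n_reps),
    config$traits)
}

#' Simulate the linkage map
#'
#' Markers are evenly spaced along each chromosome; the marker nearest each
#' anchor position (the two QTL) is snapped onto it so both QTL sit at
#' grid-reachable loci. The map is deterministic given the config.
#'
#' @param config A [sim_config()].
#' @return A [genetic_map()] with `sum(config$map$n_markers)` markers.
#' @export
simulate_map <- function(config) {
  m <- config$map
  pieces <- lapply(seq_len(m$n_chr), function(ch) {
    k <- m$n_markers[ch]
    pos <- seq(0, m$lengths[ch], length.out = k)
    anchors <- m$anchor[m$anchor$chromosome == as.character(ch), , drop = FALSE]
    for (a in anchors$position) {
      if (a > m$lengths[ch])
        stop("chromosome ", ch, " shorter than anchor position ", a)
      pos[which.min(abs(pos - a))] <- a
    }
    pos <- sort(pos)
    data.frame(marker = sprintf("c%dm%02d", ch, seq_len(k)),
               chromosome = as.character(ch), position = pos,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  genetic_map(all$marker, all$chromosome, all$position)
}

#' Simulate RIL genotypes by single seed descent
#'
#' Each line is an independent realization of the two-state Markov chain
#' along every chromosome, with transition probability between adjacent
#' markers equal to the RIL-class recombination fraction
#' [ril_recombination_fraction()] of their distance; marginal allele
#' frequency is 1/2 at every locus.
#'
#' @param map A [genetic_map()].
#' @param n_lines Number of lines.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with no missing data, line ids
#'   `RIL001, ...`.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed) {
  set.seed(as.integer(seed))
  codes <- matrix(NA_integer_, n_lines, nrow(map),
                  dimnames = list(sprintf("RIL%03d", seq_len(n_lines)),
                                  map$marker))
  for (ch in unique(map$chromosome)) {
    mi <- which(map$chromosome == ch)
    pos <- map$position[mi]
    g <- matrix(0L, n_lines, length(mi))
    g[, 1] <- stats::rbinom(n_lines, 1, 0.5)
    if (length(mi) > 1) {
      R <- ril_recombination_fraction(diff(pos))
      for (j in 2:length(mi)) {
        sw <- stats::rbinom(n_lines, 1, R[j - 1])
        g[, j] <- ifelse(sw == 1L, 1L - g[, j - 1], g[, j - 1])
      }
    }
    codes[, mi] <- g
  }
  genotype_matrix(codes, map)
}

#' Simulate true line values for the three traits
#'
#' `y_lt = mu_t + sum_q x_lq beta_qt + g_lt (+ e_lt)`, with `x` the 0/1 QTL
#' genotype, `g` multivariate normal with the polygenic covariance, and an
#' optional independent per-trait line-mean error (emulating stage-1 noise
#' in the BLUEs).
#'
#' @param geno A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @param config A [sim_config()] (supplies QTL, `mu`, `sigma_poly`).
#' @param seed Integer seed.
#' @param line_error_var Optional per-trait error variance added to the
#'   line values (use [config_error_floors()] for the stage-1-implied
#'   floors).
#' @return Matrix (lines x traits).
#' @export
simulate_traits <- function(geno, map, config, seed, line_error_var = NULL) {
  set.seed(as.integer(seed))
  q <- config$qtl
  qpos <- data.frame(chromosome = q$chromosome, position = q$position)
  probs <- qtl_genotype_probs(geno, map, cbind(qpos, marker = NA))
  X <- probs[, seq_len(nrow(qpos)), drop = FALSE]
  n <- nrow(geno)
  G <- MASS::mvrnorm(n, mu = rep(0, length(config$traits)),
                     Sigma = config$sigma_poly)
  Y <- matrix(config$mu, n, length(config$traits), byrow = TRUE) +
    X %*% q$effects + G
  if (!is.null(line_error_var)) {
    E <- vapply(line_error_var,
                function(v) stats::rnorm(n, 0, sqrt(v)), numeric(n))
    Y <- Y + E
  }
  dimnames(Y) <- list(rownames(geno), config$traits)
  Y
}

# True parental trait values (fixed effects only): A parent carries x = 0
# everywhere, B parent x = 1.
parent_true_values <- function(config) {
  b <- colSums(config$qtl$effects)
  rbind(BR007 = config$mu, SC283 = config$mu + b)
}

#' Simulate the two-environment field trial
#'
#' Lays out, per environment, `n_reps` replicates of `n_blocks` incomplete
#' blocks holding the RILs plus check entries (by default the A parent once
#' and the B parent nine times per replicate), and generates plot yield =
#' true line value + replicate effect + incomplete-block effect + plot
#' error, with environment-specific error variances.
#'
#' @param true_gy Matrix (lines x 2) of true yields with columns
#'   `Gy_control`, `Gy_Al`, including any check entries as rows.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `line`, `environment`, `replicate`,
#'   `block`, `yield`.
#' @export
simulate_field_trial <- function(true_gy, config, seed) {
  set.seed(as.integer(seed))
  f <- config$field
  e <- config$error
  ril_ids <- setdiff(rownames(true_gy), names(f$checks))
  entries <- c(ril_ids, rep(names(f$checks), times = f$checks))
  per_block <- length(entries) / f$n_blocks
  if (per_block != round(per_block))
    stop("entry count ", length(entries), " not divisible into ",
         f$n_blocks, " blocks")
  env_col <- c(control = "Gy_control", Al = "Gy_Al")
  out <- list()
  for (env in names(env_col)) {
    sde <- sqrt(e$field_sigma2_e[[env]])
    for (rep_i in seq_len(f$n_reps)) {
      laid <- sample(entries)
      block <- rep(seq_len(f$n_blocks), each = per_block)
      rep_eff <- stats::rnorm(1, 0, e$field_rep_sd)
      blk_eff <- stats::rnorm(f$n_blocks, 0, sqrt(e$field_sigma2_b))
      yield <- true_gy[laid, env_col[[env]]] + rep_eff + blk_eff[block] +
        stats::rnorm(length(laid), 0, sde)
      out[[length(out) + 1L]] <- data.frame(
        line = laid, environment = env, replicate = paste0("rep", rep_i),
        block = paste0("b", block), yield = as.numeric(yield),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate the hydroponic root-growth experiment
#'
#' For every entry (RILs plus tolerant/sensitive check NILs), generates
#' per-plant initial and final root lengths in control and Al solution such
#' that the plant-level computed RNRG is the entry's true percent value
#' times a log10-normal block and plant deviation; with both deviations at
#' zero the computed index is exactly the configured percent.
#'
#' @param true_rnrg_pct Named vector of true RNRG values on the percent
#'   scale (checks included).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `line`, `block`, `plant`, `il_c`,
#'   `fl_c`, `il_Al`, `fl_Al`.
#' @export
simulate_hydroponics <- function(true_rnrg_pct, config, seed) {
  set.seed(as.integer(seed))
  h <- config$hydro
  e <- config$error
  if (h$il_mean <= 0 || h$crgr_mean <= 0)
    stop("configured root lengths must be positive")
  ids <- names(true_rnrg_pct)
  n_rec <- length(ids) * h$n_blocks * h$n_plants
  d <- expand.grid(plant = seq_len(h$n_plants),
                   block = paste0("block", seq_len(h$n_blocks)),
                   line = ids, stringsAsFactors = FALSE)
  blk_eff <- stats::rnorm(h$n_blocks, 0, e$hydro_block_sd)
  names(blk_eff) <- paste0("block", seq_len(h$n_blocks))
  il_c <- stats::rnorm(n_rec, h$il_mean, h$il_sd)
  il_al <- stats::rnorm(n_rec, h$il_mean, h$il_sd)
  crgr <- pmax(stats::rnorm(n_rec, h$crgr_mean, h$crgr_sd), 0.5)
  ratio <- true_rnrg_pct[d$line] / 100 *
    10^(blk_eff[d$block] + stats::rnorm(n_rec, 0, e$hydro_plant_sd))
  data.frame(line = d$line, block = d$block, plant = d$plant,
             il_c = il_c, fl_c = il_c + crgr,
             il_Al = il_al, fl_Al = il_al + crgr * ratio,
             stringsAsFactors = FALSE)
}

# Hybrid design table: 2 females x 4 males with the tolerance-allele dosage
# implied by the parents (female adds one T copy, the three tolerant-donor
# males one more).
hybrid_design <- function() {
  males <- c("BR012R", "BR012(SC566)", "BR012(SC549)", "BR012(CMS225)")
  d <- expand.grid(female = c("ATF13A", "ATF14A"), male = males,
                   stringsAsFactors = FALSE)
  d <- d[order(match(d$male, males), d$female), ]
  d$hybrid <- paste0("H", seq_len(8))
  d$dosage <- (d$female == "ATF14A") + (d$male != "BR012R")
  rownames(d) <- NULL
  d[, c("hybrid", "female", "male", "dosage")]
}

#' Simulate the isogenic-hybrid split-plot yield trial
#'
#' Eight whole plots (four per treatment, completely randomized) each carry
#' the eight hybrids as sub plots. Yield = base + treatment effect +
#' whole-plot error + allele-dosage effect (+ optional extra per-copy
#' effect under Al, + male background effects) + sub-plot error. The
#' defaults are calibrated so the expected female marginals are 3.46 and
#' 3.96 t/ha and the environment marginals 4.18 and 3.24 t/ha.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `whole_plot`, `treatment`, `hybrid`,
#'   `female`, `male`, `dosage`, `yield`.
#' @export
simulate_hybrid_trial <- function(config, seed) {
  set.seed(as.integer(seed))
  hy <- config$hybrid
  des <- hybrid_design()
  wp <- expand.grid(rep = 1:4, treatment = c("control", "Al"),
                    stringsAsFactors = FALSE)
  wp$whole_plot <- paste0(ifelse(wp$treatment == "control", "C", "A"), wp$rep)
  out <- list()
  for (i in seq_len(nrow(wp))) {
    wp_err <- stats::rnorm(1, 0, hy$whole_plot_sd)
    sub <- des[sample.int(nrow(des)), , drop = FALSE]
    al <- wp$treatment[i] == "Al"
    yield <- hy$base + hy$treatment_effect[[wp$treatment[i]]] + wp_err +
      hy$allele_effect * sub$dosage +
      (if (al) hy$al_extra_per_copy * sub$dosage else 0) +
      hy$male_effect[sub$male] +
      stats::rnorm(nrow(sub), 0, hy$subplot_sd)
    out[[i]] <- data.frame(whole_plot = wp$whole_plot[i],
                           treatment = wp$treatment[i],
                           hybrid = sub$hybrid, female = sub$female,
                           male = sub$male, dosage = sub$dosage,
                           yield = as.numeric(yield),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate the complete study dataset
#'
#' Fans the global seed out to per-component child seeds (map is
#' deterministic; genotypes, traits, field, hydroponics and hybrid trial
#' each get their own), so any stage can be regenerated in isolation, and
#' returns every input the pipeline consumes.
#'
#' @param config A [sim_config()].
#' @return List with `map`, `geno`, `traits_true`, `hydro`, `field`,
#'   `hybrid`, `config` and the derived `seeds`.
#' @export
simulate_dataset <- function(config) {
  seeds <- config$seed + c(geno = 1L, traits = 2L, field = 3L,
                           hydro = 4L, hybrid = 5L)
  map <- simulate_map(config)
  geno <- simulate_ril_genotypes(map, config$n_lines, seeds[["geno"]])
  traits_true <- simulate_traits(geno, map, config, seeds[["traits"]])
  parents <- parent_true_values(config)
  true_gy <- rbind(traits_true[, c("Gy_control", "Gy_Al")],
                   parents[, c("Gy_control", "Gy_Al")])
  field <- simulate_field_trial(true_gy, config, seeds[["field"]])
  true_pct <- c(10^traits_true[, "RNRG_log10"],
                10^parents[, "RNRG_log10"],
                config$hydro$checks)
  hydro <- simulate_hydroponics(true_pct, config, seeds[["hydro"]])
  hybrid <- simulate_hybrid_trial(config, seeds[["hybrid"]])
  list(map = map, geno = geno, traits_true = traits_true, hydro = hydro,
       field = field, hybrid = hybrid, config = config, seeds = seeds)
}
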
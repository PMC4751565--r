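# shared fixtures, built in code at test time

# 3-marker single-chromosome map at 0/10/20 cM
tiny_map <- function() {
  genetic_map(c("m1", "m2", "m3"), rep("1", 3), c(0, 10, 20))
}

# reference RIL recombination fraction, written out from first principles so
# package internals are not reused in expectations
ref_ril_R <- function(d) {
  r <- (1 - exp(-2 * d / 100)) / 2
  2 * r / (1 + 2 * r)
}

# genotype matrix from a plain matrix of 0/1/NA
geno_from <- function(codes, map, lines = NULL) {
  if (is.null(lines)) lines <- sprintf("L%02d", seq_len(nrow(codes)))
  dimnames(codes) <- list(lines, map$marker)
  suppressWarnings(genotype_matrix(codes, map))
}

# default study configuration with the simulator's stage-1-implied
# line-mean noise, for stage-2-only experiments
study_traits <- function(cfg, geno, map, seed, noise = TRUE) {
  floors <- if (noise) altqtl:::config_error_floors(cfg) else NULL
  simulate_traits(geno, map, cfg, seed = seed, line_error_var = floors)
}

# balanced RCBD data frame from a line x block matrix of means + noise
rcbd_frame <- function(mu_line, n_block, sd = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(line = names(mu_line), block = paste0("b", seq_len(n_block)),
                   stringsAsFactors = FALSE)
  d$value <- mu_line[d$line] + rnorm(nrow(d), 0, sd)
  d
}
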
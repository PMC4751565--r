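test_that("RNRG arithmetic, exclusions and clamping behave as specified", {
  rec <- data.frame(line = c("L1", "L1", "L2", "L3"),
                    block = "b1", plant = c(1, 2, 1, 1),
                    il_c = c(5, 5, 5, 5), fl_c = c(11, 11, 11, 5),
                    il_Al = c(5, 5, 5, 5), fl_Al = c(11, 8, 4.9, 9))
  # L3 has a non-growing control root and must be excluded
  expect_message(r <- compute_rnrg(rec), "1 plant")
  expect_equal(nrow(r), 2)
  # equal net growth: RNRG = 100, log10 = 2; half growth within the same
  # line averages with it
  expect_equal(r$rnrg_pct[r$line == "L1"], mean(c(100, 50)))
  # negative net Al growth drives the block mean below the floor: clamped
  expect_equal(r$rnrg_pct[r$line == "L2"], 100 * (-0.1) / 6, tolerance = 1e-9)
  expect_equal(r$rnrg_log10[r$line == "L2"], log10(1))
  expect_equal(attr(r, "clamped"), 1)

  # a plant with exactly half control growth alone gives RNRG = 50
  one <- data.frame(line = "L", block = "b", plant = 1,
                    il_c = 4, fl_c = 10, il_Al = 4, fl_Al = 7)
  expect_equal(compute_rnrg(one)$rnrg_pct, 50)
})

test_that("RCBD fit returns adjusted means and heritability components", {
  mu <- c(L1 = 10, L2 = 12, L3 = 9)
  d <- rcbd_frame(mu, n_block = 2)
  d$value <- d$value + ifelse(d$block == "b2", 0.7, 0)  # pure block shift
  blues <- fit_rcbd(d, genotype_random = FALSE)
  # balanced data: BLUEs equal raw genotype means
  expect_equal(unname(blues[names(mu)]),
               unname(c(tapply(d$value, d$line, mean))[names(mu)]),
               tolerance = 1e-10)

  # no genetic signal: genotypic variance sits on the zero boundary
  d0 <- rcbd_frame(setNames(rep(5, 100), paste0("N", 1:100)), n_block = 2,
                   sd = 1, seed = 40)
  d0$value <- d0$value + ifelse(d0$block == "b2", 0.3, 0)
  vc0 <- suppressWarnings(suppressMessages(fit_rcbd(d0, genotype_random = TRUE)))
  expect_lt(vc0$sigma2_g, 0.05)
  expect_lt(vc0$h2, 0.1)

  expect_error(fit_rcbd(rcbd_frame(mu, n_block = 1)), "2 blocks")

  # h2 identity holds on every fit
  set.seed(41)
  d1 <- rcbd_frame(setNames(rnorm(30), paste0("G", 1:30)), n_block = 2,
                   sd = 0.8, seed = 42)
  vc1 <- fit_rcbd(d1, genotype_random = TRUE)
  expect_equal(vc1$h2, vc1$sigma2_g / (vc1$sigma2_g + vc1$sigma2_e / 2))
})

test_that("RCBD heritability is recovered without bias (sigma_g = sigma_e = 1, r = 2)", {
  set.seed(43)
  n_line <- 60
  h2 <- replicate(200, {
    g <- rnorm(n_line)
    d <- expand.grid(line = sprintf("G%02d", 1:n_line), block = c("b1", "b2"),
                     stringsAsFactors = FALSE)
    d$value <- g[as.integer(factor(d$line))] + rnorm(nrow(d))
    suppressWarnings(suppressMessages(fit_rcbd(d, genotype_random = TRUE)))$h2
  })
  # closed form: 1 / (1 + 1/2) = 2/3; the ratio estimator carries a small
  # O(1/n) downward bias on top of MC error of the mean (~0.004)
  expect_lt(abs(mean(h2) - 2 / 3), 0.03)
})

test_that("incomplete-block fit recovers components and merges check plots", {
  cfg <- sim_config(seed = 51)
  set.seed(52)
  n <- 51
  truth <- setNames(rnorm(n, 3.3, sqrt(0.30)), sprintf("G%02d", 1:n))
  truth <- c(truth, SC283 = 3.0)
  cfg2 <- sim_config(seed = 51, field = list(n_reps = 3, n_blocks = 10,
                                             checks = c(SC283 = 9)))
  tg <- cbind(Gy_control = truth, Gy_Al = truth)
  plots <- simulate_field_trial(tg, cfg2, seed = 53)
  sub <- plots[plots$environment == "control", ]
  # the nine-fold replicated check collapses to a single BLUE
  blues <- fit_incomplete_block(sub, genotype_random = FALSE)
  expect_equal(length(blues), n + 1)
  expect_equal(sum(names(blues) == "SC283"), 1)
  expect_equal(unname(blues["SC283"]), 3.0,
               tolerance = 4 * sqrt(0.185 / 27) + 0.2)
  vc <- fit_incomplete_block(sub, genotype_random = TRUE)
  expect_s3_class(vc, "variance_components")
  expect_equal(vc$h2, vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e / 3))

  # degenerate block variance: estimates near zero and BLUEs agree with the
  # complete-block adjusted means
  cfg0 <- sim_config(seed = 51,
                     field = list(n_reps = 3, n_blocks = 10,
                                  checks = c(SC283 = 9)),
                     error = list(hydro_plant_sd = 0.65, hydro_block_sd = 0.1,
                                  field_sigma2_e = c(control = 0.02, Al = 0.02),
                                  field_sigma2_b = 0, field_rep_sd = 0.1))
  plots0 <- simulate_field_trial(tg, cfg0, seed = 54)
  sub0 <- plots0[plots0$environment == "control", ]
  vc0 <- suppressMessages(fit_incomplete_block(sub0, genotype_random = TRUE))
  expect_lt(vc0$sigma2_b, 0.01)
  blues0 <- suppressMessages(fit_incomplete_block(sub0, genotype_random = FALSE))
  d0 <- data.frame(line = sub0$line, block = sub0$replicate, value = sub0$yield)
  rcbd0 <- fit_rcbd(d0, genotype_random = FALSE)
  expect_equal(blues0[names(truth)], rcbd0[names(truth)], tolerance = 0.02)
})

test_that("incomplete-block variance recovery is unbiased within MC error", {
  set.seed(61)
  cfg <- sim_config(seed = 61,
                    field = list(n_reps = 3, n_blocks = 10,
                                 checks = c(SC283 = 0)),
                    error = list(hydro_plant_sd = 0.65, hydro_block_sd = 0.1,
                                 field_sigma2_e = c(control = 0.20, Al = 0.20),
                                 field_sigma2_b = 0.05, field_rep_sd = 0.1))
  reps <- 120
  est <- replicate(reps, {
    truth <- setNames(rnorm(100, 0, sqrt(0.30)), sprintf("G%03d", 1:100))
    tg <- cbind(Gy_control = truth, Gy_Al = truth)
    plots <- simulate_field_trial(tg, cfg, seed = sample.int(1e8, 1))
    sub <- plots[plots$environment == "control", ]
    vc <- suppressMessages(fit_incomplete_block(sub, genotype_random = TRUE))
    c(vc$sigma2_g, vc$sigma2_b, vc$sigma2_e)
  })
  m <- rowMeans(est)
  se <- apply(est, 1, sd) / sqrt(reps)
  expect_lt(abs(m[1] - 0.30), max(4 * se[1], 0.02))
  expect_lt(abs(m[2] - 0.05), max(4 * se[2], 0.02))
  expect_lt(abs(m[3] - 0.20), max(4 * se[3], 0.02))
})

test_that("environment correlation and trait-table assembly", {
  x <- setNames(rnorm(50), paste0("G", 1:50))
  expect_equal(suppressMessages(env_genetic_correlation(x, x)), 1)
  set.seed(71)
  y <- setNames(rnorm(50), paste0("G", 1:50))
  expect_lt(abs(suppressMessages(env_genetic_correlation(x, y))),
            4 / sqrt(50))
  expect_error(suppressMessages(env_genetic_correlation(x[1:2], x[1:2])),
               "3 shared")

  # attenuation: observed correlation between noisy BLUEs falls between
  # rho * h1 * h2 ... rho (checked against the closed form rho*sqrt(h2_1 h2_2))
  set.seed(72)
  reps <- 200
  rho <- 0.6; h2_1 <- 0.8; h2_2 <- 0.7
  obs <- replicate(reps, {
    g <- MASS::mvrnorm(90, c(0, 0),
                       matrix(c(1, rho, rho, 1), 2))
    b1 <- g[, 1] + rnorm(90, 0, sqrt(1 / h2_1 - 1))
    b2 <- g[, 2] + rnorm(90, 0, sqrt(1 / h2_2 - 1))
    cor(b1, b2)
  })
  expect_equal(mean(obs), rho * sqrt(h2_1 * h2_2), tolerance = 0.03)

  # assembly: inner join, logged drops, configurable exclusions
  a <- setNames(1:5, paste0("L", 1:5))
  b <- setNames(1:4, paste0("L", 1:4))
  cc <- setNames(1:5, paste0("L", 1:5))
  expect_message(tt <- assemble_trait_table(t1 = a, t2 = b, t3 = cc),
                 "dropped")
  expect_equal(rownames(tt), paste0("L", 1:4))
  tt2 <- assemble_trait_table(t1 = a, t2 = a, t3 = a, exclude = "L5")
  expect_equal(nrow(tt2), 4)
  expect_error(assemble_trait_table(t1 = a,
                                    t2 = setNames(1, "Z"), t3 = a),
               "no lines")
})
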
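glo_meta <- function() {
  g <- expand.grid(replicate = paste0("R", 1:3),
                   time_point = c("15m", "1h", "4h"),
                   conditioning_type = c("Glo-ARM", "Glo-LTM-short",
                                         "Glo-LTM-long"),
                   stringsAsFactors = FALSE)
  g <- rbind(g, data.frame(replicate = paste0("R", 1:3), time_point = "none",
                           conditioning_type = "unconditioned"))
  data.frame(sample_id = paste0("s", seq_len(nrow(g))), species = "Cglom", g,
             stringsAsFactors = FALSE)
}

test_that("design construction enumerates groups, blocks and contrasts", {
  rub <- expand.grid(replicate = paste0("R", 1:3),
                     time_point = c("1h", "4h", "24h"),
                     conditioning_type = "Rub-LTM-long",
                     stringsAsFactors = FALSE)
  rub <- rbind(rub, data.frame(replicate = paste0("R", 1:3),
                               time_point = "none",
                               conditioning_type = "unconditioned"))
  rub <- data.frame(sample_id = paste0("s", 1:12), species = "Crub", rub)
  d <- build_design(rub)
  expect_identical(nlevels(d$group), 4L)
  expect_identical(length(d$contrasts), 3L)
  expect_identical(ncol(d$X), 1L + 2L + 3L)  # intercept + 2 blocks + 3 groups

  a <- build_design(glo_meta())
  expect_identical(nlevels(a$group), 10L)
  expect_identical(length(a$contrasts), 9L)

  only <- rub[rub$conditioning_type == "unconditioned", ]
  expect_error(build_design(only), "contrast")
  expect_error(build_design(rub[rub$conditioning_type != "unconditioned", ]),
               "unconditioned")
})

test_that("residual df reproduces the design arithmetic", {
  expect_identical(residual_df(12, 4), 8L)
  expect_identical(residual_df(30, 10), 20L)
  expect_identical(residual_df(7, 6), 1L)
  expect_error(residual_df(7, 7), "nonpositive")
})

test_that("a constant transcript has zero logFC and p = 1 everywhere", {
  meta <- two_group_meta()
  des <- build_design(meta)
  y <- matrix(50L, 3, 6, dimnames = list(paste0("t", 1:3), meta$sample_id))
  calls <- fit_and_test(y, des, 0.1)
  expect_true(all(abs(calls$logFC) < 1e-6))
  expect_true(all(calls$p_value > 1 - 1e-6))
  z <- matrix(0L, 2, 6, dimnames = list(c("z1", "z2"), meta$sample_id))
  cz <- fit_and_test(z, des, 0.1)
  expect_true(all(cz$logFC == 0 & cz$p_value == 1 & !cz$significant))
})

test_that("the IRLS optimum matches a dense grid search", {
  set.seed(51)
  y <- matrix(rnbinom(6, mu = c(40, 40, 40, 160, 160, 160), size = 10), 1,
              dimnames = list("t1", paste0("s", 1:6)))
  X <- cbind(1, rep(c(0, 1), each = 3))
  off <- matrix(log(1e4), 1, 6)
  phi <- 0.1
  fit <- memorydiff:::.nbglm_fit_cpp(y, X, off, phi)
  ll <- function(b0, b1) {
    mu <- exp(off[1, ] + X %*% c(b0, b1))
    sum(dnbinom(y[1, ], mu = mu, size = 1 / phi, log = TRUE))
  }
  ll_fit <- ll(fit$coefficients[1], fit$coefficients[2])
  grid0 <- seq(fit$coefficients[1] - 0.25, fit$coefficients[1] + 0.25, 1e-3)
  grid1 <- seq(fit$coefficients[2] - 0.25, fit$coefficients[2] + 0.25, 1e-3)
  ll_grid <- outer(grid0, grid1, Vectorize(ll))
  expect_lt(max(ll_grid) - ll_fit, 1e-3)
})

test_that("offsets make logFC invariant to consistent column rescaling", {
  set.seed(52)
  meta <- two_group_meta()
  des <- build_design(meta)
  y <- matrix(rnbinom(500 * 6, mu = 2000, size = 20), 500,
              dimnames = list(paste0("t", 1:500), meta$sample_id))
  L <- colSums(y)
  c1 <- fit_and_test(y, des, 0.05, lib_sizes = L)
  y2 <- y
  y2[, 1] <- round(y[, 1] * 3)
  L2 <- L
  L2[1] <- L[1] * 3
  c2 <- fit_and_test(y2, des, 0.05, lib_sizes = L2)
  expect_lt(max(abs(c1$logFC - c2$logFC)), 0.02)
})

test_that("permuting samples together with metadata leaves calls unchanged", {
  set.seed(53)
  meta <- two_group_meta()
  y <- matrix(rnbinom(300 * 6, mu = 100, size = 10), 300,
              dimnames = list(paste0("t", 1:300), meta$sample_id))
  perm <- c(4, 2, 6, 1, 3, 5)
  c1 <- fit_and_test(y, build_design(meta), 0.1)
  c2 <- fit_and_test(y[, perm], build_design(meta[perm, ]), 0.1)
  expect_equal(c1$logFC, c2$logFC, tolerance = 1e-8)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-8)
})

test_that("common dispersion is recovered from constant-dispersion data", {
  set.seed(54)
  meta <- two_group_meta()
  des <- build_design(meta)
  y <- matrix(rnbinom(1000 * 6, mu = 300, size = 1 / 0.1), 1000,
              dimnames = list(paste0("t", 1:1000), meta$sample_id))
  d <- estimate_dispersions(y, des)
  expect_gt(d$common, 0.07)
  expect_lt(d$common, 0.13)
  # Poisson data collapse to (near) zero dispersion
  yp <- matrix(rpois(1000 * 6, 300), 1000,
               dimnames = list(paste0("p", 1:1000), meta$sample_id))
  dp <- estimate_dispersions(yp, des)
  expect_lt(dp$common, 0.02)
  expect_lt(max(dp$per_transcript), 0.02)
})

test_that("the dispersion engine agrees with edgeR on common dispersion", {
  skip_if_not_installed("edgeR")
  set.seed(55)
  meta <- two_group_meta()
  des <- build_design(meta)
  y <- matrix(rnbinom(800 * 6, mu = 250, size = 1 / 0.15), 800,
              dimnames = list(paste0("t", 1:800), meta$sample_id))
  ours <- estimate_dispersions(y, des)$common
  dge <- edgeR::estimateGLMCommonDisp(y, des$X)
  expect_lt(abs(ours / dge - 1), 0.15)
})

test_that("power is non-decreasing in the planted effect size", {
  set.seed(56)
  meta <- two_group_meta()
  des <- build_design(meta)
  power_at <- function(lfc) {
    G <- 300
    mu <- outer(rep(150, G), c(1, 1, 1, 2^lfc, 2^lfc, 2^lfc))
    y <- matrix(rnbinom(G * 6, mu = mu, size = 1 / 0.1), G,
                dimnames = list(paste0("t", 1:G), meta$sample_id))
    mean(fit_and_test(y, des, 0.1,
                      lib_sizes = rep(150 * G, 6))$significant)
  }
  p <- vapply(c(0.5, 1, 2), power_at, 0)
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], 0.9)
})

test_that("nb_dispersion objects evaluate their trend and print cleanly", {
  set.seed(57)
  meta <- two_group_meta()
  des <- build_design(meta)
  y <- matrix(rnbinom(500 * 6, mu = 100, size = 5), 500,
              dimnames = list(paste0("t", 1:500), meta$sample_id))
  d <- estimate_dispersions(y, des)
  expect_true(all(trend_dispersion(d, c(-1, 5, 20)) > 0))
  calls <- fit_and_test(y, des, d)
  expect_s3_class(calls, "de_calls")
  expect_output(print(calls), "alpha")
  expect_identical(nrow(calls), 500L)
})
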
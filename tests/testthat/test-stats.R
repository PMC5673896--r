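test_that("PCA separates planted lignin/unnamed clusters with opposite
          loading signs", {
  set.seed(31)
  n <- 12
  base <- matrix(runif(n * 4, 0.05, 0.15), n, 4,
                 dimnames = list(NULL, c("lipids", "proteins",
                                         "tannins", "carbohydrates")))
  lignin <- c(rep(0.45, n / 2), rep(0.15, n / 2)) + rnorm(n, 0, 0.02)
  unnamed <- c(rep(0.15, n / 2), rep(0.45, n / 2)) + rnorm(n, 0, 0.02)
  m <- cbind(base, lignin = lignin, unnamed = unnamed)
  p <- pcaProfiles(m)
  expect_lt(p$loadingCor["lignin", 1] * p$loadingCor["unnamed", 1], 0)
  expect_true(all(abs(p$loadingCor) <= 100 + 1e-9))
})

test_that("PCA scores duplicate when the dataset is duplicated", {
  set.seed(32)
  m <- matrix(runif(24), 6, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  p1 <- pcaProfiles(m)
  p2 <- pcaProfiles(rbind(m, m))
  expect_equal(unname(p2$scores[1:6, ]), unname(p2$scores[7:12, ]),
               tolerance = 1e-10)
  # orthogonal components
  expect_equal(sum(p1$scores[, 1] * p1$scores[, 2]), 0,
               tolerance = 1e-8)
})

test_that("PCA loadings agree with an independent eigen-decomposition", {
  m <- matrix(c(0.50, 0.20, 0.15, 0.15,
                0.45, 0.25, 0.20, 0.10,
                0.20, 0.50, 0.10, 0.20,
                0.15, 0.55, 0.15, 0.15), 4, 4, byrow = TRUE,
              dimnames = list(NULL, c("lignin", "unnamed", "lipids",
                                      "tannins")))
  p <- pcaProfiles(m, nComponents = 2)
  z <- scale(m)
  ev <- eigen(cov(z))                   # independent eigensolver route
  sc <- z %*% ev$vectors[, 1:2]
  oracleCor <- abs(cor(m, sc) * 100)
  expect_equal(abs(p$loadingCor), oracleCor, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(p$varianceExplained,
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-8)
})

test_that("transformations behave and invert as documented", {
  y <- c(0.5, 2, 10)
  tr <- applyTransform(y, "log")
  expect_equal(tr$inverse(tr$y), y)
  expect_error(applyTransform(c(0, 1), "log"), "offset")
  auto <- applyTransform(c(0, 1, 4), "log", offset = "auto")
  expect_equal(auto$offset, 0.5)        # half the smallest positive
  rl <- applyTransform(c(0.01, 0.2, 0.9), "reciprocal_log")
  expect_true(all(1 / rl$y > 0))        # log arguments all exceeded 1
  expect_equal(rl$inverse(rl$y), c(0.01, 0.2, 0.9), tolerance = 1e-10)
})

test_that("the mixed model detects a planted interaction and sizes df", {
  set.seed(41)
  d <- simulateCores(gamma = 3, sigma = 1)
  fit <- fitLMM(d, "y", "moisture * wetting")
  a <- fit$anova
  expect_equal(a$num_df, c(1, 1, 1))
  expect_equal(a$den_df, rep(12, 3), tolerance = 0.1)
  expect_lt(a$p[a$term == "moisture:wetting"], 0.05)
  expect_true(all(fit$varcomp >= 0))
  expect_true(all(a$p >= 0 & a$p <= 1))
})

test_that("replicated cores with zero core variance estimate ~zero", {
  set.seed(42)
  d <- rbind(simulateCores(0), simulateCores(0))  # 2 obs per core
  d$y <- rnorm(nrow(d))                 # pure residual noise
  fit <- fitLMM(d, "y", c("moisture", "wetting"))
  expect_lt(fit$varcomp[["core"]], 0.2 * fit$varcomp[["residual"]])
})

test_that("aliased fixed terms raise an explicit error", {
  d <- simulateCores(0)
  d$dup <- d$moisture                   # perfectly aliased copy
  expect_error(fitLMM(d, "y", c("moisture", "dup")), "aliased")
})

test_that("LSD letters: equal truth shares, a 6-SE shift separates", {
  set.seed(43)
  d0 <- simulateCores(gamma = 0, sigma = 1)
  f0 <- fitLMM(d0, "y", "moisture * wetting")
  g0 <- lsdGroups(f0, c("moisture", "wetting"))
  expect_true(length(unique(g0$letters)) <= 2)  # no wholesale separation
  shift <- simulateCores(gamma = 0, sigma = 1)
  up <- shift$moisture == "drought" & shift$wetting == "top_precipitation"
  shift$y[up] <- shift$y[up] + 6        # ~12 SE of a cell mean
  fs <- fitLMM(shift, "y", "moisture * wetting")
  gs <- lsdGroups(fs, c("moisture", "wetting"))
  shifted <- gs$moisture == "drought" &
    gs$wetting == "top_precipitation"
  others <- gs$letters[!shifted]
  expect_false(any(grepl(gs$letters[shifted], others)))
})

test_that("letter partitions are consistent with all-pairs t tests", {
  set.seed(44)
  d <- simulateCores(gamma = 1.2, sigma = 1)
  fit <- fitLMM(d, "y", "moisture * wetting")
  emm <- emmeans::emmeans(fit$model, c("moisture", "wetting"))
  prs <- as.data.frame(emmeans::contrast(emm, "pairwise",
                                         adjust = "none"))
  grp <- lsdGroups(fit, c("moisture", "wetting"))
  lab <- paste(grp$moisture, grp$wetting)
  share <- function(a, b) {
    la <- strsplit(grp$letters[lab == a], "")[[1]]
    lb <- strsplit(grp$letters[lab == b], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  for (r in seq_len(nrow(prs))) {
    pair <- gsub("[()]", "", strsplit(prs$contrast[r], " - ")[[1]])
    sig <- prs$p.value[r] < 0.05
    # significant pair => no shared letter; non-significant => shared
    expect_equal(!share(pair[1], pair[2]), sig,
                 label = paste("pair", prs$contrast[r]))
  }
})

test_that("ratio contrasts reproduce the published intact-core ratios", {
  pres <- defaultFluxPresets()
  rt <- ratioTable(pres[pres$structure == "intact", ])
  expect_equal(rt$ratio, c(4.7, 2.4, 1.5, 8.8))
  # degenerate inputs
  broken <- pres[pres$structure == "intact", ]
  broken$co2_mgC[broken$moisture == "field" &
                   broken$wetting == "top_precipitation"] <- 0
  expect_error(ratioTable(broken), "zero denominator")
  expect_error(ratioTable(broken[-1, ]), "missing")
})

test_that("correlate guards degenerate input and finds perfect lines", {
  expect_equal(correlate(1:10, 2 * (1:10))$r, 1)
  expect_error(correlate(1:2, 1:2), "at least 3")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  set.seed(45)
  expect_gt(correlate(rnorm(16), rnorm(16))$p, 0.001)
})
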
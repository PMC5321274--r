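test_that("single-component EM reproduces the closed-form normal MLE", {
  set.seed(5)
  x <- rnorm(400, 10, 2)
  fit <- fitGmm(x, 1, seed = 3, nRandomStarts = 3, nKmeansStarts = 3,
                scale = "myr", varFloor = 1e-2)
  expectValidFit(fit)
  expect_equal(fit@mean, mean(x), tolerance = 1e-6)
  expect_equal(fit@sd, sqrt(mean((x - mean(x))^2)), tolerance = 1e-4)
  expect_equal(fit@proportion, 1)
})

test_that("two-component recovery and order invariance hold", {
  set.seed(9)
  x <- abs(c(rnorm(1200, 0.05, 0.02), rnorm(800, 0.45, 0.08)))
  fit <- fitGmm(x, 2, seed = 4, nRandomStarts = 10, nKmeansStarts = 10)
  expectValidFit(fit)
  expect_equal(fit@mean, c(0.05, 0.45), tolerance = 0.02)
  expect_equal(fit@proportion, c(0.6, 0.4), tolerance = 0.05)
  # permuting the input changes nothing
  fitP <- fitGmm(sample(x), 2, seed = 4, nRandomStarts = 10,
                 nKmeansStarts = 10)
  expect_equal(fit@mean, fitP@mean, tolerance = 1e-12)
  expect_equal(fit@logLik, fitP@logLik, tolerance = 1e-12)
  expect_error(fitGmm(x[1:15], 2), "10\\*k|10 \\* k|at least")
})

test_that("the fitted mixture agrees with an independent EM implementation", {
  library(mclust)
  set.seed(11)
  x <- c(rnorm(900, 2, 0.5), rnorm(600, 6, 1))
  fit <- fitGmm(x, 2, seed = 2, nRandomStarts = 10, nKmeansStarts = 10,
                scale = "myr", varFloor = 1e-4)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit@mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(fit@logLik, mc$loglik, tolerance = 1e-3)
})

test_that("BIC selection finds clearly separated component counts", {
  hit <- 0
  for (sd in 1:6) {
    set.seed(sd)
    x <- abs(c(rnorm(700, 0.06, 0.02), rnorm(500, 0.5, 0.06)))
    best <- selectModel(x, kRange = 2:4, seed = sd, nRandomStarts = 3,
                        nKmeansStarts = 3, shortIter = 15, nPolish = 2)
    expectValidFit(best)
    tab <- bicTable(best)
    expect_equal(tab$BIC, -2 * tab$logLik + (3 * tab$k - 1) * log(length(x)),
                 tolerance = 1e-8)
    if (best@k == 2) hit <- hit + 1
  }
  expect_gte(hit, 5)
  # a single candidate k is returned as-is
  set.seed(1)
  one <- selectModel(abs(rnorm(200, 0.3, 0.05)), kRange = 2:2, seed = 1,
                     nRandomStarts = 3, nKmeansStarts = 3)
  expect_equal(one@k, 2L)
})

test_that("log-likelihood is non-decreasing in k for nested fits", {
  set.seed(21)
  x <- abs(c(rnorm(700, 0.1, 0.04), rnorm(500, 0.4, 0.1)))
  lls <- vapply(2:4, function(k)
    fitGmm(x, k, seed = 6, nRandomStarts = 5, nKmeansStarts = 5)@logLik,
    numeric(1))
  expect_true(all(diff(lls) >= -1e-4 * abs(lls[-length(lls)])))
})

test_that("component retention applies a strict 20 percent rule", {
  mk <- function(props) new("KsMixtureFit", k = length(props),
    mean = seq_along(props) * 0.1, sd = rep(0.02, length(props)),
    proportion = props, logLik = 0, bic = (3 * length(props) - 1) * log(100),
    n = 100L, scale = "ks", converged = TRUE, logLikTrace = c(0, 0),
    seed = 1L, bicTable = data.frame())
  expect_equal(nrow(retainComponents(mk(c(0.5, 0.3, 0.2)))), 2)
  expect_equal(nrow(retainComponents(mk(c(0.21, 0.79)))), 2)
  expect_warning(none <- retainComponents(mk(c(0.1, 0.15, 0.75)),
                                          minProportion = 0.9))
  expect_equal(nrow(none), 0)
})

test_that("dating components converts scales and labels age windows", {
  comp <- data.frame(mean = c(0.3996, 0.05, 0), sd = c(0.027, 0.01, 0.001),
                     proportion = c(0.3, 0.5, 0.2))
  dated <- dateComponents(comp, 2.7e-3)
  expect_equal(dated$meanMyr[1], 74.0, tolerance = 1e-9)
  expect_equal(dated$sdMyr[1], 5.0, tolerance = 1e-9)
  expect_equal(dated$meanMyr[3], 0)
  expect_equal(dated$label, c("WGD-candidate", "SSD-candidate",
                              "SSD-candidate"))
  off <- dateComponents(comp, 2.7e-3, ssdMax = NA)
  expect_true(all(off$label == "unclassified"))
})

test_that("pooled analysis with one species matches its per-species fit", {
  set.seed(31)
  ages <- abs(rnorm(600, 74, 6))
  single <- pooledAnalysis(list(SP = ages), kRange = 2:3, seed = 5,
                           nRandomStarts = 5, nKmeansStarts = 5)
  direct <- selectModel(ages, kRange = 2:3, seed = 5, scale = "myr",
                        varFloor = 1e-2, nRandomStarts = 5,
                        nKmeansStarts = 5)
  expect_equal(single@mean, direct@mean, tolerance = 1e-12)
  expect_equal(single@bic, direct@bic, tolerance = 1e-12)
  expect_equal(single@scale, "myr")
})
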
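test_that("prefilter keeps exactly the samples analyzable for both genes", {
  x <- c(1, 15.2, NA, 5, -0.1, 7); y <- c(2, 3, 4, NA, 6, 14)
  names(x) <- names(y) <- sprintf("s%d", 1:6)
  expect_equal(prefilter_values(x, y), c(1L, 6L))
  # all in range, none missing: identity
  expect_equal(prefilter_values(c(a = 1, b = 2), c(a = 3, b = 4)), 1:2)
  # brute-force oracle on random vectors with random masks
  set.seed(31)
  for (i in 1:20) {
    x <- runif(50, -2, 17); y <- runif(50, -2, 17)
    x[sample(50, 5)] <- NA; y[sample(50, 5)] <- NA
    oracle <- intersect(
      which(!is.na(x) & x >= 0 & x <= 15),
      which(!is.na(y) & y >= 0 & y <= 15))
    expect_equal(prefilter_values(x, y), oracle)
  }
})

test_that("pair GMM selects the number of components by minimum BIC", {
  set.seed(5)
  # one bivariate Gaussian
  x <- rnorm(200, 5); y <- 0.4 * x + rnorm(200, 0, 0.9)
  names(x) <- names(y) <- sprintf("s%03d", 1:200)
  fit1 <- fit_pair_gmm(x, y)
  expect_equal(fit1$k_selected, 1L)

  # two components 6 sigma apart: k = 2, assignments match the planted split
  x2 <- c(rnorm(100, 2, 1), rnorm(100, 8, 1))
  y2 <- c(rnorm(100, 2, 1), rnorm(100, 8, 1))
  names(x2) <- names(y2) <- sprintf("s%03d", 1:200)
  fit2 <- fit_pair_gmm(x2, y2)
  expect_equal(fit2$k_selected, 2L)
  planted <- rep(1:2, each = 100)
  agree <- max(mean(fit2$assignment == planted),
               mean(fit2$assignment == 3 - planted))
  expect_gte(agree, 0.95)

  # below the minimum cluster size the pair is skipped
  expect_null(fit_pair_gmm(x[1:29], y[1:29]))
})

test_that("GMM component count equals an independent min-BIC computation", {
  # oracle: refit each k separately, compute the mixture log-likelihood
  # from the fitted parameters with our own bivariate normal density,
  # and take argmin of BIC = -2 logL + npar log n (npar = 6k - 1)
  set.seed(77)
  cases <- list(
    cbind(rnorm(150, 4), rnorm(150, 4)),
    cbind(c(rnorm(80, 1), rnorm(80, 7)), c(rnorm(80, 1), rnorm(80, 7))),
    cbind(c(rnorm(60, 0), rnorm(60, 5), rnorm(60, 10)),
          c(rnorm(60, 5), rnorm(60, 0), rnorm(60, 10))))
  for (dat in cases) {
    rownames(dat) <- sprintf("s%03d", seq_len(nrow(dat)))
    x <- setNames(dat[, 1], rownames(dat)); y <- setNames(dat[, 2], rownames(dat))
    fit <- fit_pair_gmm(x, y)
    bic <- sapply(1:5, function(k) {
      m <- tryCatch(mclust::Mclust(dat, G = k, modelNames = "VVV",
                                   verbose = FALSE), error = function(e) NULL)
      if (is.null(m)) return(Inf)
      ll <- mixture_loglik(dat, m$parameters$pro, m$parameters$mean,
                           m$parameters$variance$sigma)
      -2 * ll + (6 * k - 1) * log(nrow(dat))
    })
    expect_equal(fit$k_selected, which.min(bic))
  }
})

test_that("cluster Spearman thresholds candidates at |rho| > 0.5", {
  s <- sprintf("s%02d", 1:40)
  x <- setNames(seq(1, 8, length.out = 40), s)
  expect_equal(cluster_spearman(x, x^2, s)$rho, 1)
  expect_true(cluster_spearman(x, x^2, s)$candidate)
  expect_equal(cluster_spearman(x, -x, s)$rho, -1)
  expect_true(cluster_spearman(x, -x, s)$candidate)
  expect_false(cluster_spearman(x, setNames(rep(2, 40), s), s)$candidate)

  # planted rho 0.4 is rejected in most draws (Gaussian copula generator)
  set.seed(12)
  rejections <- replicate(50, {
    rho_p <- 2 * sin(pi * 0.4 / 6)
    a <- rnorm(100); b <- rho_p * a + sqrt(1 - rho_p^2) * rnorm(100)
    names(a) <- names(b) <- sprintf("s%03d", 1:100)
    !cluster_spearman(a, b, names(a))$candidate
  })
  expect_gte(mean(rejections), 0.8)
})

test_that("correlation power matches the Fisher-z closed form", {
  # independent inline evaluation of the closed form
  fisher_power <- function(n, r, alpha)
    pnorm(abs(atanh(r)) * sqrt(n - 3) - qnorm(1 - alpha / 2))
  for (n in c(30, 100, 500)) for (r in c(0.1, 0.5, 0.85))
    expect_equal(correlation_power(n, r), fisher_power(n, r, 0.001),
                 tolerance = 1e-6)
  expect_equal(correlation_power(100, 0.5),
               pnorm(atanh(0.5) * sqrt(97) - qnorm(0.9995)), tolerance = 1e-6)
  expect_equal(correlation_power(50, 1), 1)
  expect_gt(correlation_power(1000, 0.9999), 0.999999)
  expect_equal(correlation_power(100, 0), 0.001 / 2, tolerance = 1e-4)
})

test_that("condition z-tests label enriched clusters and only those", {
  annot <- two_cond_annot(50, 50, c("c", "other"))
  u <- annot$sample
  # cluster = exactly the 50 condition-c samples: overwhelming evidence;
  # exact binomial oracle bound: P(50 of 50 in-cluster | p = 0.5) = 2^-50
  res <- test_condition_categorical(u[1:50], u, annot, "c")
  expect_true(res$labeled)
  expect_lt(res$p_in_cluster, 1e-10)
  expect_lt(res$p_capture, 1e-10)

  # cluster composition identical to background: not labeled
  mixed <- c(u[1:25], u[51:75])
  res2 <- test_condition_categorical(mixed, u, annot, "c")
  expect_false(res2$labeled)

  # condition depleted in the cluster: one-sided, never labeled
  res3 <- test_condition_categorical(u[1:50], u, annot, "other")
  expect_false(res3$labeled)
  expect_gt(res3$p_in_cluster, 0.5)
  # absent condition: undefined p, not labeled
  res4 <- test_condition_categorical(u[1:50], u, annot, "ghost")
  expect_false(res4$labeled)
  expect_true(is.na(res4$p_in_cluster))
})

test_that("quantitative condition test needs r^2 > 0.30 and p < 0.001", {
  u <- sprintf("s%03d", 1:100)
  cov_sep <- setNames(c(rnorm(50, 10, 0.5), rnorm(50, 0, 0.5)), u)
  res <- test_condition_quantitative(u[1:50], u, cov_sep)
  expect_true(res$labeled)
  expect_gt(res$r_square, 0.9)

  # independent covariate: slope p-values behave like a null
  set.seed(61)
  ps <- replicate(500, {
    cv <- setNames(rnorm(100), u)
    test_condition_quantitative(u[1:50], u, cv)$p_reg
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  expect_false(any(replicate(20, {
    cv <- setNames(rnorm(100), u)
    test_condition_quantitative(u[1:50], u, cv)$labeled
  })))
  # constant covariate: never labeled
  expect_false(test_condition_quantitative(u[1:50], u,
                                           setNames(rep(1, 100), u))$labeled)
})

test_that("differential-cluster-expression filter requires both genes to shift", {
  set.seed(19)
  u <- sprintf("s%03d", 1:120)
  members <- u[1:60]
  x <- setNames(c(rnorm(60, 8), rnorm(60, 4)), u)  # 4-unit in-cluster shift
  y <- setNames(c(rnorm(60, 9), rnorm(60, 5)), u)
  expect_true(filter_dce(x, y, members, u)$keep)

  y_flat <- setNames(rnorm(120, 5), u)  # gene B identical in/out
  expect_false(filter_dce(x, y_flat, members, u)$keep)

  y_const <- setNames(rep(3, 120), u)   # zero variance
  res <- filter_dce(x, y_const, members, u)
  expect_false(res$keep)
  expect_true(is.na(res$p_b))
})

test_that("missingness-bias filter drops condition-unbalanced missingness only", {
  set.seed(23)
  annot <- two_cond_annot(60, 60, c("c", "other"))
  s <- annot$sample
  x <- setNames(rnorm(120, 6), s); y <- setNames(rnorm(120, 6), s)
  expect_true(filter_missingness_bias(x, y, annot, "c")$keep)  # no missingness

  x80 <- x; x80[s[1:48]] <- NA  # 80% missing in condition c only
  expect_false(filter_missingness_bias(x80, y, annot, "c")$keep)

  # symmetric 10% missingness everywhere: a balanced null, so each gene's
  # t-test p is ~uniform and the edge survives with probability ~(1-0.1)^2;
  # check the kept rate is consistent with that, i.e. no systematic drop
  kept <- replicate(200, {
    xm <- x; ym <- y
    xm[sample(s, 12)] <- NA; ym[sample(s, 12)] <- NA
    filter_missingness_bias(xm, ym, annot, "c")$keep
  })
  expect_gte(mean(kept), 0.70)
  expect_lte(mean(kept), 0.92)
})

test_that("edge ranking orders by |similarity|, then r^2, then p, losslessly", {
  e <- data.frame(source = c("a", "c", "e", "g"), target = c("b", "d", "f", "h"),
                  similarity = c(0.7, 0.9, 0.9, -0.95),
                  r_square = c(NA, 0.5, 0.5, NA),
                  p_test1 = c(1e-5, NA, NA, 1e-6), p_test2 = c(1e-4, NA, NA, 1e-6),
                  p_reg = c(NA, 1e-4, 1e-8, NA))
  r <- rank_edges(e)
  expect_equal(r$source, c("g", "e", "c", "a"))
  expect_equal(r$rank, 1:4)
  expect_setequal(paste(r$source, r$target), paste(e$source, e$target))
})

test_that("constructed networks satisfy every retention invariant", {
  b <- default_bundle()
  g <- log2_quantile_normalize(b$gem)
  pe <- b$truth$planted_edges
  pairs <- rbind(as.matrix(pe[, c("gene_a", "gene_b")]),
                 cbind(sprintf("G%04d", 101:115), sprintf("G%04d", 151:165)))
  edges <- build_csgcn(g, b$annotation, pairs = pairs)
  expect_gt(nrow(edges), 0)
  expect_true(all(abs(edges$similarity) > 0.5))
  expect_true(all(edges$power >= 0.8))
  expect_true(all(edges$cluster_size >= 30))
  expect_true(all(nzchar(edges$condition)))
  expect_true(all(edges$p_welch_a <= 0.001 & edges$p_welch_b <= 0.001))
  expect_true(all(is.na(edges$p_miss_a) | edges$p_miss_a >= 0.1))

  # determinism
  edges2 <- build_csgcn(g, b$annotation, pairs = pairs)
  expect_identical(edges, edges2)

  # invariance to sample column order
  perm <- sample(ncol(g$values))
  gp <- gem(g$values[, perm], "log2")
  edges3 <- build_csgcn(gp, b$annotation, pairs = pairs)
  key <- function(e) sort(paste(e$source, e$target, e$condition))
  expect_equal(key(edges3), key(edges))
})

test_that("null data yields labeled edges at no more than the tested rate", {
  b <- generate_dataset(40, c(a = 60, b = 60), synthetic_truth(), seed = 14)
  g <- log2_quantile_normalize(b$gem)
  edges <- build_csgcn(g, b$annotation)  # 780 null pairs
  # two one-sided tests at alpha = 0.001 plus the |rho| > 0.5 gate:
  # expected count well below binomial(780, 0.002) upper tail (~5)
  expect_lte(nrow(edges), 5)
})
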
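# UPGMA, PCA, multiscale-bootstrap AU support, ANOVA + Holm

test_that("euclidean distances match hand values and impute missing cells", {
  x <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(as.matrix(euclidean_distance(x))["a", "b"], 5)

  x3 <- rbind(a = c(1, 2), b = c(1, 2), c = c(4, 6))
  d <- as.matrix(euclidean_distance(x3))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 5)

  xm <- rbind(a = c(1, NA), b = c(3, 2), c = c(5, 4))
  expect_message(dm <- euclidean_distance(xm), "imputed")
  expect_equal(as.matrix(dm)["a", "b"],
               sqrt((1 - 3)^2 + (3 - 2)^2))  # NA -> column mean 3

  allna <- rbind(a = c(NA_real_, NA_real_), b = c(1, 2))
  expect_error(euclidean_distance(allna), "no observed features")
})

test_that("UPGMA merges the spec fixture at heights 1 and 4.5", {
  d <- matrix(0, 3, 3, dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  d["s1", "s2"] <- d["s2", "s1"] <- 1
  d["s1", "s3"] <- d["s3", "s1"] <- 4
  d["s2", "s3"] <- d["s3", "s2"] <- 5
  tree <- average_linkage(as.dist(d))
  expect_equal(tree$height, c(1, 4.5))
  expect_equal(tree$clusters[[1]], c("s1", "s2"))
  expect_equal(tree$clusters[[2]], c("s1", "s2", "s3"))

  two <- average_linkage(as.dist(matrix(c(0, 2, 2, 0), 2,
                                        dimnames = list(c("x", "y")))))
  expect_equal(two$height, 2)

  eq <- as.dist(matrix(3, 4, 4, dimnames = list(paste0("s", 1:4))) -
                  diag(3, 4))
  eqt <- average_linkage(eq)
  expect_equal(max(eqt$height), 3)

  nan <- matrix(c(0, NaN, NaN, 0), 2, dimnames = list(c("x", "y")))
  expect_error(average_linkage(as.dist(nan)), "non-finite")
})

test_that("UPGMA heights are monotone and trees ultrametric on random data", {
  set.seed(55)
  for (i in 1:15) {
    x <- matrix(rnorm(7 * 3), 7, 3, dimnames = list(paste0("s", 1:7), NULL))
    tree <- average_linkage(euclidean_distance(x))
    expect_true(all(diff(tree$height) >= -1e-12))
    # cophenetic heights symmetric + ultrametric three-point condition
    coph <- stats::cophenetic(tree$hclust)
    cm <- as.matrix(coph)
    for (k in 1:5) {
      ijk <- sample(7, 3)
      three <- sort(c(cm[ijk[1], ijk[2]], cm[ijk[1], ijk[3]],
                      cm[ijk[2], ijk[3]]), decreasing = TRUE)
      expect_lt(abs(three[1] - three[2]), 1e-9)
    }
  }
})

test_that("PCA reports explained-variance fractions consistent with eigen", {
  line <- cbind(1:5, 2 * (1:5))
  p <- pca(line)
  expect_equal(p$var_explained[1], 1)

  set.seed(9)
  x <- matrix(rnorm(4 * 2), 4, 2)
  p2 <- pca(x)
  ev <- eigen(stats::cov(x))
  expect_equal(sort(p2$sdev^2, decreasing = TRUE),
               sort(ev$values, decreasing = TRUE), tolerance = 1e-10)
  expect_equal(abs(unname(p2$scores)),
               abs(scale(x, scale = FALSE) %*% ev$vectors),
               tolerance = 1e-8)
  expect_equal(sum(p2$var_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(p2$var_explained) <= 1e-12))

  centered <- scale(x, scale = FALSE)
  attr(centered, "scaled:center") <- NULL
  expect_equal(abs(pca(centered, center = FALSE)$scores),
               abs(pca(x, center = TRUE)$scores), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(pca(matrix(1, 3, 2)), "zero-variance")
})

test_that("clusters recovered in every replicate get AU = BP = 1", {
  x <- rbind(g1a = c(0, 0, 0, 0), g1b = c(0.02, 0, 0.01, 0),
             g2a = c(9, 9, 9, 9), g2b = c(9.02, 9, 9.01, 9))
  tr <- multiscale_bootstrap_au(x, "euclidean", n_boot = 150, seed = 4)
  g1 <- which(vapply(tr$clusters, identical, logical(1),
                     y = c("g1a", "g1b")))
  g2 <- which(vapply(tr$clusters, identical, logical(1),
                     y = c("g2a", "g2b")))
  expect_equal(tr$au[c(g1, g2)], c(1, 1))
  expect_equal(tr$bp[c(g1, g2)], c(1, 1))
})

test_that("the AU probit fit matches an independent least-squares oracle", {
  scales <- seq(0.5, 1.4, by = 0.1)
  n_boot <- 1000
  bp <- c(0.62, 0.66, 0.69, 0.72, 0.75, 0.77, 0.80, 0.82, 0.84, 0.85)
  got <- tcrep:::fit_au(bp, scales, n_boot)
  z <- qnorm(1 - bp)
  fit <- lm(z ~ 0 + I(sqrt(scales)) + I(1 / sqrt(scales)))
  expected <- 1 - pnorm(coef(fit)[1] - coef(fit)[2])
  expect_equal(unname(got["au"]), unname(expected), tolerance = 1e-6)
  # rising BP_r means positive curvature: AU exceeds the r = 1 BP
  expect_gt(got[["au"]], bp[6])

  # degenerate profiles bypass the fit
  expect_equal(unname(tcrep:::fit_au(rep(1, 10), scales, n_boot)["au"]), 1)
  expect_equal(unname(tcrep:::fit_au(rep(0, 10), scales, n_boot)["au"]), 0)
  # fewer than three usable scales: AU missing
  mixed <- c(1, 1, 1, 1, 0, 0, 0, 0, 0.5, 0.6)
  expect_true(is.na(tcrep:::fit_au(mixed, scales, n_boot)["au"]))
})

test_that("Morisita-Horn distance trees collapse for identical repertoires", {
  counts <- rbind(s1 = c(5, 3, 2), s2 = c(10, 6, 4), s3 = c(50, 30, 20))
  colnames(counts) <- c("A", "B", "C")
  tree <- average_linkage(as.dist(1 - tcrep:::mh_similarity_matrix(counts)))
  expect_true(all(abs(tree$height) < 1e-12))
})

test_that("multiscale bootstrap validates its scale set", {
  x <- rbind(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  expect_error(multiscale_bootstrap_au(x, scales = c(1.1, 1.2), n_boot = 100),
               "span values")
  expect_error(multiscale_bootstrap_au(x, n_boot = 50), "n_boot")
})

test_that("group comparison runs ANOVA with Holm-adjusted Welch pairs", {
  vals <- c(1, 2, 3, 1, 2, 3)
  grp <- rep(c("a", "b"), each = 3)
  cmp <- group_comparison(vals, grp)
  expect_equal(cmp$f_statistic, 0)
  expect_equal(cmp$pairwise$p_raw, 1)

  set.seed(31)
  v2 <- c(rnorm(4), rnorm(4, 5), rnorm(4, 10))
  g2 <- rep(c("a", "b", "c"), each = 4)
  cmp2 <- group_comparison(v2, g2)
  expect_equal(nrow(cmp2$pairwise), 3)
  expect_true(all(cmp2$pairwise$p_holm >= cmp2$pairwise$p_raw))
  expect_equal(cmp2$pairwise$p_holm,
               p.adjust(cmp2$pairwise$p_raw, method = "holm"))
  ord <- order(cmp2$pairwise$p_raw)
  expect_true(all(diff(cmp2$pairwise$p_holm[ord]) >= -1e-15))

  expect_warning(cmp3 <- group_comparison(c(v2, 99), c(g2, "tiny")),
                 "excluded: tiny")
  expect_equal(nrow(cmp3$pairwise), 3)
  expect_error(
    suppressWarnings(group_comparison(c(1, 2, 3), c("a", "a", "b"))),
    "fewer than two groups")
})
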
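# downsampling, sharing, diversity/clonality, overlap, top-clonotype tables

test_that("downsampling at full depth is the identity and validates depth", {
  r <- make_rep(c(A = 5, B = 3, C = 2))
  expect_equal(downsample(r, 10, seed = 1)$counts, r$counts)
  expect_error(downsample(r, 11), "exceeds total")
  expect_error(downsample(r, 0), ">= 1")
})

test_that("a single read is drawn uniformly over the read multiset", {
  r <- make_rep(c(A = 1, B = 1))
  set.seed(20)
  picks <- replicate(400, names(downsample(r, 1)$counts))
  pa <- mean(picks == "A")
  # both outcomes occur with roughly equal probability (3 s.e. of 0.025)
  expect_gt(pa, 0.5 - 3 * 0.025)
  expect_lt(pa, 0.5 + 3 * 0.025)
})

test_that("downsampled counts match hypergeometric expectations", {
  counts <- c(A = 50, B = 30, C = 15, D = 5)
  r <- make_rep(counts)
  depth <- 40
  set.seed(21)
  draws <- replicate(500, rep(0, 4), simplify = "matrix")
  for (i in 1:500) {
    d <- downsample(r, depth)$counts
    draws[match(names(d), names(counts)), i] <- d
  }
  expmean <- depth * counts / sum(counts)
  v <- depth * (counts / 100) * (1 - counts / 100) * (100 - depth) / 99
  se <- sqrt(v / 500)
  expect_true(all(abs(rowMeans(draws) - expmean) < 3 * se))
})

test_that("common depth is the lowest sample total", {
  reps <- list(make_rep(c(A = 9000)), make_rep(c(B = 12000)),
               make_rep(c(C = 30000)))
  expect_equal(common_depth(reps), 9000)
  expect_equal(common_depth(reps[1]), 9000)
  expect_equal(common_depth(list(make_rep(c(A = 5)), make_rep(c(B = 5)))), 5)
})

test_that("shared clonotype counts are set intersections", {
  a <- make_rep(c(A = 1, B = 2, C = 3))
  b <- make_rep(c(B = 1, C = 1, D = 1))
  expect_equal(shared_clonotypes(a, b), 2)
  expect_equal(shared_clonotypes(a, a), 3)
  expect_equal(shared_clonotypes(a, make_rep(c(X = 1))), 0)
  expect_lte(shared_clonotypes(a, b), min(a$richness, b$richness))
})

test_that("resampled sharing is exact at full depth and bounded by the truth", {
  a <- make_rep(c(A = 2, B = 1), "a")
  b <- make_rep(c(A = 1, C = 2), "b")
  sh <- resampled_sharing(list(a, b), depth = 3, iterations = 5, seed = 1)
  expect_equal(sh$mean_shared, 1)
  expect_equal(sh$sd_shared, 0)

  sh2 <- resampled_sharing(list(a, b), depth = 2, iterations = 50, seed = 2)
  expect_lte(sh2$mean_shared, shared_clonotypes(a, b))

  expect_warning(resampled_sharing(list(a, b), depth = 2, iterations = 1,
                                   seed = 3),
                 "iterations = 1")
})

test_that("clonality follows 1 - Pielou evenness with declared edge cases", {
  uni <- make_rep(setNames(rep(90, 100), paste0("c", 1:100)))
  expect_identical(clonality(uni), 0)

  r <- make_rep(c(A = 8, B = 2))
  d <- diversity_report(r)
  expect_equal(d$shannon_h, 0.72193, tolerance = 1e-4)
  expect_equal(d$pielou_j, 0.72193, tolerance = 1e-4)
  expect_equal(d$clonality, 0.27807, tolerance = 1e-4)

  expect_equal(clonality(make_rep(c(A = 42))), 1)
  expect_equal(diversity_report(make_rep(c(A = 42)))$pielou_j, 0)
})

test_that("clonality of downsampled repertoires tracks the full-depth value", {
  set.seed(33)
  counts <- setNames(c(300, 200, 100, rpois(200, 8) + 1), paste0("c", 1:203))
  r <- make_rep(counts)
  full <- clonality(r)
  for (frac in c(0.25, 0.5, 1)) {
    d <- round(frac * r$total)
    cl <- mean(replicate(40, clonality(downsample(r, d))))
    expect_lt(abs(cl - full), 0.05)
  }
})

test_that("Morisita-Horn matches hand values and is depth-invariant", {
  a <- make_rep(c(A = 1, B = 1), "a")
  b <- make_rep(c(A = 1, C = 1), "b")
  expect_equal(morisita_horn(a, b), 0.5)
  expect_equal(morisita_horn(a, a), 1)
  expect_equal(morisita_horn(a, make_rep(c(X = 1, Y = 1))), 0)

  set.seed(14)
  for (i in 1:10) {
    x <- make_rep(setNames(rpois(30, 5) + 1, paste0("k", 1:30)))
    y <- make_rep(setNames(rpois(30, 5) + 1, paste0("k", 11:40)))
    scaled <- make_rep(x$counts * 7, "xs")
    expect_equal(morisita_horn(scaled, y), morisita_horn(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Morisita-Horn agrees with the community-ecology reference", {
  skip_if_not_installed("vegan")
  set.seed(15)
  for (i in 1:10) {
    reps <- lapply(1:4, function(j) {
      keys <- sample(paste0("k", 1:50), 30)
      make_rep(setNames(rpois(30, 10) + 1, keys), paste0("s", j))
    })
    m <- repertoire_matrix(reps)
    ours <- overlap_matrix(reps)
    ref <- 1 - as.matrix(vegan::vegdist(m, method = "horn"))
    expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
  }
})

test_that("overlap matrices are symmetric with unit diagonal in [0,1]", {
  set.seed(16)
  reps <- lapply(1:5, function(j) {
    make_rep(setNames(rpois(20, 6) + 1, sample(paste0("k", 1:40), 20)),
             paste0("s", j))
  })
  ov <- overlap_matrix(reps)
  expect_equal(ov, t(ov))
  expect_equal(unname(diag(ov)), rep(1, 5))
  expect_true(all(ov >= 0 & ov <= 1))
})

test_that("top clonotypes rank by frequency with lexicographic tie-break", {
  r <- make_rep(c(A = 5, B = 3, C = 2))
  top <- top_clonotypes(r, 2)
  expect_equal(top$key, c("A", "B"))
  expect_equal(top$frequency, c(0.5, 0.3))

  tie <- make_rep(c(B = 2, A = 2))
  expect_equal(top_clonotypes(tie, 1)$key, "A")

  expect_equal(nrow(top_clonotypes(r, 20)), 3)
  expect_error(top_clonotypes(r, 0), "k must be")
})

test_that("cumulative frequency pools per-sample top lists", {
  r1 <- make_rep(c(A = 5, B = 3, C = 2), "r1")
  cft1 <- cumulative_frequency_table(list(r1), k = 3)
  expect_equal(cft1$per_sample$cumulative_frequency, 1.0)

  # union {A, B, D} against {A:5, B:3, C:2} covers 0.8
  r2 <- make_rep(c(A = 9, B = 2, D = 9), "r2")
  cft2 <- cumulative_frequency_table(list(r1, r2), k = 2)
  expect_setequal(cft2$union_keys, c("A", "B", "D"))
  expect_equal(
    cft2$per_sample$cumulative_frequency[cft2$per_sample$sample_id == "r1"],
    0.8)

  big <- make_rep(setNames(c(30, 10, 5, 3, 2, rep(1, 50)),
                           c("A", "B", "C", "D", "E", paste0("x", 1:50))),
                  "big")
  cftb <- cumulative_frequency_table(list(big), k = 20)
  expect_equal(cftb$per_sample$top5_own_share, 0.5)
})

test_that("focal clonotype matrices hold frequencies with zero for absent keys", {
  r1 <- make_rep(c(A = 5, B = 5), "r1")
  r2 <- make_rep(c(A = 2, C = 8), "r2")
  m <- focal_clonotype_matrix(c("A", "C", "Z", "A"), list(r1, r2))
  expect_equal(rownames(m), c("A", "C", "Z"))  # deduplicated
  expect_equal(m["A", ], c(r1 = 0.5, r2 = 0.2))
  expect_equal(unname(m["Z", ]), c(0, 0))
  expect_true(all(colSums(m) <= 1 + 1e-12))
  expect_error(focal_clonotype_matrix(character(0), list(r1)), "empty")
})
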
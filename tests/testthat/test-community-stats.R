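test_that("Bray-Curtis and Jaccard follow their closed forms", {
  expect_equal(bray_curtis(c(1, 2, 0), c(0, 2, 2)), 3 / 7)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined-distance")
  expect_equal(jaccard_distance(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE)),
               2 / 3)
  expect_equal(jaccard_distance(c(TRUE, FALSE), c(TRUE, FALSE)), 0)
  expect_equal(jaccard_distance(c(TRUE, FALSE), c(FALSE, TRUE)), 1)
  expect_error(jaccard_distance(c(FALSE, FALSE), c(FALSE, FALSE)),
               "undefined-distance")
})

test_that("binary Bray-Curtis equals 1 - 2a/(2a+b+c) on 0/1 vectors", {
  set.seed(10)
  for (i in 1:20) {
    x <- as.numeric(runif(15) < 0.5)
    y <- as.numeric(runif(15) < 0.5)
    if (sum(x) + sum(y) == 0) next
    a <- sum(x == 1 & y == 1)
    b <- sum(x == 1 & y == 0)
    c2 <- sum(x == 0 & y == 1)
    expect_equal(bray_curtis(x, y), 1 - 2 * a / (2 * a + b + c2))
  }
})

test_that("dissimilarity matrices are symmetric, zero-diagonal, bounded", {
  set.seed(11)
  m <- matrix(rpois(60, 8), 6, 10,
              dimnames = list(paste0("s", 1:6), NULL))
  for (method in c("bray", "jaccard")) {
    d <- dissimilarity_matrix(if (method == "bray") m else m > 4, method)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 6))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(rownames(d), rownames(m))
  }
})

test_that("pairwise dissimilarities agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(rpois(50, 6) + 1, 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  expect_equal(as.matrix(vegan::vegdist(m, "bray")),
               dissimilarity_matrix(m, "bray"), ignore_attr = TRUE,
               tolerance = 1e-12)
  b <- m > 5
  expect_equal(as.matrix(vegan::vegdist(b, "jaccard", binary = TRUE)),
               dissimilarity_matrix(b, "jaccard"), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("Mantel r is the upper-triangle correlation, invariant to scale", {
  set.seed(13)
  m <- matrix(rpois(80, 6) + 1, 8, 10, dimnames = list(paste0("s", 1:8), NULL))
  d1 <- dissimilarity_matrix(m, "bray")
  expect_equal(mantel_test(d1, d1, permutations = 19, seed = 1)$r, 1)
  expect_equal(mantel_test(d1, 0.2 + 0.5 * d1, permutations = 19, seed = 1)$r,
               1)
  d2 <- dissimilarity_matrix(m[, sample(10)] + matrix(runif(80), 8), "bray")
  r <- mantel_test(d1, d2, permutations = 19, seed = 1)$r
  expect_equal(r, cor(d1[upper.tri(d1)], d2[upper.tri(d2)]))
})

test_that("Mantel agrees with vegan's statistic and enumeration p-value", {
  skip_if_not_installed("vegan")
  set.seed(14)
  m1 <- matrix(rpois(50, 5) + 1, 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  m2 <- m1 + matrix(rpois(50, 3), 5, 10)
  d1 <- dissimilarity_matrix(m1, "bray")
  d2 <- dissimilarity_matrix(m2, "bray")
  got <- mantel_test(d1, d2, permutations = all_perms(5))
  veg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(got$r, unname(veg$statistic), tolerance = 1e-12)
  # exhaustive enumeration, computed independently with explicit loops
  v1 <- d1[upper.tri(d1)]
  perms <- all_perms(5)
  r_all <- numeric(nrow(perms))
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    dp <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) dp[i, j] <- d2[p[i], p[j]]
    r_all[k] <- cor(v1, dp[upper.tri(dp)])
  }
  expect_equal(got$p, mean(r_all >= got$r - 1e-12))
})

test_that("PERMANOVA matches vegan and its SS decomposition closes", {
  skip_if_not_installed("vegan")
  set.seed(15)
  m <- matrix(rpois(120, 6) + 1, 12, 10,
              dimnames = list(paste0("s", 1:12), NULL))
  grp <- rep(c("a", "b", "c"), each = 4)
  d <- dissimilarity_matrix(m, "bray")
  got <- permanova(d, grp, permutations = 99, seed = 2)
  df <- data.frame(grp = grp)
  veg <- vegan::adonis2(as.dist(d) ~ grp, data = df, permutations = 99)
  expect_equal(got$pseudo_F, veg$F[1], tolerance = 1e-10)
  expect_equal(got$R2, veg$R2[1], tolerance = 1e-10)
  expect_equal(got$df, veg$Df[1])
  expect_lt(abs(got$ss["between"] + got$ss["within"] - got$ss["total"]), 1e-9)
})

test_that("PERMANOVA p equals exhaustive label-permutation enumeration", {
  set.seed(16)
  m <- matrix(rpois(60, 5) + 1, 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  grp <- c("a", "a", "a", "b", "b", "b")
  d <- dissimilarity_matrix(m, "bray")
  perms <- all_perms(6)
  got <- permanova(d, grp, permutations = perms)
  # independent enumeration via explicit SS computation per labelling
  f_of <- function(labels) {
    n <- 6; k <- 2
    sst <- sum((d^2)[upper.tri(d)]) / n
    ssw <- 0
    for (g in unique(labels)) {
      idx <- which(labels == g)
      sub <- d[idx, idx]^2
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_all <- apply(perms, 1, function(p) f_of(grp[p]))
  expect_equal(got$p, mean(f_all >= got$pseudo_F - 1e-12))
  # two tight groups far apart: R2 near 1
  d2 <- matrix(1, 4, 4); d2[1:2, 1:2] <- 0.01; d2[3:4, 3:4] <- 0.01
  diag(d2) <- 0
  sep <- permanova(d2, c("x", "x", "y", "y"), permutations = 19, seed = 3)
  expect_gt(sep$R2, 0.95)
  expect_error(permanova(d2, rep("x", 4)), "degenerate")
})

test_that("null p-values are super-uniform for both permutation tests", {
  set.seed(17)
  n_rep <- 60
  p_mantel <- numeric(n_rep)
  p_perm <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    m1 <- matrix(rpois(90, 6) + 1, 9, 10)
    m2 <- matrix(rpois(90, 6) + 1, 9, 10)
    rownames(m1) <- rownames(m2) <- paste0("s", 1:9)
    d1 <- dissimilarity_matrix(m1, "bray")
    d2 <- dissimilarity_matrix(m2, "bray")
    p_mantel[k] <- mantel_test(d1, d2, permutations = 199)$p
    p_perm[k] <- permanova(d1, rep(c("a", "b", "c"), each = 3),
                           permutations = 199)$p
  }
  for (alpha in c(0.05, 0.25, 0.5)) {
    slack <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(p_mantel <= alpha), alpha + slack)
    expect_lte(mean(p_perm <= alpha), alpha + slack)
  }
  expect_true(all(p_mantel >= 1 / 200))
})

test_that("Bonferroni multiplies by m and caps at 1", {
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni(0.9), 0.9)
  expect_equal(bonferroni(c(0.5, 0.6, 0.7)), c(1, 1, 1))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("period-wise Mantel keeps one sample per participant and adjusts", {
  set.seed(18)
  meta <- data.frame(
    sample_id = paste0("s", 1:16),
    participant = rep(1:4, times = 4),
    day = rep(1:4, each = 4),
    period = rep(c("w1", "w2"), each = 8),
    stringsAsFactors = FALSE)
  cnt <- matrix(rpois(16 * 6, 10) + 1, 16, 6,
                dimnames = list(meta$sample_id, paste0("t", 1:6)))
  diary <- matrix(runif(16 * 6) < 0.5, 16, 6,
                  dimnames = list(meta$sample_id, paste0("t", 1:6)))
  diary[rowSums(diary) == 0, 1] <- TRUE
  res <- periodwise_mantel(cnt, diary, meta, permutations = 99, seed = 4)
  expect_equal(nrow(res), 2L)
  expect_equal(res$n, c(4L, 4L))
  expect_equal(res$p_adjusted, pmin(1, 2 * res$p))
  sel <- attr(res, "selected")[["w1"]]
  expect_equal(sort(sel$day), rep(2L, 4))  # latest day within the period
  # a period with too few participants is skipped with a warning
  meta2 <- meta
  meta2$participant[meta2$period == "w2"] <- 1L
  meta2$day <- rep(1:8, times = 2)  # keep (participant, day) usable
  expect_warning(res2 <- periodwise_mantel(cnt, diary, meta2,
                                           permutations = 99, seed = 4),
                 "skipped")
  expect_equal(res2$period, "w1")
})

test_that("identical matrices give r = 1 in every period", {
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     participant = rep(1:4, 2), day = rep(1:2, each = 4),
                     period = rep(c("a", "b"), each = 4),
                     stringsAsFactors = FALSE)
  set.seed(19)
  cnt <- matrix(rpois(8 * 5, 20) + 1, 8, 5,
                dimnames = list(meta$sample_id, paste0("t", 1:5)))
  rel <- sweep(cnt, 1, rowSums(cnt), "/")
  res <- periodwise_mantel(cnt, rel, meta, permutations = 99, seed = 5)
  expect_true(all(abs(res$r - 1) < 1e-12))
})
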
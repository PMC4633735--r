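test_that("correlation distance treats anticorrelation as proximity", {
  v <- vectors_with_cor(diag(1), 16, seed = 1)[, 1]
  dA <- fake_decomp(matrix(v, 1), "a")
  dB <- fake_decomp(matrix(-v, 1), "b")
  dC <- fake_decomp(matrix(v, 1), "c")
  tree <- build_pc_tree(list(dA, dB, dC))
  expect_equal(tree$dist["PC1_a", "PC1_b"], 0, tolerance = 1e-12)
  expect_equal(tree$dist["PC1_a", "PC1_c"], 0, tolerance = 1e-12)
  expect_true(all(tree$dist >= 0 & tree$dist <= 1))
  expect_identical(tree$dist, t(tree$dist))
  expect_true(all(diag(tree$dist) == 0))
})

test_that("a hand-computed UPGMA on three components merges as derived", {
  # pairwise r = (0.9, 0.1, 0.1): the 0.9 pair merges at 1 - 0.9 = 0.1,
  # the third joins at 1 - (0.1 + 0.1)/2 = 0.9
  R <- rbind(c(1, 0.9, 0.1), c(0.9, 1, 0.1), c(0.1, 0.1, 1))
  v <- vectors_with_cor(R, 20, seed = 2)
  decomps <- lapply(1:3, function(i)
    fake_decomp(matrix(v[, i], 1), paste0("L", i)))
  tree <- build_pc_tree(decomps)
  expect_equal(tree$cor["PC1_L1", "PC1_L2"], 0.9, tolerance = 1e-12)
  expect_equal(sort(tree$hclust$height), c(0.1, 0.9), tolerance = 1e-10)
  grp <- cutree(tree$hclust, h = 0.5)
  expect_identical(unname(grp["PC1_L1"]), unname(grp["PC1_L2"]))
  expect_false(grp["PC1_L3"] == grp["PC1_L1"])
})

test_that("UPGMA merge sequence equals the brute-force oracle", {
  set.seed(10)
  for (rep in 1:12) {
    p <- sample(4:10, 1)
    vs <- matrix(rnorm(24 * p), 24, p)
    decomps <- lapply(seq_len(p), function(i)
      fake_decomp(matrix(vs[, i], 1), paste0("L", i)))
    tree <- build_pc_tree(decomps)
    oracle <- upgma_oracle(tree$dist)
    expect_equal(sort(tree$hclust$height), sort(oracle$heights),
                 tolerance = 1e-10)
    for (j in seq_along(oracle$heights)) {
      part_pkg <- cutree(tree$hclust, k = p - j)
      expect_identical(comembership(unname(part_pkg)),
                       comembership(oracle$partitions[[j]]))
    }
  }
})

test_that("tree construction rejects mismatched inputs", {
  v <- matrix(rnorm(8), 1)
  dA <- fake_decomp(v, "a", sample_ids = paste0("s", 1:8))
  dB <- fake_decomp(v, "b", sample_ids = paste0("x", 1:8))
  expect_error(build_pc_tree(list(dA, dB)), "mismatched sample orders")
  expect_error(build_pc_tree(list(dA)), "fewer than 2")
})

test_that("within-layer components are uncorrelated in centered decompositions", {
  ds <- simulate_multiomics(small_config(seed = 13))
  decomps <- lapply(log_layers(ds), pca_decompose)
  tree <- build_pc_tree(decomps)
  for (ly in names(decomps)) {
    idx <- which(tree$labels$layer == ly)
    off <- abs(tree$cor[idx, idx])
    diag(off) <- 0
    expect_lt(max(off), 1e-8)
  }
})

test_that("select_pcs picks the tightest cross-layer cluster with tie-breaks", {
  # two candidate clusters: {L1,L2,L3} at |r| ~ 0.95 and {L4,L5} at ~ 0.7
  R <- diag(6)
  R[1, 2] <- R[2, 1] <- 0.95; R[1, 3] <- R[3, 1] <- 0.95
  R[2, 3] <- R[3, 2] <- 0.95
  R[4, 5] <- R[5, 4] <- 0.7
  v <- vectors_with_cor(R, 30, seed = 3)
  layers <- c("a", "b", "c", "a", "b", "x")
  decomps <- lapply(1:6, function(i)
    fake_decomp(matrix(v[, i], 1), paste0(layers[i], i)))
  tree <- build_pc_tree(decomps)
  sel <- select_pcs(tree, cut_height = 0.6, min_layers = 2)
  expect_setequal(sel$members$label, c("PC1_a1", "PC1_b2", "PC1_c3"))
  expect_equal(sel$cluster_mean_abs_r, 0.95, tolerance = 1e-9)
})

test_that("an all-singleton tree is reported with the nearest feasible cut", {
  R <- diag(3); R[upper.tri(R)] <- 0.05; R[lower.tri(R)] <- 0.05
  v <- vectors_with_cor(R, 40, seed = 4)
  decomps <- lapply(1:3, function(i)
    fake_decomp(matrix(v[, i], 1), paste0("L", i)))
  tree <- build_pc_tree(decomps)
  expect_error(select_pcs(tree, cut_height = 0.3), "nearest feasible")
})

test_that("select_pcs recovers planted cross-layer structure", {
  hits <- 0L
  for (seed in 1:6) {
    ds <- simulate_multiomics(small_config(seed = seed))
    decomps <- lapply(log_layers(ds), pca_decompose)
    tree <- build_pc_tree(decomps)
    sel <- select_pcs(tree)
    # contrast vectors of the planted patterns over the design
    tumor <- as.numeric(ds$design$class %in% c("ICC", "HCC"))
    icc <- as.numeric(ds$design$class == "ICC")
    aligned <- vapply(seq_len(nrow(sel$members)), function(i) {
      cx <- decomps[[sel$members$layer[i]]]$contributions[sel$members$k[i], ]
      max(abs(cor(cx, tumor)), abs(cor(cx, icc)))
    }, 0)
    ok <- length(unique(sel$members$layer)) == 3L && all(aligned > 0.7)
    hits <- hits + ok
  }
  expect_gte(hits, 5L)
})

test_that("categorical regression equals closed-form one-way ANOVA", {
  # toy 8-sample case, 4 classes of 2, plus randomized instances
  set.seed(20)
  for (rep in 1:20) {
    m <- 8L
    cx <- rnorm(m)
    C <- matrix(cx, 1)
    d <- fake_decomp(C, "toy")
    des <- sample_design(d$sample_ids,
                         rep(c("ICC", "ICC_NT", "HCC", "HCC_NT"), each = 2))
    fit <- categorical_regression(d, 1, des)
    oracle <- anova_oracle(cx, rep(c("ICC", "ICC_NT", "HCC", "HCC_NT"), each = 2))
    expect_equal(fit$F_statistic, oracle$F, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)
    # cell-means coefficients are the class means of the contributions
    cls_mean <- tapply(cx, rep(c("ICC", "ICC_NT", "HCC", "HCC_NT"), each = 2),
                       mean)[c("ICC", "ICC_NT", "HCC", "HCC_NT")]
    expect_equal(unname(fit$coefficients[c("ICC", "ICC_NT", "HCC", "HCC_NT")]),
                 as.numeric(cls_mean), tolerance = 1e-12)
  }
})

test_that("degenerate contribution vectors are handled explicitly", {
  d <- fake_decomp(matrix(rep(0.25, 8), 1), "toy")
  des <- sample_design(d$sample_ids,
                       rep(c("ICC", "ICC_NT", "HCC", "HCC_NT"), each = 2))
  fit <- categorical_regression(d, 1, des)
  expect_identical(fit$F_statistic, 0)
  expect_identical(fit$p_value, 1)

  # perfect class separation with zero residual variance
  d2 <- fake_decomp(matrix(rep(c(1, 2, 3, 4), each = 2), 1), "toy")
  expect_warning(fit2 <- categorical_regression(d2, 1, des), "zero residual")
  expect_identical(fit2$p_value, 0)
})

test_that("scatter report matches the closed-form Pearson formula", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.8; R[1, 3] <- R[3, 1] <- -0.4
  R[2, 3] <- R[3, 2] <- 0.2
  v <- vectors_with_cor(R, 32, seed = 5)
  decomps <- lapply(1:3, function(i)
    fake_decomp(matrix(v[, i], 1), paste0("L", i)))
  tree <- build_pc_tree(decomps)
  sel <- select_pcs(tree, cut_height = 0.9, min_layers = 2)
  tab <- scatter_report(sel, decomps)
  self <- tab[tab$pc1 == tab$pc2, ]
  expect_true(all(self$r == 1))
  for (i in which(tab$pc1 != tab$pc2)) {
    a <- decomps[[match(sub("PC1_", "", tab$pc1[i]), c("L1", "L2", "L3"))]]$contributions[1, ]
    b <- decomps[[match(sub("PC1_", "", tab$pc2[i]), c("L1", "L2", "L3"))]]$contributions[1, ]
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    tt <- r * sqrt((length(a) - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tt), df = length(a) - 2)
    expect_equal(tab$r[i], r, tolerance = 1e-12)
    expect_equal(tab$p_value[i], p, tolerance = 1e-12)
  }
})

test_that("same-layer orthogonal components report r = 0", {
  v <- vectors_with_cor(diag(2), 16, seed = 6)
  d <- fake_decomp(t(v), "solo")
  sel <- structure(list(members = data.frame(label = c("PC1_solo", "PC2_solo"),
                                             layer = "solo", k = 1:2),
                        cluster_mean_abs_r = 1, cut_height = 0.5),
                   class = "selected_pc_set")
  tab <- scatter_report(sel, list(d))
  off <- tab[tab$pc1 != tab$pc2, ]
  expect_lt(abs(off$r), 1e-8)
})

test_that("trees export to Newick with component labels", {
  ds <- simulate_multiomics(small_config(seed = 14))
  tree <- build_pc_tree(lapply(log_layers(ds), pca_decompose))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_pc_tree_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, tree$labels$label)
})
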
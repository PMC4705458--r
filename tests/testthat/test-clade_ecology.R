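lineages <- data.frame(id = c("g1", "g2", "g3"),
                       Order = c("O1", "O1", "O2"))

test_that("relative abundance aggregation and unclassified handling", {
  counts <- matrix(c(30, 70, 0,
                     25, 0, 75), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("g1", "g2", "gX")))
  ab <- aggregate_relative_abundance(counts, lineages, "Order")
  expect_equal(ab$rel["s1", "O1"], 1.0)       # both genera under O1
  expect_equal(ab$rel["s2", "O1"], 0.25)      # gX unclassified
  expect_equal(ab$unclassified[["s2"]], 0.75)
  expect_true(all(rowSums(ab$rel) + ab$unclassified <= 1 + 1e-12))

  counts0 <- rbind(counts, s3 = c(0, 0, 0))
  expect_warning(ab0 <- aggregate_relative_abundance(counts0, lineages),
                 "zero reads")
  expect_equal(rownames(ab0$rel), c("s1", "s2"))
})

test_that("min-max scaled summaries behave globally and per phylum", {
  rel <- matrix(c(0.1, 0.2, 0.3,
                  0.2, 0.2, 0.2,
                  0.0, 0.1, 0.2), 3, 3, byrow = FALSE,
                dimnames = list(paste0("s", 1:3), c("c1", "c2", "c3")))
  ab <- structure(list(rel = rel, rank = "Order"),
                  class = "abundance_table")
  groups <- setNames(paste0("cat", 1:3), paste0("s", 1:3))
  sm <- scaled_summary(ab, groups)
  expect_equal(unname(sm$means["c1", ]), c(0.1, 0.2, 0.3))
  expect_equal(min(sm$scaled), 0)
  expect_equal(max(sm$scaled), 1)
  expect_equal(unname(sm$scaled["c1", ]), (c(0.1, 0.2, 0.3) - 0) / 0.3)

  # constant table maps to all zero
  abc <- structure(list(rel = rel * 0 + 0.2, rank = "Order"),
                   class = "abundance_table")
  expect_true(all(scaled_summary(abc, groups)$scaled == 0))

  # per-phylum scaling of one phylum unaffected by the other
  ph <- c(c1 = "P1", c2 = "P1", c3 = "P2")
  sp <- scaled_summary(ab, groups, scope = "per_phylum", phylum_of = ph)
  expect_equal(unname(sp$scaled["c3", ]), c(0, 0.5, 1))
  sp2 <- scaled_summary(
    structure(list(rel = t(t(rel) * c(1, 1, 10)), rank = "Order"),
              class = "abundance_table"),
    groups, scope = "per_phylum", phylum_of = ph)
  expect_equal(sp$scaled[c("c1", "c2"), ], sp2$scaled[c("c1", "c2"), ])
})

test_that("site association test matches exhaustive enumeration on a toy", {
  # 6 samples, 3 target / 3 other; clade present only in target
  rel <- matrix(c(1, 1, 1, 0, 0, 0), 6, 1,
                dimnames = list(paste0("s", 1:6), "cl"))
  groups <- setNames(rep(c("T", "U"), each = 3), paste0("s", 1:6))
  res <- site_association_test(rel, groups, n_perm = 999, seed = 4)
  rT <- res[res$category == "T", ]
  # exhaustive null: 20 label arrangements, stat >= 1 only for the
  # observed one -> exact one-sided p = 1/20; sampled permutations draw
  # the tied-max arrangement with probability 3!3!/6! = 1/20
  expect_equal(rT$statistic, 1)
  expect_gt(rT$p_value, 0.03)
  expect_lt(rT$p_value, 0.08)

  # with 10 vs 10 samples the tied-max arrangement is essentially never
  # drawn, so the p-value hits its 1/(n_perm+1) floor
  rel20 <- matrix(c(runif(10, 0.5, 1), rep(0, 10)), 20, 1,
                  dimnames = list(paste0("t", 1:20), "cl"))
  g20 <- setNames(rep(c("T", "U"), each = 10), paste0("t", 1:20))
  r20 <- site_association_test(rel20, g20, n_perm = 999, seed = 8)
  expect_equal(r20$p_value[r20$category == "T"], 1 / 1000)

  # constant abundance: statistic 0, p = 1 under the >= convention
  relc <- matrix(0.5, 6, 1, dimnames = list(paste0("s", 1:6), "cl"))
  resc <- site_association_test(relc, groups, n_perm = 99, seed = 1)
  expect_equal(resc$statistic, c(0, 0))
  expect_equal(resc$p_value, c(1, 1))

  # absent clade: statistic 0, p = 1
  rel0 <- cbind(rel, none = 0)
  res0 <- site_association_test(rel0, groups, n_perm = 99, seed = 1)
  expect_equal(res0$statistic[res0$clade == "none"], c(0, 0))
  expect_equal(res0$p_value[res0$clade == "none"], c(1, 1))

  # seed reproducibility is bit-exact; p bounded below by 1/(n_perm+1)
  res2 <- site_association_test(rel, groups, n_perm = 999, seed = 4)
  expect_identical(res$p_value, res2$p_value)
  expect_true(all(res$p_value >= 1 / 1000))

  expect_error(site_association_test(rel, setNames(rep("T", 6), paste0("s", 1:6))),
               ">= 2 categories")
})

test_that("indval statistic variant is available and sane", {
  rel <- matrix(c(1, 1, 1, 0, 0, 0), 6, 1,
                dimnames = list(paste0("s", 1:6), "cl"))
  groups <- setNames(rep(c("T", "U"), each = 3), paste0("s", 1:6))
  res <- site_association_test(rel, groups, n_perm = 999, seed = 2,
                               statistic = "indval")
  rT <- res[res$category == "T", ]
  expect_equal(rT$statistic, 1)  # perfect specificity x fidelity
  # tied-max arrangement has probability 1/20 per permutation
  expect_gt(rT$p_value, 0.02)
  expect_lt(rT$p_value, 0.09)
})

test_that("spearman screen equals the midrank Pearson oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  ab <- matrix(x, 5, 1, dimnames = list(paste0("s", 1:5), "cl"))
  env <- data.frame(sample = paste0("s", 1:5), v = y)
  expect_equal(spearman_screen(ab, env)$rho, 1)
  env$v <- rev(y)
  expect_equal(spearman_screen(ab, env)$rho, -1)

  # hand-computed case: rho = 0.8
  ab4 <- matrix(c(1, 2, 3, 4), 4, 1,
                dimnames = list(paste0("s", 1:4), "cl"))
  env4 <- data.frame(sample = paste0("s", 1:4), v = c(1, 3, 2, 4))
  r4 <- spearman_screen(ab4, env4)
  expect_equal(r4$rho, 0.8)
  expect_equal(r4$p_value,
               2 * pt(-abs(0.8 * sqrt(2 / (1 - 0.64))), df = 2))

  # ties: midrank Pearson oracle to 1e-12 on random vectors
  set.seed(42)
  for (i in 1:50) {
    n <- 10 + i %% 20
    xx <- sample(1:6, n, replace = TRUE) + ifelse(runif(n) < 0.5, 0.5, 0)
    yy <- sample(1:5, n, replace = TRUE)
    abx <- matrix(xx, n, 1, dimnames = list(paste0("s", 1:n), "cl"))
    envx <- data.frame(sample = paste0("s", 1:n), v = yy)
    got <- spearman_screen(abx, envx)$rho
    oracle <- stats::cor(rank(xx), rank(yy), method = "pearson")
    if (is.na(oracle)) next
    expect_equal(got, oracle, tolerance = 1e-12)
  }

  # missing values pairwise; < 3 complete pairs skipped; zero variance skipped
  envm <- data.frame(sample = paste0("s", 1:5), v = c(2, NA, 6, 8, 10),
                     w = c(1, NA, NA, NA, 2), z = rep(3, 5))
  rm <- spearman_screen(ab, envm)
  expect_equal(rm$n[rm$variable == "v"], 4)
  expect_equal(rm$skipped_reason[rm$variable == "w"],
               "fewer than 3 complete pairs")
  expect_equal(rm$skipped_reason[rm$variable == "z"], "zero variance")

  # BH adjustment flag
  rb <- spearman_screen(ab, envm, adjust = "BH")
  expect_true("p_adjusted" %in% names(rb))
})
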
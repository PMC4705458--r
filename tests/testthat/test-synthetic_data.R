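test_that("sim_params validates divergence interleaving and sizes", {
  expect_s3_class(sim_params(), "sim_params")
  bad <- c(within_genus = 6, between_genus = 8, between_family = 15.75,
           between_order = 23, outgroup = 35)
  expect_error(sim_params(divergence = bad), "interleave")
  expect_error(sim_params(n_orders = 1L, families_per_order = 1L,
                          genera_per_family = 1L, leaves_per_genus = 2L),
               ">= 4")
})

test_that("simulated trees have the planted leaf counts and determinism", {
  p <- sim_params(seed = 3, n_orders = 2L, families_per_order = 1L,
                  genera_per_family = 2L, leaves_per_genus = 2L)
  tr <- simulate_tree(p)
  expect_equal(length(tr$phy$tip.label), 8 + 5)  # in-group + outgroup
  expect_equal(sort(tr$outgroup), sort(paste0("og", 1:5)))
  expect_equal(nrow(attr(tr, "truth")), 8)
  expect_null(tr$phy$node.label)  # singleton levels collapsed cleanly
  tr2 <- simulate_tree(p)
  expect_identical(ape::write.tree(tr$phy), ape::write.tree(tr2$phy))
  # planted between-genus distance exceeds the genus cutoff by design
  expect_gt(p$divergence["between_genus"],
            attr(rank_thresholds(), "cutoffs")["Genus"] + 2)
})

test_that("JC evolution is deterministic with expected identity decay", {
  p <- fast_params(11, gap_col_rate = 0)
  tr <- simulate_tree(p)
  aln1 <- evolve_alignment(tr, p)
  aln2 <- evolve_alignment(tr, p)
  expect_identical(aln1$records$aligned_seq, aln2$records$aligned_seq)

  # zero branch lengths -> identical sequences
  tr0 <- tr; tr0$phy$edge.length[] <- 0
  aln0 <- evolve_alignment(tr0, p)
  expect_equal(length(unique(aln0$records$aligned_seq)), 1)
  d0 <- pairwise_identity_matrix(aln0)
  expect_true(all(d0 == 0))

  # realized distance near the JC expectation within 3 binomial SEs
  truth <- attr(tr, "truth")
  d <- pairwise_identity_matrix(aln1)
  same_genus <- outer(truth$Genus, truth$Genus, "==")
  diag(same_genus) <- NA
  ids <- truth$id
  planted <- p$divergence["within_genus"]
  se <- 100 * sqrt(planted / 100 * (1 - planted / 100) / p$seq_length)
  # genus MRCAs sit at the planted divergence; mean realized pairwise
  # distance within genera must sit below it (coalescent heights), and
  # cross-order distances near their own expectation
  expect_lt(mean(d[ids, ids][same_genus & !is.na(same_genus)]), planted + 3 * se)
  diff_order <- outer(truth$Order, truth$Order, "!=")
  planted_o <- p$divergence["between_order"]
  se_o <- 100 * sqrt(planted_o / 100 * (1 - planted_o / 100) / p$seq_length)
  expect_equal(mean(d[ids, ids][diff_order]), unname(planted_o),
               tolerance = 3 * se_o / planted_o)
})

test_that("metadata synthesis hits every filter branch as configured", {
  p0 <- fast_params(13, contaminant_fraction = 0)
  b0 <- make_fixture_bundle(p0, tempfile("meta0"))
  truth0 <- read.delim(file.path(b0$dir, "truth_lineages.tsv"))
  aln0 <- read_alignment_fasta(file.path(b0$dir, "alignment.fasta"),
                               file.path(b0$dir, "metadata.tsv"))
  rep0 <- apply_quality_filters(aln0)
  rep0 <- rep0[rep0$id %in% truth0$id, ]
  expect_true(all(rep0$pass))  # contaminant fraction 0 -> all selected

  p1 <- fast_params(13, contaminant_fraction = 1)
  tr <- simulate_tree(p1)
  aln <- synthesize_metadata(evolve_alignment(tr, p1), p1, tr$outgroup)
  rep1 <- apply_quality_filters(aln)
  rep1 <- rep1[!rep1$id %in% tr$outgroup, ]
  expect_false(any(rep1$pass))  # contaminant fraction 1 -> none

  # outgroup records are cultivated, never environmental
  repo <- apply_quality_filters(aln)
  expect_false(any(repo$environmental[repo$id %in% tr$outgroup]))
})

test_that("abundance/env simulator plants detectable structure", {
  p <- sim_params(seed = 21, n_samples = 40L)
  eco <- simulate_abundance_env(p, clades = paste0("cl", 1:10))
  expect_equal(dim(eco$counts), c(40, 10))
  expect_equal(unname(rowSums(eco$counts)), rep(10000, 40))
  expect_equal(eco$truth$clade[eco$truth$effect == "indicator"], "cl1")

  # same seed -> identical tables
  eco2 <- simulate_abundance_env(p, clades = paste0("cl", 1:10))
  expect_identical(eco$counts, eco2$counts)
  expect_identical(eco$env, eco2$env)

  # noiseless monotone limit: Spearman rho = 1 against depth
  pn <- sim_params(seed = 22, dispersion = 0, env_missing_rate = 0,
                   env_strength = 4, fold_change = 1,  # gradient only
                   depth = 1000000L)  # high depth avoids rounding ties
  econ <- simulate_abundance_env(pn, clades = paste0("cl", 1:6))
  rel <- econ$counts / rowSums(econ$counts)
  r <- spearman_screen(rel[, "cl2", drop = FALSE], econ$env,
                       variables = "depth")
  expect_equal(r$rho, 1)

  expect_error(simulate_abundance_env(sim_params(fold_change = 0),
                                      clades = c("a", "b")),
               "fold-change")
})

test_that("fixture bundles are byte-identical and margin-checked", {
  p <- fast_params(31)
  d1 <- tempfile("b1"); d2 <- tempfile("b2")
  make_fixture_bundle(p, d1)
  make_fixture_bundle(p, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  rm <- read.delim(file.path(d1, "realized_margins.tsv"))
  expect_true(all(rm$pass == 1))
  expect_true(all(rm$within_max < rm$cutoff - 0.25))
  expect_true(all(rm$between_min > rm$cutoff + 0.25))

  # annotating one planted order leaves exactly n_orders - 1 unknown
  pk <- fast_params(33, known_orders = 1L, contaminant_fraction = 0)
  bk <- make_fixture_bundle(pk, tempfile("bk"))
  res <- run_pipeline(bk$dir, tempfile("bko"), seed = 33, n_perm = 49)
  s <- summary(res$hierarchy)
  expect_equal(s$n_unknown[s$rank == "Order"], 2L)
  expect_equal(s$n_ctus[s$rank == "Order"], 3L)
})
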
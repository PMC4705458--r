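test_that("outgroup rooting splits outgroup from in-group", {
  tr <- tree_from_newick("((A:1,B:1):1,(C:1,D:1):1,(O1:1,O2:1):1);",
                         c("O1", "O2"))
  rooted <- root_with_outgroup(tr)
  expect_true(ape::is.rooted(rooted$phy))
  expect_true(ape::is.monophyletic(rooted$phy, c("O1", "O2")))
  expect_true(ape::is.monophyletic(rooted$phy, c("A", "B", "C", "D")))

  # five-leaf outgroup clade: in-group is everything else
  tr5 <- tree_from_newick(
    "((A:1,B:1):1,(C:1,D:1):1,((O1:1,O2:1):1,(O3:1,(O4:1,O5:1):1):1):1);",
    paste0("O", 1:5))
  r5 <- root_with_outgroup(tr5)
  expect_true(ape::is.monophyletic(r5$phy, c("A", "B", "C", "D")))

  # non-monophyletic outgroup: warning + best-split rooting
  trb <- tree_from_newick("((O1:1,A:1):1,(B:1,C:1):1,(O2:1,D:1):1);",
                          c("O1", "O2"))
  expect_warning(rb <- root_with_outgroup(trb), "not monophyletic")
  expect_true(ape::is.rooted(rb$phy))

  expect_error(root_with_outgroup(tree_from_newick("(A:1,B:1,C:1);")),
               "no outgroup")
  tr_all <- tree_from_newick("(A:1,B:1,C:1);")
  tr_all$outgroup <- c("A", "B", "C")
  expect_error(root_with_outgroup(tr_all), "every leaf")
})

test_that("CTUs are maximal monochromatic clades", {
  tr <- tree_from_newick("((((A:1,B:1):1,C:2):1,(D:1,E:1):2):1,O1:4);",
                         "O1")
  rooted <- root_with_outgroup(tr)
  # coherent OTUs -> one component each
  p <- c(A = 1L, B = 1L, C = 1L, D = 2L, E = 2L)
  ctus <- recognize_rank_ctus(rooted, p)
  expect_equal(nrow(ctus), 2)
  expect_equal(sort(vapply(ctus$members, paste, "", collapse = "")),
               c("ABC", "DE"))
  expect_equal(ctus$n_components, c(1L, 1L))

  # single OTU -> one CTU equal to the whole in-group
  p1 <- setNames(rep(1L, 5), names(p))
  ctus1 <- recognize_rank_ctus(rooted, p1)
  expect_equal(nrow(ctus1), 1)
  expect_setequal(ctus1$members[[1]], names(p))

  # interleaved OTUs split into singleton components
  tr2 <- tree_from_newick("(((A:1,C:1):1,(B:1,D:1):1):1,O1:3);", "O1")
  r2 <- root_with_outgroup(tr2)
  p2 <- c(A = 1L, B = 1L, C = 2L, D = 2L)
  ctus2 <- recognize_rank_ctus(r2, p2)
  expect_equal(nrow(ctus2), 4)
  expect_equal(sort(as.integer(table(ctus2$otu))), c(2L, 2L))
  expect_true(all(vapply(ctus2$members, length, 1L) == 1))

  expect_error(recognize_rank_ctus(r2, p2[-1]), "without OTU")
})

test_that("polytomy children are never silently grouped", {
  tr <- tree_from_newick("((A:1,B:1,C:1,D:1):1,O1:2);", "O1")
  rooted <- root_with_outgroup(tr)
  # A and B monochromatic within a polytomy: two singleton components,
  # not one two-leaf CTU (no silent resolution of the polytomy)
  p <- c(A = 1L, B = 1L, C = 2L, D = 3L)
  ctus <- recognize_rank_ctus(rooted, p)
  expect_equal(nrow(ctus), 4)
  expect_equal(ctus$n_components[ctus$otu == 1], c(2L, 2L))
})

test_that("hierarchy nests, names follow the convention, known flags work", {
  p <- fast_params(9)
  b <- make_fixture_bundle(p, tempfile("hier"))
  res <- run_pipeline(b$dir, tempfile("hout"), seed = 9, n_perm = 49)
  h <- res$hierarchy
  ct <- h$ctus

  # partition + nesting invariants at every rank
  for (rk in h$ranks) {
    mem <- unlist(ct$members[ct$rank == rk])
    expect_setequal(mem, h$leaves)
    expect_false(anyDuplicated(mem) > 0)
  }
  kids <- which(!is.na(ct$parent_index))
  for (k in kids) {
    expect_true(all(ct$members[[k]] %in% ct$members[[ct$parent_index[k]]]))
    expect_equal(match(ct$rank[ct$parent_index[k]], h$ranks) + 1L,
                 match(ct$rank[k], h$ranks))
  }
  # context-free naming: Phylum1, Phylum1.Order1 style
  expect_true(any(grepl("^Phylum[0-9]+$", ct$name[ct$rank == "Phylum"])))
  expect_true(all(grepl("^Phylum[0-9]+\\.Genus[0-9]+(-[0-9]+)?$",
                        ct$name[ct$rank == "Genus"])))
  expect_false(anyDuplicated(ct$name) > 0)

  # monophyly: every CTU member set equals the in-group leaf set of a node
  rooted <- root_with_outgroup(
    read_tree_newick(file.path(b$dir, "tree.nwk"),
                     readLines(file.path(b$dir, "outgroup.txt"))))
  keep <- intersect(rooted$phy$tip.label,
                    c(h$leaves, rooted$outgroup))
  pr <- ape::keep.tip(rooted$phy, keep)
  sets <- ctuscope:::node_tip_sets(pr)
  ingroup_sets <- lapply(sets, function(s)
    sort(setdiff(pr$tip.label[s], rooted$outgroup)))
  for (i in seq_len(nrow(ct)))
    expect_true(any(vapply(ingroup_sets, identical, TRUE,
                           y = sort(ct$members[[i]]))),
                label = ct$name[i])

  # named context
  h2 <- assign_names(h, "Thaumarchaeota")
  expect_true(all(grepl("^Thaumarchaeota\\.",
                        h2$ctus$name[h2$ctus$rank == "Order"])))

  # known-clade flagging
  truth <- read.delim(file.path(b$dir, "truth_lineages.tsv"))
  ids1 <- intersect(truth$id[truth$Order == "TrueOrder1"], h$leaves)
  h3 <- flag_known_clades(h, setNames(rep("SAR11", length(ids1)), ids1))
  s3 <- summary(h3)
  expect_equal(s3$n_unknown[s3$rank == "Order"],
               s3$n_ctus[s3$rank == "Order"] - 1L)
  expect_true(all(vapply(
    h3$ctus$known_labels[h3$ctus$status == "known"],
    function(x) identical(x, "SAR11"), TRUE)))
  # no annotations -> all unknown; all annotated -> none unknown
  expect_true(all(flag_known_clades(h)$ctus$status == "unknown"))
  all_ann <- setNames(rep("K", length(h$leaves)), h$leaves)
  expect_true(all(flag_known_clades(h, all_ann)$ctus$status == "known"))
  expect_warning(flag_known_clades(h, c(nope = "X")), "non-leaf")
})

test_that("hyphen suffixes appear iff an OTU splits into components", {
  # force a polyphyletic order OTU: tree groups A+C and B+D, identity
  # clustering would put {A,B} and {C,D} together
  tr <- tree_from_newick("(((A:1,C:1):1,(B:1,D:1):1):1,(O1:1,O2:1):2);",
                         c("O1", "O2"))
  parts <- structure(lapply(c(25, 21.5, 18, 13.5, 5.5), function(cut) {
    if (cut > 10) setNames(c(1L, 1L, 2L, 2L), c("A", "B", "C", "D"))
    else setNames(1:4, c("A", "B", "C", "D"))
  }), names = c("Phylum", "Class", "Order", "Family", "Genus"),
  class = "rank_partitions")
  h <- recognize_ctus(tr, parts, context_name = "Bacteroidetes")
  ord <- h$ctus$name[h$ctus$rank == "Order"]
  expect_setequal(ord, c("Bacteroidetes.Order1-1", "Bacteroidetes.Order1-2",
                         "Bacteroidetes.Order2-1", "Bacteroidetes.Order2-2"))
  gen <- h$ctus$name[h$ctus$rank == "Genus"]
  expect_true(all(grepl("^Bacteroidetes\\.Genus[0-9]+$", gen)))  # no suffix
})

test_that("recognition is idempotent and correct on random planted trees", {
  # random synthetic trees: OTUs defined as true clades must come back as
  # single components covering the same leaves
  for (s in 1:100) {
    set.seed(s)
    n <- 8 + s %% 10
    phy <- ape::rtree(n)
    phy$tip.label <- sprintf("t%02d", 1:n)
    tr <- ctuscope:::new_ctu_tree(phy, character())
    # pick a random internal node; its clade is OTU 1, rest OTU 2 (+3...)
    sets <- ctuscope:::node_tip_sets(phy)
    internal <- (n + 2):(n + phy$Nnode)
    v <- sample(internal, 1)
    otus <- setNames(rep(2L, n), phy$tip.label)
    otus[phy$tip.label[sets[[v]]]] <- 1L
    ctus <- recognize_rank_ctus(tr, otus)
    one <- ctus[ctus$otu == 1L, ]
    expect_equal(nrow(one), 1L, label = paste("seed", s))
    expect_setequal(one$members[[1]], phy$tip.label[sets[[v]]])
    # coverage and disjointness
    expect_setequal(unlist(ctus$members), phy$tip.label)
    # union of an OTU's components equals the OTU
    expect_setequal(unlist(ctus$members[ctus$otu == 2L]),
                    setdiff(phy$tip.label, phy$tip.label[sets[[v]]]))
  }
})
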
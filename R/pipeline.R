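## End-to-end driver: read a fixture bundle (or generate one), mine marine
## sequences, cluster, recognize CTUs, run the ecology statistics, and
## write deterministic outputs. Backs the `ctuscope` command-line script.

#' Run the full CTU pipeline on a fixture bundle
#'
#' Stages: (1) read alignment/metadata, tree and tables from `fixture_dir`
#' (layout as written by [make_fixture_bundle()]); (2) mine marine
#' environmental quality-passing sequences ([apply_quality_filters()],
#' [select_clades_for_trees()]; without a prior-clade file every record is
#' its own clade); (3) conservation-mask, compute distances and cut nested
#' OTU partitions; (4) root on the outgroup and recognize, name and flag
#' CTUs; (5) aggregate the count table to the analysis rank and run the
#' site-association and Spearman screens; (6) write `taxonomy.tsv`,
#' `lineages.tsv`, `associations.tsv`, `correlations.tsv` and
#' `summary.tsv` under `out_dir`. All stages are deterministic given the
#' fixture and `seed`.
#'
#' @param fixture_dir directory with the pipeline inputs.
#' @param out_dir output directory.
#' @param seed integer seed for the permutation tests.
#' @param context_name naming context, see [assign_names()].
#' @param rank analysis rank for the ecology stage.
#' @param n_perm permutations for [site_association_test()].
#' @param thresholds a [rank_thresholds()] object.
#' @return list with `report`, `selection`, `partitions`, `hierarchy`,
#'   `abundance`, `associations`, `correlations`, `files`, invisibly.
#' @export
run_pipeline <- function(fixture_dir, out_dir, seed = 1L,
                         context_name = "", rank = "Order",
                         n_perm = 999, thresholds = rank_thresholds()) {
  path <- function(f) file.path(fixture_dir, f)
  aln <- read_alignment_fasta(path("alignment.fasta"), path("metadata.tsv"))
  outgroup <- if (file.exists(path("outgroup.txt")))
    readLines(path("outgroup.txt")) else character()
  tree <- read_tree_newick(path("tree.nwk"), outgroup)

  report <- apply_quality_filters(aln)
  report <- report[!report$id %in% outgroup, , drop = FALSE]
  prior <- list()
  if (file.exists(path("prior_clades.tsv"))) {
    pc <- read.delim(path("prior_clades.tsv"), stringsAsFactors = FALSE)
    prior <- split(pc$id, pc$clade)
  }
  selection <- select_clades_for_trees(prior, report)
  ids <- selection$selected_ids
  if (length(ids) < 2) stop2("fewer than 2 sequences survive mining")

  sub <- aln
  sub$records <- sub$records[match(ids, sub$records$id), , drop = FALSE]
  mask <- build_conservation_mask(sub)
  dmat <- pairwise_identity_matrix(sub, mask)
  dendro <- furthest_neighbor_dendrogram(dmat)
  partitions <- cut_partitions(dendro, thresholds)

  keep <- intersect(tree$phy$tip.label, c(ids, outgroup))
  pruned <- new_ctu_tree(ape::keep.tip(tree$phy, keep),
                         intersect(outgroup, keep))
  ann <- character()
  if (file.exists(path("known_annotations.tsv"))) {
    adf <- read.delim(path("known_annotations.tsv"),
                      stringsAsFactors = FALSE)
    if (nrow(adf)) {
      adf <- adf[adf$id %in% ids, , drop = FALSE]
      ann <- stats::setNames(adf$label, adf$id)
    }
  }
  hierarchy <- recognize_ctus(pruned, partitions, context_name, ann)

  abundance <- associations <- correlations <- NULL
  if (file.exists(path("counts.tsv"))) {
    tabs <- read_tables(path("counts.tsv"),
                        if (file.exists(path("env.tsv"))) path("env.tsv"))
    lmap <- read.delim(path("lineage_map.tsv"), stringsAsFactors = FALSE)
    abundance <- aggregate_relative_abundance(tabs$counts, lmap, rank)
    if (!is.null(tabs$env)) {
      groups <- stats::setNames(tabs$env$water_body, tabs$env$sample)
      associations <- site_association_test(abundance, groups,
                                            n_perm = n_perm, seed = seed)
      correlations <- spearman_screen(abundance, tabs$env)
    }
  }

  files <- write_outputs(hierarchy,
                         list(associations = associations,
                              correlations = correlations), out_dir)
  s <- summary(hierarchy)
  f <- file.path(out_dir, "summary.tsv")
  write.table(s, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(report = report, selection = selection,
                 partitions = partitions, hierarchy = hierarchy,
                 abundance = abundance, associations = associations,
                 correlations = correlations, files = c(files, f)))
}

#' Read a key=value configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored;
#' values that parse as numbers become numeric, comma-separated values
#' become vectors. Keys matching [sim_params()] arguments configure the
#' simulator; `context_name`, `rank`, `n_perm` configure the pipeline.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop2("bad config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
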
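## Seed-deterministic synthetic fixtures with known ground truth: ultrametric
## trees with planted rank structure, Jukes-Cantor sequence evolution,
## SILVA-style metadata, and abundance/environment tables with planted
## indicator and gradient effects.

#' Simulation parameters for synthetic fixtures
#'
#' The defaults describe the bundled "smoke" world: 120 in-group sequences
#' in 3 planted orders x 2 families x 2 genera x 10 leaves, plus 5
#' cultivated outgroup sequences; alignment length 1200; planted pairwise
#' divergences (in percent observed distance) interleaved with the rank
#' cutoffs with >= 2 percentage points of margin on each side of the
#' genus (5.5), family (13.5) and order (18) cutoffs:
#' within genus 2, between genera 8, between families 15.75, between
#' orders 23, outgroup 35. Ecology: 40 samples in 4 water-body categories,
#' sequencing depth 10,000 reads, a 5-fold planted enrichment of the first
#' planted order in the first category, and a planted positive depth
#' gradient on the second planted order.
#'
#' @param seed integer master seed; every stage derives its own stream.
#' @param n_orders,families_per_order,genera_per_family,leaves_per_genus
#'   planted taxon sizes.
#' @param n_outgroup outgroup leaves attached below the in-group root.
#' @param divergence named numeric vector of planted percent distances:
#'   `within_genus`, `between_genus`, `between_family`, `between_order`,
#'   `outgroup`.
#' @param seq_length alignment columns.
#' @param gap_col_rate fraction of columns converted to mostly-gap columns
#'   (removed later by the conservation mask).
#' @param contaminant_fraction fraction of in-group records given
#'   contaminant metadata (soil source, cultivated name, or sub-threshold
#'   Pintail, cycling) to exercise the mining filters.
#' @param domain domain written into metadata; the default `"Archaea"`
#'   pairs with the 900 bp length rule (a 1200-column alignment cannot
#'   exceed the strict 1200 bp bacterial rule once gaps are injected).
#' @param known_orders integer indices of planted orders whose leaves get
#'   known-clade annotations in the bundle (default none).
#' @param context_name naming context for CTU names ("" gives
#'   `Phylum1.Order1`-style names).
#' @param n_samples,categories ecology design: `categories` is a character
#'   vector of water-body labels recycled over samples.
#' @param depth reads per sample.
#' @param dispersion Dirichlet overdispersion of per-sample proportions
#'   around the baseline (larger = less noise; 0 = deterministic expected
#'   counts).
#' @param fold_change planted enrichment of the indicator order in its
#'   target category.
#' @param env_strength log-scale slope of the planted depth gradient.
#' @param env_missing_rate fraction of environmental cells set missing.
#' @return a `sim_params` list.
#' @export
sim_params <- function(seed = 1L,
                       n_orders = 3L, families_per_order = 2L,
                       genera_per_family = 2L, leaves_per_genus = 10L,
                       n_outgroup = 5L,
                       divergence = c(within_genus = 2, between_genus = 8,
                                      between_family = 15.75,
                                      between_order = 23, outgroup = 35),
                       seq_length = 1200L, gap_col_rate = 0.02,
                       contaminant_fraction = 0.1,
                       domain = "Archaea",
                       known_orders = integer(),
                       context_name = "",
                       n_samples = 40L,
                       categories = c("LP ocean water", "MP coastal water",
                                      "HP coastal water", "LP anoxic water"),
                       depth = 10000L, dispersion = 200,
                       fold_change = 5, env_strength = 3,
                       env_missing_rate = 0.02) {
  p <- as.list(environment())
  cut <- attr(rank_thresholds(), "cutoffs")
  d <- p$divergence
  ok <- d["within_genus"] < cut["Genus"] &&
    cut["Genus"] < d["between_genus"] &&
    d["between_genus"] < cut["Family"] &&
    cut["Family"] < d["between_family"] &&
    d["between_family"] < cut["Order"] &&
    cut["Order"] < d["between_order"] &&
    d["between_order"] < d["outgroup"]
  if (!ok)
    stop2("divergence levels must interleave the rank cutoffs: ",
          "within_genus < 5.5 < between_genus < 13.5 < between_family",
          " < 18 < between_order < outgroup")
  if (p$n_orders * p$families_per_order * p$genera_per_family *
      p$leaves_per_genus < 4) stop2("need >= 4 in-group leaves")
  structure(p, class = "sim_params")
}

# Jukes-Cantor branch length (substitutions/site) for an expected observed
# percent distance
jc_branch_length <- function(percent) {
  p <- percent / 100
  if (any(p >= 0.75)) stop2("observed distance must be < 75%")
  -0.75 * log(1 - 4 * p / 3)
}

# random ultrametric subtree over `labels`, depth `height` (Newick string
# without trailing semicolon); coalescent topology via ape::rcoal
random_ultrametric_newick <- function(labels, height) {
  k <- length(labels)
  if (k == 1) return(paste0(labels, ":", format(height, digits = 12)))
  t <- ape::rcoal(k, tip.label = labels)
  depth <- max(ape::node.depth.edgelength(t))
  t$edge.length <- t$edge.length / depth * height
  sub(";$", "", ape::write.tree(t))
}

#' Simulate a tree with planted rank structure
#'
#' Builds a rooted ultrametric in-group tree whose node heights place the
#' expected observed pairwise distances exactly at the planted divergence
#' levels (heights are Jukes-Cantor branch lengths, so that distances
#' compose exactly along paths): leaves of one genus coalesce by
#' `within_genus`, genera of one family at `between_genus`, families of
#' one order at `between_family`, orders at `between_order`. Topology
#' within each level is random (coalescent). `n_outgroup` outgroup leaves
#' (`og1` ...) are attached below the in-group root at the `outgroup`
#' divergence.
#'
#' @param params a [sim_params()] object.
#' @return a `ctu_tree` with attribute `truth`: data.frame id/Order/
#'   Family/Genus for in-group leaves.
#' @export
simulate_tree <- function(params) {
  set.seed(derive_seed(params$seed, 1))
  d <- params$divergence
  h_g <- jc_branch_length(d["within_genus"]) / 2
  h_f <- jc_branch_length(d["between_genus"]) / 2
  h_o <- jc_branch_length(d["between_family"]) / 2
  h_r <- jc_branch_length(d["between_order"]) / 2
  h_top <- jc_branch_length(d["outgroup"]) / 2
  stopifnot(h_g < h_f, h_f < h_o, h_o < h_r, h_r < h_top)

  leaf <- 0L
  truth <- list()
  fmt <- function(x) format(x, digits = 12, scientific = FALSE)
  order_nwk <- character(params$n_orders)
  for (o in seq_len(params$n_orders)) {
    fam_nwk <- character(params$families_per_order)
    for (f in seq_len(params$families_per_order)) {
      gen_nwk <- character(params$genera_per_family)
      for (g in seq_len(params$genera_per_family)) {
        ids <- sprintf("s%04d", leaf + seq_len(params$leaves_per_genus))
        leaf <- leaf + params$leaves_per_genus
        truth[[length(truth) + 1]] <- data.frame(
          id = ids, Order = paste0("TrueOrder", o),
          Family = paste0("TrueFamily", o, ".", f),
          Genus = paste0("TrueGenus", o, ".", f, ".", g),
          stringsAsFactors = FALSE)
        gen_nwk[g] <- paste0(random_ultrametric_newick(ids, h_g),
                             ":", fmt(h_f - h_g))
      }
      fam_nwk[f] <- paste0("(", paste(gen_nwk, collapse = ","), "):",
                           fmt(h_o - h_f))
    }
    order_nwk[o] <- paste0("(", paste(fam_nwk, collapse = ","), "):",
                           fmt(h_r - h_o))
  }
  ingroup <- paste0("(", paste(order_nwk, collapse = ","), "):",
                    fmt(h_top - h_r))
  og_ids <- paste0("og", seq_len(params$n_outgroup))
  outgroup <- paste0(random_ultrametric_newick(og_ids, h_g), ":",
                     fmt(h_top - h_g))
  nwk <- paste0("(", ingroup, ",", outgroup, ");")
  phy <- ape::collapse.singles(ape::read.tree(text = nwk))
  tree <- new_ctu_tree(phy, og_ids)
  attr(tree, "truth") <- do.call(rbind, truth)
  tree
}

#' Evolve an alignment along a tree under Jukes-Cantor
#'
#' Draws a uniform root sequence and applies independent per-site JC
#' substitutions along each branch (change probability
#' `3/4 * (1 - exp(-4t/3))` for branch length `t`). Optionally converts a
#' random `gap_col_rate` fraction of columns into mostly-gap columns (95%
#' of sequences gapped) to exercise the conservation mask.
#'
#' @param tree a `ctu_tree` with branch lengths.
#' @param params a [sim_params()] object (`seq_length`, `gap_col_rate`,
#'   `seed`).
#' @return a `ctu_alignment` with empty metadata fields.
#' @export
evolve_alignment <- function(tree, params) {
  set.seed(derive_seed(params$seed, 2))
  phy <- tree$phy
  L <- params$seq_length
  ntip <- length(phy$tip.label)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  seqs <- vector("list", ntip + phy$Nnode)
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  eo <- ape::reorder.phylo(phy, "postorder")
  pre <- rev(seq_len(nrow(eo$edge)))
  lens <- eo$edge.length %||% rep(0, nrow(eo$edge))
  for (k in pre) {
    par <- eo$edge[k, 1]; child <- eo$edge[k, 2]
    s <- seqs[[par]]
    p_change <- 0.75 * (1 - exp(-4 * lens[k] / 3))
    hit <- which(runif(L) < p_change)
    if (length(hit))
      s[hit] <- 1L + (s[hit] - 1L + sample.int(3L, length(hit),
                                               replace = TRUE)) %% 4L
    seqs[[child]] <- s
  }
  m <- matrix("", ntip, L)
  for (i in seq_len(ntip)) m[i, ] <- BASES[seqs[[i]]]
  if (params$gap_col_rate > 0) {
    gap_cols <- which(runif(L) < params$gap_col_rate)
    for (cc in gap_cols) {
      gapped <- sample.int(ntip, ceiling(0.95 * ntip))
      m[gapped, cc] <- "-"
    }
  }
  records <- data.frame(
    id = phy$tip.label, organism_name = "", strain = "",
    isolation_source = "", pintail = NA_real_, seq_quality = NA_real_,
    align_quality = NA_real_, domain = NA_character_,
    aligned_seq = apply(m, 1, paste, collapse = ""),
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  new_alignment(records)
}

MARINE_SOURCES <- c("surface seawater, North Atlantic, 5 m",
                    "mesopelagic water column, station ALOHA, 500 m",
                    "bathypelagic ocean water, 2000 m",
                    "epipelagic seawater, Sargasso Sea",
                    "open ocean water column, equatorial Pacific")
CONTAMINANT_SPECS <- list(
  soil = list(source = "agricultural soil, maize field"),
  cultivated = list(name = "Nitrosopumilus maritimus", strain = "SCM1"),
  low_pintail = list(pintail = 50))

#' Synthesize SILVA-style metadata for a simulated alignment
#'
#' In-group records get marine water-column isolation sources, uncultured
#' clone organism names, empty strains, above-threshold quality scores and
#' the configured domain. A `contaminant_fraction` of in-group records
#' instead get one of three defects (cycling): a soil isolation source, a
#' cultivated organism name with a culture-collection strain, or a
#' sub-threshold Pintail score. Outgroup records are cultivated type
#' strains (never selected by mining).
#'
#' @param aln a `ctu_alignment` from [evolve_alignment()].
#' @param params a [sim_params()] object.
#' @param outgroup_ids leaf ids to treat as outgroup.
#' @return the alignment with metadata filled in, plus attribute
#'   `contaminated` (character vector of contaminated ids).
#' @export
synthesize_metadata <- function(aln, params, outgroup_ids = character()) {
  set.seed(derive_seed(params$seed, 3))
  r <- aln$records
  n <- nrow(r)
  is_og <- r$id %in% outgroup_ids
  r$domain <- params$domain
  r$pintail <- runif(n, 80, 100)
  r$seq_quality <- runif(n, 80, 100)
  r$align_quality <- runif(n, 92, 100)
  r$organism_name <- paste0("uncultured marine archaeon clone ", r$id)
  r$strain <- ""
  r$isolation_source <- sample(MARINE_SOURCES, n, replace = TRUE)

  r$organism_name[is_og] <- paste0("Nitrososphaera viennensis strain EN76-",
                                   seq_len(sum(is_og)))
  r$strain[is_og] <- paste0("DSM 2621", seq_len(sum(is_og)))
  r$isolation_source[is_og] <- "garden soil enrichment culture"

  in_idx <- which(!is_og)
  n_cont <- round(params$contaminant_fraction * length(in_idx))
  cont <- sort(sample(in_idx, n_cont))
  types <- rep(names(CONTAMINANT_SPECS), length.out = n_cont)
  for (k in seq_along(cont)) {
    i <- cont[k]
    spec <- CONTAMINANT_SPECS[[types[k]]]
    if (!is.null(spec$source)) r$isolation_source[i] <- spec$source
    if (!is.null(spec$name)) {
      r$organism_name[i] <- spec$name
      r$strain[i] <- spec$strain
    }
    if (!is.null(spec$pintail)) r$pintail[i] <- spec$pintail
  }
  aln$records <- r
  attr(aln, "contaminated") <- r$id[cont]
  aln
}

#' Simulate clade-by-sample counts and an environment table
#'
#' Baseline clade proportions are one symmetric Dirichlet(1) draw shared by
#' all samples; per-sample proportions are over-dispersed around it
#' (Dirichlet with precision `dispersion`; 0 = none). Planted effects:
#' clades of the indicator set get their proportion multiplied by
#' `fold_change` in the target category, and clades of the gradient set by
#' `exp(env_strength * depth_scaled)`, before renormalization. Counts are
#' multinomial at `depth` reads (deterministic rounding when
#' `dispersion = 0`). Environmental variables are uniform over
#' oceanographically plausible ranges; a fraction of cells is set missing
#' (never in `depth`, which carries the planted gradient).
#'
#' @param params a [sim_params()] object.
#' @param clades character vector of clade ids (count-table columns), or a
#'   `ctu_hierarchy` whose order-rank CTU names are used.
#' @param indicator_clades,gradient_clades clade subsets carrying the
#'   planted effects; defaults pick the first and second clade.
#' @param target_category category receiving the indicator enrichment
#'   (default: first category).
#' @return list with `counts` (samples x clades), `env` (data.frame with
#'   `sample`, numeric variables, `biome`, `water_body`) and `truth`
#'   (planted effects).
#' @export
simulate_abundance_env <- function(params, clades,
                                   indicator_clades = NULL,
                                   gradient_clades = NULL,
                                   target_category = NULL) {
  if (inherits(clades, "ctu_hierarchy"))
    clades <- clades$ctus$name[clades$ctus$rank == "Order"]
  stopifnot(length(clades) >= 2)
  if (params$fold_change <= 0) stop2("fold-change must be > 0")
  set.seed(derive_seed(params$seed, 4))
  ncl <- length(clades)
  ns <- params$n_samples
  cats <- rep_len(params$categories, ns)
  target <- target_category %||% params$categories[1]
  indicator_clades <- indicator_clades %||% clades[1]
  gradient_clades <- gradient_clades %||% clades[2]
  samples <- sprintf("sample%03d", seq_len(ns))

  env <- data.frame(
    sample = samples,
    depth = round(runif(ns, 5, 4000), 1),
    temperature = round(runif(ns, -2, 30), 2),
    salinity = round(runif(ns, 30, 40), 2),
    dissolved_oxygen = round(runif(ns, 0, 8), 2),
    chlorophyll_a = round(runif(ns, 0, 10), 2),
    nitrate = round(runif(ns, 0, 40), 2),
    phosphate = round(runif(ns, 0, 3), 3),
    biome = rep_len(c("coastal biome", "oceanic epipelagic biome",
                      "oceanic mesopelagic biome"), ns),
    water_body = cats,
    stringsAsFactors = FALSE)
  if (params$env_missing_rate > 0) {
    for (v in c("temperature", "salinity", "dissolved_oxygen",
                "chlorophyll_a", "nitrate", "phosphate")) {
      miss <- runif(ns) < params$env_missing_rate
      env[[v]][miss] <- NA
    }
  }

  base <- rgamma(ncl, 1); base <- base / sum(base)
  z <- (env$depth - 5) / (4000 - 5)
  counts <- matrix(0, ns, ncl, dimnames = list(samples, clades))
  for (s in seq_len(ns)) {
    p <- base
    if (cats[s] == target)
      p[clades %in% indicator_clades] <-
        p[clades %in% indicator_clades] * params$fold_change
    p[clades %in% gradient_clades] <-
      p[clades %in% gradient_clades] * exp(params$env_strength * z[s])
    p <- p / sum(p)
    if (params$dispersion > 0) {
      p <- rgamma(ncl, shape = params$dispersion * p)
      p <- p / sum(p)
      counts[s, ] <- as.vector(rmultinom(1, params$depth, p))
    } else {
      counts[s, ] <- round(params$depth * p)
    }
  }
  truth <- data.frame(
    effect = c(rep("indicator", length(indicator_clades)),
               rep("gradient", length(gradient_clades))),
    clade = c(indicator_clades, gradient_clades),
    target = c(rep(target, length(indicator_clades)),
               rep("depth", length(gradient_clades))),
    value = c(rep(params$fold_change, length(indicator_clades)),
              rep(params$env_strength, length(gradient_clades))),
    stringsAsFactors = FALSE)
  list(counts = counts, env = env, truth = truth)
}

#' Check that realized distances bracket the rank cutoffs
#'
#' The tree plants divergences in expectation; finite sequences add
#' binomial sampling noise, and complete linkage reacts to the extreme
#' realized pairwise distance, not the mean. This check verifies, per
#' fixture, that the realized distance distribution brackets the genus,
#' family and order cutoffs: max within-taxon distance below the cutoff
#' and min between-taxon distance above it, with a small `guard` band
#' absorbing mask differences between the full and the mined sequence
#' sets. Bundles enforce this invariant (see [make_fixture_bundle()]).
#'
#' @param dmat percent-distance matrix over in-group ids.
#' @param truth data.frame with `id`, `Genus`, `Family`, `Order`.
#' @param thresholds a [rank_thresholds()] object.
#' @param guard guard band in percentage points.
#' @return logical; attribute `details` has per-rank realized extremes.
#' @export
check_realized_margins <- function(dmat, truth,
                                   thresholds = rank_thresholds(),
                                   guard = 0.25) {
  cut <- attr(thresholds, "cutoffs")
  ids <- intersect(rownames(dmat), truth$id)
  d <- dmat[ids, ids]
  details <- list()
  ok <- TRUE
  for (rk in c("Genus", "Family", "Order")) {
    lab <- truth[[rk]][match(ids, truth$id)]
    same <- outer(lab, lab, "==")
    diag(same) <- NA
    within_max <- max(d[same & !is.na(same)])
    between_min <- min(d[!same & !is.na(same)])
    pass <- within_max < cut[rk] - guard && between_min > cut[rk] + guard
    details[[rk]] <- c(cutoff = unname(cut[rk]), within_max = within_max,
                       between_min = between_min, pass = pass)
    ok <- ok && pass
  }
  structure(ok, details = details)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates and writes every pipeline input with ground truth:
#' `alignment.fasta` + `metadata.tsv`, `tree.nwk` + `outgroup.txt`,
#' `known_annotations.tsv` (leaves of `params$known_orders`, labeled
#' `KnownClade<k>`), `counts.tsv` (samples x planted genera),
#' `env.tsv`, `lineage_map.tsv` (genus -> planted lineage, standing in for
#' an amplicon classifier's taxonomy), `truth_lineages.tsv`,
#' `truth_ecology.tsv` and `params.R` (dput of the parameters). Bundles
#' are byte-identical across runs with the same parameters and seed.
#'
#' Each bundle satisfies the realized-margin invariant
#' ([check_realized_margins()]): if sampling noise pushes an extreme
#' realized distance across a rank cutoff, the tree/alignment pair is
#' regenerated from the next derived seed (deterministically, so the
#' bundle is still a pure function of `params`); the attempt number is
#' recorded in `realized_margins.tsv`.
#'
#' @param params a [sim_params()] object.
#' @param out_dir directory to write into (created).
#' @param max_attempts regeneration attempts before giving up (per-attempt pass
#'   rate is roughly 25% under the smoke defaults, so 60 makes exhaustion
#'   vanishingly unlikely).
#' @return list with all generated objects and `dir`, invisibly.
#' @export
make_fixture_bundle <- function(params, out_dir, max_attempts = 60L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tree <- aln <- truth <- margins <- NULL
  for (attempt in seq_len(max_attempts)) {
    p2 <- params
    p2$seed <- derive_seed(params$seed, attempt - 1L)
    tree <- simulate_tree(p2)
    truth <- attr(tree, "truth")
    aln <- evolve_alignment(tree, p2)
    aln <- synthesize_metadata(aln, p2, tree$outgroup)
    ing <- aln
    ing$records <- ing$records[!ing$records$id %in% tree$outgroup, ,
                               drop = FALSE]
    dmat <- pairwise_identity_matrix(ing, build_conservation_mask(ing))
    margins <- check_realized_margins(dmat, truth)
    if (margins) break
  }
  if (!margins)
    stop2("could not realize planted margins in ", max_attempts,
          " attempts; widen the planted divergences")
  det <- do.call(rbind, attr(margins, "details"))
  margins_df <- data.frame(rank = rownames(det), det, attempt = attempt,
                           row.names = NULL)
  write.table(margins_df, file.path(out_dir, "realized_margins.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  genera <- unique(truth$Genus)
  eco <- simulate_abundance_env(
    params, clades = genera,
    indicator_clades = truth$Genus[truth$Order == "TrueOrder1"],
    gradient_clades = truth$Genus[truth$Order == "TrueOrder2"])

  write_alignment_fasta(aln, file.path(out_dir, "alignment.fasta"),
                        file.path(out_dir, "metadata.tsv"))
  write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
  writeLines(tree$outgroup, file.path(out_dir, "outgroup.txt"))

  ann <- data.frame(id = character(), label = character())
  if (length(params$known_orders)) {
    for (k in params$known_orders) {
      ids <- truth$id[truth$Order == paste0("TrueOrder", k)]
      ann <- rbind(ann, data.frame(id = ids,
                                   label = paste0("KnownClade", k)))
    }
  }
  write.table(ann, file.path(out_dir, "known_annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  counts_df <- data.frame(sample = rownames(eco$counts), eco$counts,
                          check.names = FALSE)
  write.table(counts_df, file.path(out_dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(eco$env, file.path(out_dir, "env.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  lineage_map <- unique(truth[, c("Genus", "Family", "Order")])
  names(lineage_map)[1] <- "id"
  write.table(lineage_map, file.path(out_dir, "lineage_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tl <- truth
  tl$contaminated <- tl$id %in% attr(aln, "contaminated")
  write.table(tl, file.path(out_dir, "truth_lineages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(eco$truth, file.path(out_dir, "truth_ecology.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(deparse(unclass(params)), file.path(out_dir, "params.R"))

  invisible(list(dir = out_dir, tree = tree, alignment = aln,
                 truth = tl, ecology = eco))
}
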
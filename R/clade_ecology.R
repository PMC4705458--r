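## Clade-by-sample ecology: relative-abundance aggregation at a chosen
## rank, min-max scaled biome/water-body summaries, one-sided permutation
## site-association tests, and Spearman correlation screens against
## environmental gradients.

#' Aggregate counts to relative abundance at a taxonomic rank
#'
#' Sums the clade-by-sample counts within each rank-level clade of the
#' lineage map and divides by each sample's total classified reads.
#' Count-table clades missing from the map (or mapped to `NA`) contribute
#' to the unclassified remainder, so per-sample fractions sum to <= 1.
#' Samples with zero total reads are excluded with a warning.
#'
#' @param counts integer matrix, samples x clades (e.g. genus-level ids).
#' @param lineage_map data.frame with column `id` (matching count columns)
#'   plus rank columns `Phylum` ... `Genus` (as from [ctu_lineages()]), or
#'   a named character vector id -> rank-level clade.
#' @param rank which rank column to aggregate to (default `"Order"`, the
#'   rank used for all downstream analyses).
#' @return an `abundance_table`: list with `rel` (numeric matrix, samples x
#'   rank clades, fractions), `unclassified` (per-sample fraction),
#'   `totals` (classified reads per sample) and `rank`.
#' @export
aggregate_relative_abundance <- function(counts, lineage_map,
                                         rank = "Order") {
  if (is.data.frame(lineage_map)) {
    if (!all(c("id", rank) %in% names(lineage_map)))
      stop2("lineage map needs columns 'id' and '", rank, "'")
    lineage_map <- stats::setNames(lineage_map[[rank]], lineage_map$id)
  }
  totals <- rowSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warn2("excluding ", sum(empty), " sample(s) with zero reads: ",
          paste(head(rownames(counts)[empty], 5), collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
    totals <- totals[!empty]
  }
  grp <- unname(lineage_map[colnames(counts)])
  grp[is.na(grp)] <- "unclassified"
  clades <- sort(setdiff(unique(grp), "unclassified"))
  rel <- vapply(clades, function(cl)
    rowSums(counts[, grp == cl, drop = FALSE]) / totals,
    numeric(nrow(counts)))
  if (!is.matrix(rel)) rel <- matrix(rel, nrow = nrow(counts),
                                     dimnames = list(rownames(counts), clades))
  uncl <- rowSums(counts[, grp == "unclassified", drop = FALSE]) / totals
  structure(list(rel = rel, unclassified = uncl, totals = totals,
                 rank = rank),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$rel), "samples x", ncol(x$rel),
      x$rank, "clades\n")
  invisible(x)
}

#' Min-max scaled mean abundances per sample category
#'
#' Mean relative abundance per (clade, category), then min-max scaled to
#' \[0, 1\] so that 0 is the minimum and 1 the maximum mean abundance —
#' either over the whole table (`scope = "all"`, bubble-plot style) or
#' within each phylum (`scope = "per_phylum"`, so one phylum's scaling is
#' unaffected by another's). Rows with constant means map to 0. Categories
#' with no samples are omitted.
#'
#' @param abundance an `abundance_table`.
#' @param groups character vector of category labels named by (or aligned
#'   with) sample ids.
#' @param scope `"all"` or `"per_phylum"`.
#' @param phylum_of for `scope = "per_phylum"`: named character vector
#'   clade -> phylum.
#' @return list with `means` and `scaled` (clade x category matrices).
#' @export
scaled_summary <- function(abundance, groups, scope = c("all", "per_phylum"),
                           phylum_of = NULL) {
  scope <- match.arg(scope)
  rel <- abundance$rel
  if (!is.null(names(groups))) groups <- groups[rownames(rel)]
  groups <- as.character(groups)
  keep <- !is.na(groups)
  rel <- rel[keep, , drop = FALSE]
  groups <- groups[keep]
  cats <- sort(unique(groups))
  means <- vapply(cats, function(g)
    colMeans(rel[groups == g, , drop = FALSE]), numeric(ncol(rel)))
  if (!is.matrix(means))
    means <- matrix(means, ncol = length(cats),
                    dimnames = list(colnames(rel), cats))
  minmax <- function(m) {
    lo <- min(m); hi <- max(m)
    if (hi == lo) return(m * 0)
    (m - lo) / (hi - lo)
  }
  if (scope == "all") {
    scaled <- minmax(means)
  } else {
    if (is.null(phylum_of)) stop2("per_phylum scope needs phylum_of")
    scaled <- means
    for (ph in unique(phylum_of[rownames(means)])) {
      rows <- which(phylum_of[rownames(means)] == ph)
      scaled[rows, ] <- minmax(means[rows, , drop = FALSE])
    }
  }
  list(means = means, scaled = scaled)
}

#' One-sided permutation site-association test
#'
#' For each clade and each sample category, tests the null hypothesis that
#' the clade's relative abundance is not higher in the target category
#' than in the other samples. The statistic is the difference between the
#' mean relative abundance in the target category and in all other
#' samples; the null distribution comes from `n_perm` random permutations
#' of the category labels (shared across clades and categories within one
#' call, so a fixed seed reproduces every p-value exactly), and the
#' one-sided p-value is `(1 + #\{permuted >= observed\}) / (n_perm + 1)`.
#' A clade absent from all samples gets statistic 0 and p = 1.
#'
#' @param abundance an `abundance_table` (or a plain samples x clades
#'   matrix of fractions).
#' @param groups category labels, named by or aligned with sample ids; at
#'   least 2 categories.
#' @param n_perm number of label permutations.
#' @param seed integer RNG seed.
#' @param statistic `"mean_diff"` (default, matching the null above) or
#'   `"indval"`, an indicator-value style statistic `sqrt(A * B)` where A
#'   is the specificity (share of the clade's total mean abundance in the
#'   target category) and B the fidelity (share of target samples
#'   occupied).
#' @return data.frame, one row per (clade, category): `clade`, `category`,
#'   `statistic`, `p_value`, `n_perm`, `seed`, plus `best` flagging each
#'   clade's best-supported category.
#' @export
site_association_test <- function(abundance, groups, n_perm = 999,
                                  seed = 1L,
                                  statistic = c("mean_diff", "indval")) {
  statistic <- match.arg(statistic)
  rel <- if (inherits(abundance, "abundance_table")) abundance$rel
         else as.matrix(abundance)
  if (!is.null(names(groups))) groups <- groups[rownames(rel)]
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(rel), !anyNA(groups))
  cats <- sort(unique(groups))
  if (length(cats) < 2) stop2("need >= 2 categories")
  n <- nrow(rel)

  if (statistic == "mean_diff") {
    # stat(clade, cat) = w_cat' rel: one matrix product per permutation
    W <- vapply(cats, function(cc) {
      inb <- groups == cc
      ifelse(inb, 1 / sum(inb), -1 / sum(!inb))
    }, numeric(n))
    stat_fun <- function(ord) crossprod(rel, W[ord, , drop = FALSE])
  } else {
    stat_fun <- function(ord) {
      g <- groups[ord]  # labels permuted over samples
      vapply(cats, function(cc) {
        inb <- g == cc
        a_num <- colMeans(rel[inb, , drop = FALSE])
        a_den <- a_num + colMeans(rel[!inb, , drop = FALSE])
        a <- ifelse(a_den > 0, a_num / a_den, 0)
        b <- colMeans(rel[inb, , drop = FALSE] > 0)
        sqrt(a * b)
      }, numeric(ncol(rel))) |>
        matrix(nrow = ncol(rel), ncol = length(cats))
    }
  }
  obs <- stat_fun(seq_len(n))  # clades x categories
  set.seed(seed)
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  for (b in seq_len(n_perm))
    exceed <- exceed + (stat_fun(sample.int(n)) >= obs - 1e-12)
  p <- (1 + exceed) / (n_perm + 1)
  # absent clades: statistic 0, p 1 by convention
  absent <- colSums(rel) == 0
  obs[absent, ] <- 0
  p[absent, ] <- 1

  out <- data.frame(
    clade = rep(colnames(rel), times = length(cats)),
    category = rep(cats, each = ncol(rel)),
    statistic = as.vector(obs), p_value = as.vector(p),
    n_perm = n_perm, seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  best <- stats::ave(seq_len(nrow(out)), out$clade, FUN = function(i)
    i == i[order(out$p_value[i], -out$statistic[i])[1]])
  out$best <- best == 1
  out
}

#' Spearman correlation screen against environmental variables
#'
#' Spearman rank correlation (midranks for ties; equivalently Pearson on
#' average ranks) between each clade's relative abundance and each numeric
#' environmental variable, with missing values excluded pairwise. The
#' p-value uses the t-distribution approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (two-sided). Pairs with fewer than 3 complete observations or zero
#' variance are skipped with a reason. Results with p below `alpha` are
#' flagged `reported`, mirroring a "only correlations with p < 0.05 are
#' shown" display rule; optional Benjamini-Hochberg adjustment.
#'
#' @param abundance an `abundance_table` or samples x clades matrix.
#' @param env data.frame with a `sample` column (or rownames) and numeric
#'   environmental columns.
#' @param variables which env columns to screen; default all numeric ones.
#' @param alpha reporting threshold on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `clade`, `variable`, `rho`, `p_value`, `n`,
#'   `reported`, `skipped_reason`.
#' @export
spearman_screen <- function(abundance, env, variables = NULL, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rel <- if (inherits(abundance, "abundance_table")) abundance$rel
         else as.matrix(abundance)
  if ("sample" %in% names(env)) {
    rownames(env) <- env$sample
    env <- env[, setdiff(names(env), "sample"), drop = FALSE]
  }
  env <- env[rownames(rel), , drop = FALSE]
  if (is.null(variables))
    variables <- names(env)[vapply(env, is.numeric, TRUE)]
  rows <- list()
  for (cl in colnames(rel)) for (v in variables) {
    x <- rel[, cl]; y <- env[[v]]
    ok <- !is.na(x) & !is.na(y)
    n_ok <- sum(ok)
    if (n_ok < 3) {
      rows[[length(rows) + 1]] <- data.frame(
        clade = cl, variable = v, rho = NA_real_, p_value = NA_real_,
        n = n_ok, skipped_reason = "fewer than 3 complete pairs")
      next
    }
    rx <- rank(x[ok]); ry <- rank(y[ok])
    if (stats::var(rx) == 0 || stats::var(ry) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        clade = cl, variable = v, rho = NA_real_, p_value = NA_real_,
        n = n_ok, skipped_reason = "zero variance")
      next
    }
    rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n_ok - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n_ok - 2)
    }
    rows[[length(rows) + 1]] <- data.frame(
      clade = cl, variable = v, rho = rho, p_value = p, n = n_ok,
      skipped_reason = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") {
    keep <- !is.na(out$p_value)
    out$p_adjusted <- NA_real_
    out$p_adjusted[keep] <- stats::p.adjust(out$p_value[keep], "BH")
    out$reported <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  } else {
    out$reported <- !is.na(out$p_value) & out$p_value < alpha
  }
  out
}
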
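## Domain types and readers/writers for the formats the pipeline touches:
## aligned FASTA + sidecar metadata TSV, Newick trees with a designated
## outgroup, clade-by-sample count tables and per-sample environment tables.

RANKS <- c("Phylum", "Class", "Order", "Family", "Genus")

METADATA_COLS <- c("id", "organism_name", "strain", "isolation_source",
                   "pintail", "seq_quality", "align_quality", "domain")

#' Rank-specific sequence identity thresholds
#'
#' The percent-identity thresholds delineating each taxonomic rank under
#' furthest-neighbor clustering: 75% (phylum), 78.5% (class), 82% (order),
#' 86.5% (family) and 94.5% (genus). The corresponding distance cutoffs are
#' `100 - identity`.
#'
#' @param identity named numeric vector of percent identities, ordered
#'   Phylum, Class, Order, Family, Genus. Must be strictly increasing and in
#'   (0, 100).
#' @return an object of class `rank_thresholds`: a named numeric vector of
#'   identities with attribute `cutoffs` (percent distance).
#' @examples
#' rank_thresholds()
#' attr(rank_thresholds(), "cutoffs")["Genus"]  # 5.5
#' @export
rank_thresholds <- function(identity = c(Phylum = 75, Class = 78.5,
                                         Order = 82, Family = 86.5,
                                         Genus = 94.5)) {
  if (!identical(names(identity), RANKS))
    stop2("thresholds must be named ", paste(RANKS, collapse = ", "),
          " in that order")
  if (any(diff(identity) <= 0))
    stop2("identity thresholds must be strictly increasing from Phylum to Genus")
  if (any(identity <= 0 | identity >= 100))
    stop2("identity thresholds must lie in (0, 100)")
  structure(identity, cutoffs = 100 - identity, class = "rank_thresholds")
}

## ---- Alignment ------------------------------------------------------------

new_alignment <- function(records) {
  lens <- nchar(records$aligned_seq)
  if (length(unique(lens)) > 1) {
    bad <- records$id[which(lens != lens[1])[1]]
    stop2("ragged alignment: sequence '", bad, "' has length ",
          lens[lens != lens[1]][1], ", expected ", lens[1])
  }
  if (anyDuplicated(records$id))
    stop2("duplicate sequence id: '", records$id[duplicated(records$id)][1], "'")
  ungapped <- nchar(gsub("[-.]", "", records$aligned_seq))
  if (any(ungapped < 1))
    stop2("sequence '", records$id[ungapped < 1][1], "' has no bases")
  structure(list(records = records, n_columns = lens[1]),
            class = "ctu_alignment")
}

#' @export
print.ctu_alignment <- function(x, ...) {
  cat("ctu_alignment:", nrow(x$records), "sequences x", x$n_columns,
      "columns\n")
  invisible(x)
}

#' Number of sequences / alignment columns
#' @param aln a `ctu_alignment`.
#' @return integer.
#' @export
n_records <- function(aln) nrow(aln$records)

#' Alignment as a character matrix
#'
#' One row per record, one column per alignment position, uppercase, with
#' U mapped to T and '.' gaps normalized to '-'.
#'
#' @param aln a `ctu_alignment`.
#' @return character matrix with rownames set to record ids.
#' @export
alignment_matrix <- function(aln) {
  s <- toupper(aln$records$aligned_seq)
  s <- chartr("U.", "T-", s)
  m <- matrix(unlist(strsplit(s, ""), use.names = FALSE),
              nrow = nrow(aln$records), byrow = TRUE)
  rownames(m) <- aln$records$id
  m
}

#' Read an aligned FASTA with a sidecar metadata table
#'
#' SILVA-style export: sequences in (gapped) FASTA, metadata in a
#' tab-separated file keyed by sequence id with columns `id`,
#' `organism_name`, `strain`, `isolation_source`, `pintail`, `seq_quality`,
#' `align_quality`, `domain`. Records without metadata are kept with
#' missing (`NA`) quality fields, which later fail the quality filter.
#'
#' @param path FASTA file of aligned sequences (gap characters `-` or `.`).
#' @param metadata_path tab-separated metadata file; `NULL` for none.
#' @return a `ctu_alignment`.
#' @export
read_alignment_fasta <- function(path, metadata_path = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  records <- data.frame(
    id = ids, organism_name = "", strain = "", isolation_source = "",
    pintail = NA_real_, seq_quality = NA_real_, align_quality = NA_real_,
    domain = NA_character_, aligned_seq = as.character(seqs),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  if (!is.null(metadata_path)) {
    md <- read.delim(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character", na.strings = c("NA", ""))
    missing_cols <- setdiff(METADATA_COLS, names(md))
    if (length(missing_cols))
      stop2("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
    orphans <- setdiff(md$id, ids)
    if (length(orphans)) {
      warn2("metadata ids absent from FASTA, skipped: ",
            paste(head(orphans, 5), collapse = ", "))
      md <- md[md$id %in% ids, , drop = FALSE]
    }
    idx <- match(records$id, md$id)
    hit <- !is.na(idx)
    for (col in c("organism_name", "strain", "isolation_source", "domain"))
      records[[col]][hit] <- ifelse(is.na(md[[col]][idx[hit]]), "",
                                    md[[col]][idx[hit]])
    for (col in c("pintail", "seq_quality", "align_quality"))
      records[[col]][hit] <- suppressWarnings(as.numeric(md[[col]][idx[hit]]))
    records$domain[records$domain == ""] <- NA_character_
    for (col in c("pintail", "seq_quality", "align_quality")) {
      bad <- !is.na(records[[col]]) &
        (records[[col]] < 0 | records[[col]] > 100)
      if (any(bad))
        stop2(col, " outside [0, 100] for id '", records$id[bad][1], "'")
    }
  }
  new_alignment(records)
}

#' Write an alignment (FASTA + metadata TSV)
#'
#' Inverse of [read_alignment_fasta()]; round-trips all record fields.
#'
#' @param aln a `ctu_alignment`.
#' @param path output FASTA path.
#' @param metadata_path output metadata TSV path; `NULL` to skip.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path, metadata_path = NULL) {
  out <- Biostrings::BStringSet(aln$records$aligned_seq)
  names(out) <- aln$records$id
  Biostrings::writeXStringSet(out, path, width = 80L)
  if (!is.null(metadata_path)) {
    md <- aln$records[, METADATA_COLS]
    write.table(md, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

## ---- Tree -----------------------------------------------------------------

#' Read a Newick tree with a designated outgroup
#'
#' Parses a Newick file (branch lengths and polytomies preserved, support
#' values carried if present) and flags the given leaves as the outgroup.
#' The outgroup is used by [root_with_outgroup()] and its members are
#' excluded from all CTU membership downstream.
#'
#' @param path Newick file.
#' @param outgroup_ids character vector of leaf labels; must all be leaves.
#' @return a `ctu_tree`: list with `phy` (an [ape::read.tree()] `phylo`)
#'   and `outgroup`.
#' @export
read_tree_newick <- function(path, outgroup_ids = character()) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    pos <- if (any(depth < 0)) which(depth < 0)[1] else length(depth)
    stop2("unbalanced parentheses in Newick at position ", pos)
  }
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop2("could not parse Newick file: ", path)
  new_ctu_tree(phy, outgroup_ids)
}

new_ctu_tree <- function(phy, outgroup_ids = character()) {
  if (anyDuplicated(phy$tip.label))
    stop2("duplicate leaf labels in tree")
  missing <- setdiff(outgroup_ids, phy$tip.label)
  if (length(missing))
    stop2("outgroup id not a leaf: '", missing[1], "'")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop2("negative branch lengths")
  structure(list(phy = phy, outgroup = as.character(outgroup_ids)),
            class = "ctu_tree")
}

#' @export
print.ctu_tree <- function(x, ...) {
  cat("ctu_tree:", length(x$phy$tip.label), "leaves (",
      length(x$outgroup), "outgroup )\n")
  invisible(x)
}

#' Write a tree to Newick
#' @param tree a `ctu_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree$phy, file = path)
  invisible(path)
}

## ---- Tables ---------------------------------------------------------------

#' Read clade-by-sample counts and the per-sample environment table
#'
#' Both files are rectangular TSVs with a header. The count table has
#' samples in rows (first column `sample`) and clades in columns; the
#' environment table has one row per sample with numeric columns (`depth`,
#' `temperature`, `salinity`, `dissolved_oxygen`, `chlorophyll_a`,
#' `nitrate`, `phosphate`; possibly missing) and categorical columns
#' (`biome`, `water_body`). Missing numeric cells become `NA` and are
#' excluded pairwise by downstream correlations.
#'
#' @param sample_path count TSV.
#' @param env_path environment TSV; `NULL` for none.
#' @return list with `counts` (integer matrix, samples x clades) and `env`
#'   (data.frame or `NULL`).
#' @export
read_tables <- function(sample_path, env_path = NULL) {
  st <- read.delim(sample_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% names(st)) stop2("count table needs a 'sample' column")
  counts <- as.matrix(st[, setdiff(names(st), "sample"), drop = FALSE])
  rownames(counts) <- st$sample
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop2("missing values in count table")
  if (any(counts < 0))
    stop2("negative count for sample '",
          rownames(counts)[which(rowSums(counts < 0) > 0)[1]], "'")
  env <- NULL
  if (!is.null(env_path)) {
    env <- read.delim(env_path, stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
    if (!"sample" %in% names(env)) stop2("environment table needs a 'sample' column")
    missing <- setdiff(rownames(counts), env$sample)
    if (length(missing))
      warn2("samples missing from environment table: ",
            paste(head(missing, 5), collapse = ", "))
  }
  list(counts = counts, env = env)
}

## ---- Output writers -------------------------------------------------------

#' Write pipeline outputs
#'
#' Writes, with deterministic row order (hierarchy preorder, then
#' lexicographic for result tables):
#' * `taxonomy.tsv` — one row per CTU: name, rank, parent, member count,
#'   known/unknown status, semicolon-joined member id list;
#' * `lineages.tsv` — per-leaf `Phylum;Class;Order;Family;Genus` path;
#' * `associations.tsv`, `correlations.tsv` — ecology results, when given.
#'
#' @param hierarchy a `ctu_hierarchy` from [build_hierarchy()] (named).
#' @param results optional list with elements `associations` and/or
#'   `correlations` (data.frames).
#' @param out_dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_outputs <- function(hierarchy, results = list(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop2("cannot create output directory: ", out_dir)
  files <- character()

  ct <- hierarchy$ctus
  tax <- data.frame(
    name = ct$name, rank = ct$rank, parent = ct$parent,
    n_members = vapply(ct$members, length, 1L),
    status = ct$status,
    members = vapply(ct$members, function(m) paste(m, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  f <- file.path(out_dir, "taxonomy.tsv")
  write.table(tax, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  lin <- ctu_lineages(hierarchy)
  f <- file.path(out_dir, "lineages.tsv")
  write.table(lin[order(lin$id), ], f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)

  for (nm in c("associations", "correlations")) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    res <- results[[nm]]
    if (is.null(res))
      res <- data.frame()
    if (nrow(res))
      res <- res[do.call(order, unname(res[, 1:2, drop = FALSE])), ,
                 drop = FALSE]
    write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Per-leaf lineage table
#'
#' @param hierarchy a named `ctu_hierarchy`.
#' @return data.frame with columns `id`, `Phylum` ... `Genus`, `lineage`
#'   (semicolon-joined five-rank path), one row per in-group leaf.
#' @export
ctu_lineages <- function(hierarchy) {
  leaves <- hierarchy$leaves
  out <- data.frame(id = leaves, stringsAsFactors = FALSE)
  for (rk in RANKS) {
    sub <- hierarchy$ctus[hierarchy$ctus$rank == rk, , drop = FALSE]
    v <- rep(NA_character_, length(leaves))
    for (i in seq_len(nrow(sub)))
      v[match(sub$members[[i]], leaves)] <- sub$name[i]
    out[[rk]] <- v
  }
  out$lineage <- do.call(paste, c(out[RANKS], sep = ";"))
  out
}
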
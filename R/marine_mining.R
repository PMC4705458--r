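## Marine water-column sequence mining: keyword classification of isolation
## sources, detection of environmental (uncultivated) records, quality and
## length filters, and the >= 50% marine clade-inclusion rule applied to
## guide-tree clades.

#' Default keyword rule set for isolation-source mining
#'
#' The published pipeline used a complex keyword expression over SILVA
#' isolation-source fields that is not publicly reproduced; this editable
#' default vocabulary stands in for it and is what the synthetic-data
#' generator draws from, making mining self-consistent on fixtures.
#' Patterns are case-insensitive regular expressions, matched in the order
#' exclusion, then marine water column, then other marine.
#'
#' @param marine_water_column,other_marine,exclusion,environmental_name,clone_strain
#'   character vectors of patterns overriding the defaults.
#' @return a `keyword_rules` list with those five elements.
#' @export
default_keyword_rules <- function(
    marine_water_column = c("seawater", "sea water", "water column",
                            "ocean(ic)? water", "pelagic", "bathypelagic",
                            "mesopelagic", "epipelagic", "brine",
                            "marine water", "open ocean"),
    other_marine = c("marine sediment", "hydrothermal vent", "sediment",
                     "sponge", "coral", "microbial mat", "vent fluid",
                     "cold seep"),
    exclusion = c("soil", "freshwater", "fresh water", "lake", "river",
                  "gut", "feces", "faeces", "sludge", "rhizosphere",
                  "compost", "wastewater"),
    environmental_name = c("uncultured", "unidentified", "environmental",
                           "clone"),
    clone_strain = c("^clone\\b", "^cl[._-]", "^env[._-]")) {
  rules <- list(marine_water_column = marine_water_column,
                other_marine = other_marine,
                exclusion = exclusion,
                environmental_name = environmental_name,
                clone_strain = clone_strain)
  for (nm in names(rules)) {
    if (!length(rules[[nm]])) stop2("rule list '", nm, "' is empty")
    for (p in rules[[nm]])  # each pattern must compile
      tryCatch(grepl(p, "", ignore.case = TRUE),
               error = function(e) stop2("bad pattern in '", nm, "': ", p))
  }
  structure(rules, class = "keyword_rules")
}

#' Classify an isolation-source string
#'
#' Total, deterministic classification of free-text isolation sources into
#' `marine_water_column`, `other_marine` or `non_marine`. Exclusion
#' patterns take precedence (so "agricultural soil" never matches a marine
#' keyword embedded in it), then marine water column, then other marine;
#' no match, `NA` or empty text yields `non_marine`.
#'
#' @param text character vector of isolation sources.
#' @param rules a `keyword_rules` list, see [default_keyword_rules()].
#' @return character vector over the three classes.
#' @export
classify_isolation_source <- function(text, rules = default_keyword_rules()) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  hit <- function(patterns)
    Reduce(`|`, lapply(patterns, grepl, x = text, ignore.case = TRUE))
  out <- rep("non_marine", length(text))
  mwc <- hit(rules$marine_water_column)
  om  <- hit(rules$other_marine)
  excl <- hit(rules$exclusion)
  out[om] <- "other_marine"
  out[mwc] <- "marine_water_column"
  out[excl | text == ""] <- "non_marine"
  out
}

#' Flag environmental (uncultivated-origin) records
#'
#' A record is environmental iff its organism name matches an
#' environmental-name pattern (e.g. "uncultured", "clone") AND its strain
#' field is empty or looks like a clone identifier. A culture-collection
#' strain (e.g. "DSM 1234") overrides an environmental-looking name.
#'
#' @param organism_name,strain character vectors (recycled to equal length).
#' @param rules a `keyword_rules` list.
#' @return logical vector.
#' @export
flag_environmental <- function(organism_name, strain = "",
                               rules = default_keyword_rules()) {
  n <- max(length(organism_name), length(strain))
  organism_name <- rep_len(as.character(organism_name), n)
  strain <- rep_len(as.character(strain), n)
  strain[is.na(strain)] <- ""
  name_env <- Reduce(`|`, lapply(rules$environmental_name, grepl,
                                 x = organism_name, ignore.case = TRUE))
  strain_ok <- strain == "" |
    Reduce(`|`, lapply(rules$clone_strain, grepl, x = strain,
                       ignore.case = TRUE))
  name_env & strain_ok
}

#' Apply sequence quality and length filters
#'
#' Per-record pass/fail against the pipeline's vetting criteria: Pintail
#' >= 75, sequence quality >= 75, alignment quality >= 90 (inclusive, as
#' "minimum of" thresholds), and ungapped length strictly greater than
#' 1200 bp for Bacteria / 900 bp for Archaea. Missing quality values fail
#' (only vetted sequences are retained); an unknown domain fails the length
#' criterion with reason "unknown domain".
#'
#' @param aln a `ctu_alignment`.
#' @param min_pintail,min_seq_quality,min_align_quality inclusive quality
#'   thresholds.
#' @param min_len_bacteria,min_len_archaea exclusive ungapped-length
#'   thresholds per domain.
#' @param rules a `keyword_rules` list used for the source and
#'   environmental columns of the report.
#' @return a `filter_report` data.frame with one row per record: `id`,
#'   `source_class`, `environmental`, `pass_pintail`, `pass_seq_quality`,
#'   `pass_align_quality`, `pass_length`, `reason`, `pass` (all criteria
#'   AND environmental AND not non-marine).
#' @export
apply_quality_filters <- function(aln, min_pintail = 75,
                                  min_seq_quality = 75,
                                  min_align_quality = 90,
                                  min_len_bacteria = 1200,
                                  min_len_archaea = 900,
                                  rules = default_keyword_rules()) {
  r <- aln$records
  ge <- function(x, thr) !is.na(x) & x >= thr
  ungapped <- nchar(gsub("[-.]", "", r$aligned_seq))
  min_len <- ifelse(is.na(r$domain), NA_real_,
                    ifelse(r$domain == "Bacteria", min_len_bacteria,
                           ifelse(r$domain == "Archaea", min_len_archaea,
                                  NA_real_)))
  pass_len <- !is.na(min_len) & ungapped > min_len
  rep <- data.frame(
    id = r$id,
    source_class = classify_isolation_source(r$isolation_source, rules),
    environmental = flag_environmental(r$organism_name, r$strain, rules),
    pass_pintail = ge(r$pintail, min_pintail),
    pass_seq_quality = ge(r$seq_quality, min_seq_quality),
    pass_align_quality = ge(r$align_quality, min_align_quality),
    pass_length = pass_len,
    reason = ifelse(is.na(min_len), "unknown domain", ""),
    stringsAsFactors = FALSE
  )
  rep$pass <- rep$pass_pintail & rep$pass_seq_quality &
    rep$pass_align_quality & rep$pass_length & rep$environmental &
    rep$source_class != "non_marine"
  class(rep) <- c("filter_report", class(rep))
  rep
}

#' Select whole guide-tree clades for tree reconstruction
#'
#' Applies the marine clade-inclusion rule to a prior partition of records
#' into guide-tree clades: a clade is selected entirely iff at least 50% of
#' its members are classified `marine_water_column` AND every remaining
#' member is `other_marine` (a clade mixed with any `non_marine` member is
#' dropped). The returned ids are the union of selected clades minus
#' records failing the quality/environmental filters. Records absent from
#' every prior clade are treated as singleton clades. The 50% denominator
#' is all clade members, before quality filtering.
#'
#' @param prior_clades named list of character vectors of record ids (the
#'   guide-tree clades); need not cover all records.
#' @param report a `filter_report` from [apply_quality_filters()].
#' @return list with `selected_ids` (character) and `clades` (data.frame of
#'   per-clade fractions and verdicts).
#' @export
select_clades_for_trees <- function(prior_clades, report) {
  assigned <- unlist(prior_clades, use.names = FALSE)
  if (anyDuplicated(assigned))
    stop2("prior clades are not disjoint: '",
          assigned[duplicated(assigned)][1], "'")
  singletons <- setdiff(report$id, assigned)
  clades <- c(prior_clades,
              stats::setNames(as.list(singletons), singletons))
  src <- stats::setNames(report$source_class, report$id)
  pass <- stats::setNames(report$pass, report$id)
  info <- do.call(rbind, lapply(names(clades), function(nm) {
    ids <- clades[[nm]]
    cls <- src[ids]
    cls[is.na(cls)] <- "non_marine"  # records unknown to the report
    frac <- mean(cls == "marine_water_column")
    data.frame(clade = nm, n = length(ids),
               marine_fraction = frac,
               has_non_marine = any(cls == "non_marine"),
               selected = frac >= 0.5 && !any(cls == "non_marine"),
               stringsAsFactors = FALSE)
  }))
  sel_clades <- info$clade[info$selected]
  sel_ids <- unlist(clades[sel_clades], use.names = FALSE)
  sel_ids <- sel_ids[!is.na(pass[sel_ids]) & pass[sel_ids]]
  list(selected_ids = sort(sel_ids), clades = info)
}
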
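#' Read one miRNA-target interaction table
#'
#' Reads a tab- or comma-delimited table of miRNA-target interactions from one
#' evidence source (e.g. an export of a curated interaction database) into a
#' catalog fragment. Rows with an empty miRNA or target identifier are dropped
#' and counted; duplicated (miRNA, target) rows are collapsed and counted.
#'
#' @param path Path to a delimited text file.
#' @param target_class `"mRNA"` or `"lncRNA"`: the class of the target column.
#' @param source_label Evidence-source label attached to every edge.
#' @param mirna_col,target_col Column names holding the miRNA and target
#'   identifiers (the "dialect" of the file).
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.csv` comma, otherwise tab).
#' @return A tibble with columns `mirna_id`, `target_id`, `target_class`,
#'   `sources`, carrying a `load_report` attribute (see [load_report()]).
#' @seealso [harmonize_and_merge()]
#' @export
read_interaction_table <- function(path, target_class = c("mRNA", "lncRNA"),
                                   source_label,
                                   mirna_col = "mirna", target_col = "target",
                                   delim = NULL) {
  target_class <- match.arg(target_class)
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c(mirna_col, target_col)) {
    if (!col %in% names(raw)) {
      abort(sprintf("Column `%s` is missing from %s.", col, path))
    }
  }
  if (nrow(raw) == 0L) {
    warn(sprintf("Interaction table %s is empty.", path))
  }
  edges <- tibble(
    mirna_id = as.character(raw[[mirna_col]]),
    target_id = as.character(raw[[target_col]])
  )
  blank <- is.na(edges$mirna_id) | is.na(edges$target_id) |
    trimws(edges$mirna_id) == "" | trimws(edges$target_id) == ""
  kept <- edges[!blank, , drop = FALSE]
  deduped <- distinct(kept, .data$mirna_id, .data$target_id)
  out <- mutate(deduped, target_class = target_class, sources = source_label)
  attr(out, "load_report") <- list(
    path = path, source = source_label, rows = nrow(edges),
    dropped_blank = sum(blank), duplicates = nrow(kept) - nrow(deduped)
  )
  out
}

#' Load report of an interaction-table fragment
#'
#' @param fragment A fragment returned by [read_interaction_table()].
#' @return A list with the file path, source label, row count, and the
#'   numbers of blank-dropped and duplicate-collapsed rows.
#' @export
load_report <- function(fragment) attr(fragment, "load_report")

#' Harmonize and merge interaction-catalog fragments
#'
#' Merges fragments from several evidence sources into a single deduplicated
#' interaction catalog. Identifiers are canonicalised (miRNA ids lowercase,
#' gene symbols uppercase), target symbols are optionally mapped through an
#' alias map, and redundant edges are collapsed with their evidence sources
#' unioned. The miRNA background size `N_T` used by the competition test
#' defaults to the number of distinct miRNAs in the merged catalog; pass
#' `n_mirna_universe` to use a genome-wide background instead.
#'
#' @param fragments A list of fragments from [read_interaction_table()], or a
#'   single edge tibble with columns `mirna_id`, `target_id`, `target_class`,
#'   `sources`.
#' @param aliases Optional alias map: a data frame with columns `raw` and
#'   `canonical`, where `canonical = NA` flags an unmappable identifier.
#'   Targets present in the map are renamed; targets flagged unmappable are
#'   excluded and counted; targets absent from the map pass through unchanged.
#'   A raw symbol mapped to two distinct canonical symbols is an error.
#' @param n_mirna_universe Background miRNA count `N_T`; defaults to the
#'   distinct miRNAs observed in the merged catalog.
#' @return An `lcenet_catalog`: a tibble of unique
#'   (`mirna_id`, `target_id`, `target_class`) edges with semicolon-joined
#'   `sources`, plus attributes `n_mirna_universe` and `merge_report`.
#' @export
harmonize_and_merge <- function(fragments, aliases = NULL,
                                n_mirna_universe = NULL) {
  if (is.data.frame(fragments)) fragments <- list(fragments)
  edges <- bind_rows(lapply(fragments, as_tibble))
  required <- c("mirna_id", "target_id", "target_class", "sources")
  if (!all(required %in% names(edges))) {
    abort("Fragments need columns mirna_id, target_id, target_class, sources.")
  }
  edges <- mutate(edges,
    mirna_id = canonical_mirna(.data$mirna_id),
    target_id = canonical_gene(.data$target_id)
  )

  excluded <- 0L
  if (!is.null(aliases)) {
    aliases <- mutate(as_tibble(aliases),
      raw = canonical_gene(.data$raw),
      canonical = if_else(is.na(.data$canonical), NA_character_,
                          canonical_gene(.data$canonical))
    )
    ambiguous <- aliases %>%
      distinct(.data$raw, .data$canonical) %>%
      count(.data$raw) %>%
      filter(.data$n > 1L)
    if (nrow(ambiguous) > 0L) {
      abort(sprintf("Ambiguous alias for: %s",
                    paste(ambiguous$raw, collapse = ", ")))
    }
    edges <- left_join(edges, distinct(aliases), by = c(target_id = "raw"))
    mapped <- !is.na(edges$canonical)
    in_map <- edges$target_id %in% aliases$raw
    excluded <- sum(in_map & !mapped)
    edges <- edges %>%
      filter(!(in_map & !mapped)) %>%
      mutate(target_id = if_else(is.na(.data$canonical), .data$target_id,
                                 .data$canonical)) %>%
      select(-"canonical")
  }

  merged <- edges %>%
    group_by(.data$mirna_id, .data$target_id, .data$target_class) %>%
    summarise(sources = paste_sources(.data$sources), .groups = "drop") %>%
    arrange(.data$mirna_id, .data$target_id)

  both_classes <- merged %>%
    distinct(.data$mirna_id, .data$target_id, .data$target_class) %>%
    count(.data$mirna_id, .data$target_id) %>%
    filter(.data$n > 1L)
  if (nrow(both_classes) > 0L) {
    warn(sprintf(
      "%d pair(s) appear as both mRNA and lncRNA targets; kept in both classes.",
      nrow(both_classes)
    ))
  }

  n_obs <- dplyr::n_distinct(merged$mirna_id)
  n_t <- as.integer(n_mirna_universe %||% n_obs)
  if (n_t < n_obs) {
    abort("`n_mirna_universe` is smaller than the distinct miRNAs observed.")
  }
  new_lcenet_catalog(merged, n_t,
                     report = list(input_edges = nrow(edges),
                                   merged_edges = nrow(merged),
                                   excluded_unmapped = excluded))
}

new_lcenet_catalog <- function(edges, n_mirna_universe, report = NULL) {
  out <- as_tibble(edges)
  attr(out, "n_mirna_universe") <- as.integer(n_mirna_universe)
  attr(out, "merge_report") <- report
  class(out) <- c("lcenet_catalog", class(out))
  out
}

#' Background miRNA universe size of a catalog
#' @param catalog An `lcenet_catalog`.
#' @return Integer `N_T`.
#' @export
mirna_universe_size <- function(catalog) {
  attr(catalog, "n_mirna_universe") %||%
    dplyr::n_distinct(catalog$mirna_id)
}

#' Write / read a merged catalog as TSV
#'
#' The background size is stored in a `# n_mirna_universe:` header comment so
#' a round-trip preserves it.
#' @param catalog An `lcenet_catalog`.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  writeLines(sprintf("# n_mirna_universe: %d", mirna_universe_size(catalog)),
             path)
  readr::write_tsv(catalog, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  header <- readLines(path, n = 1L)
  n_t <- if (grepl("^# n_mirna_universe:", header)) {
    as.integer(sub("^# n_mirna_universe:\\s*", "", header))
  } else {
    NULL
  }
  edges <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  new_lcenet_catalog(edges, n_t %||% dplyr::n_distinct(edges$mirna_id))
}
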
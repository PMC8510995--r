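# Parsing and unification of validated and predicted miRNA-target tables
# (miRTarBase/TarBase-style validated lists, TargetScan/miRDB-style predicted
# lists) into a single provenance-tracked target map.

VALIDATED_SOURCES <- c("mirnet", "mirtarbase", "tarbase")
PREDICTED_SOURCES <- c("targetscan", "mirdb")

#' Normalize miRNA identifiers
#'
#' Database exports and figures mix species prefixes ("mmu-miR-29a-3p" vs
#' "miR-29a-3p"), casing ("Let-7d-5p") and occasionally drop the hyphen after
#' the family token ("miR181d-5p"). This parser strips the species prefix for
#' matching (keeping it as a column), restores canonical casing ("miR-",
#' "let-"), preserves the arm suffix (-3p/-5p), and is idempotent.
#'
#' @param raw Character vector of miRNA names.
#' @return A tibble with columns `raw`, `species` (`NA` if absent) and `core`
#'   (the normalized id used for joins).
#' @export
#' @examples
#' normalize_mirna_id(c("mmu-miR-29a-3p", "Let-7d-5p", "miR181d-5p"))$core
normalize_mirna_id <- function(raw) {
  if (length(raw) == 0) return(tibble(raw = character(), species = character(),
                                      core = character()))
  if (any(is.na(raw) | !nzchar(raw))) {
    abort("miRNA ids must be non-empty strings.", class = "mirlink_parse_error")
  }
  m <- stringr::str_match(
    raw, "^(?:([A-Za-z]{3,4})-)?((?i:mir|let))-?([0-9A-Za-z.\\-]+)$"
  )
  bad <- is.na(m[, 3])
  # a 3-4 letter 'species' capture can swallow 'let'/'mir' themselves
  fam_as_sp <- !is.na(m[, 2]) & tolower(m[, 2]) %in% c("mir", "let")
  if (any(fam_as_sp)) {
    m2 <- stringr::str_match(raw[fam_as_sp],
                             "^((?i:mir|let))-?([0-9A-Za-z.\\-]+)$")
    m[fam_as_sp, 2] <- NA
    m[fam_as_sp, 3] <- m2[, 2]
    m[fam_as_sp, 4] <- m2[, 3]
    bad[fam_as_sp] <- is.na(m2[, 2])
  }
  if (any(bad)) {
    abort(paste0("Unparseable miRNA id(s): ",
                 paste(unique(raw[bad]), collapse = ", ")),
          class = "mirlink_parse_error")
  }
  fam <- ifelse(tolower(m[, 3]) == "let", "let", "miR")
  tibble(raw = raw,
         species = tolower(m[, 2]),
         core = paste0(fam, "-", tolower(m[, 4])))
}

#' Read a miRNA-target table
#'
#' Expects a TSV with header and at least `mirna_id` and `gene_symbol`
#' columns; optional `score`. Evidence is assigned from `source`
#' (targetscan/mirdb are predicted, mirnet/mirtarbase/tarbase validated)
#' unless the file carries its own `evidence` column. Rows with an empty or
#' unparseable miRNA id or empty gene symbol are skipped with a message
#' giving the count; duplicates on (miRNA, gene, source) are dropped.
#'
#' @param path TSV file.
#' @param source One of `r paste(c(VALIDATED_SOURCES, PREDICTED_SOURCES),
#'   collapse = ", ")`; may be omitted if the file has a `source` column.
#' @return Tibble of records: `mirna_id` (normalized core), `species`,
#'   `gene_symbol` (uppercase), `evidence`, `source`, `score`.
#' @export
read_target_table <- function(path, source = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0 && ncol(tbl) == 0) {
    warn(sprintf("Empty target table: %s", path))
    return(tibble(mirna_id = character(), species = character(),
                  gene_symbol = character(), evidence = character(),
                  source = character(), score = numeric()))
  }
  needed <- c("mirna_id", "gene_symbol")
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("Target table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mirlink_format_error")
  }
  if (is.null(source) && !"source" %in% names(tbl)) {
    abort("Provide `source` or include a `source` column.",
          class = "mirlink_format_error")
  }
  src <- if ("source" %in% names(tbl)) tolower(tbl$source) else
    rep(tolower(source), nrow(tbl))
  known <- c(VALIDATED_SOURCES, PREDICTED_SOURCES)
  if (any(!src %in% known)) {
    abort(paste0("Unknown source(s): ",
                 paste(unique(src[!src %in% known]), collapse = ", ")),
          class = "mirlink_format_error")
  }

  ok <- !is.na(tbl$mirna_id) & nzchar(tbl$mirna_id) &
    !is.na(tbl$gene_symbol) & nzchar(tbl$gene_symbol)
  parsed <- tryCatch(normalize_mirna_id(tbl$mirna_id[ok]),
                     mirlink_parse_error = function(e) NULL)
  if (is.null(parsed)) {
    # row-wise fallback so malformed ids are skipped, not fatal
    per <- lapply(tbl$mirna_id[ok], function(id) {
      tryCatch(normalize_mirna_id(id), mirlink_parse_error = function(e) NULL)
    })
    parse_ok <- !vapply(per, is.null, logical(1))
    parsed <- dplyr::bind_rows(per[parse_ok])
    idx <- which(ok)
    ok[idx[!parse_ok]] <- FALSE
  }
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    inform(sprintf("read_target_table: skipped %d malformed row(s) in %s",
                   n_skipped, path))
  }

  out <- tibble(
    mirna_id = parsed$core,
    species = parsed$species,
    gene_symbol = toupper(tbl$gene_symbol[ok]),
    source = src[ok],
    score = if ("score" %in% names(tbl)) as.numeric(tbl$score[ok]) else
      NA_real_
  )
  out$evidence <- if ("evidence" %in% names(tbl)) {
    tolower(tbl$evidence[ok])
  } else {
    ifelse(out$source %in% PREDICTED_SOURCES, "predicted", "validated")
  }
  consistent <- (out$source %in% PREDICTED_SOURCES) ==
    (out$evidence == "predicted")
  if (any(!consistent)) {
    abort("Evidence column inconsistent with source (targetscan/mirdb must be predicted).",
          class = "mirlink_format_error")
  }
  dplyr::distinct(out[, c("mirna_id", "species", "gene_symbol", "evidence",
                          "source", "score")],
                  .data$mirna_id, .data$gene_symbol, .data$source,
                  .keep_all = TRUE)
}

#' Build a unified target map
#'
#' Merges target records from one or more tables into a map with one row per
#' (miRNA, gene) pair. Sources of duplicated pairs are merged
#' (semicolon-joined, sorted); a pair supported by at least one validated
#' source is labelled validated.
#'
#' @param ... Tibbles of records from [read_target_table()].
#' @param species Optional species code (e.g. `"mmu"`); records carrying a
#'   different explicit species prefix are dropped.
#' @return Tibble of class `target_map`: `mirna_id`, `gene_symbol`,
#'   `evidence`, `sources`.
#' @export
build_target_map <- function(..., species = NULL) {
  rec <- dplyr::bind_rows(...)
  if (!is.null(species) && nrow(rec) > 0) {
    rec <- rec[is.na(rec$species) | rec$species == tolower(species), ]
  }
  if (nrow(rec) == 0) {
    out <- tibble(mirna_id = character(), gene_symbol = character(),
                  evidence = character(), sources = character())
    return(structure(out, class = c("target_map", class(out))))
  }
  out <- rec |>
    dplyr::group_by(.data$mirna_id, .data$gene_symbol) |>
    dplyr::summarise(
      evidence = if (any(.data$evidence == "validated")) "validated" else
        "predicted",
      sources = paste(sort(unique(.data$source)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mirna_id, .data$gene_symbol)
  structure(out, class = c("target_map", class(out)))
}

filter_evidence <- function(map, evidence_filter = c("both", "validated",
                                                     "predicted")) {
  evidence_filter <- match.arg(evidence_filter)
  if (evidence_filter == "both") return(map)
  map[map$evidence == evidence_filter, ]
}

#' Union of target genes over a set of miRNAs
#'
#' Collects the distinct target genes of the queried miRNAs (after an
#' optional evidence filter) and reports how many of the queried miRNAs were
#' present in the map at all — mirroring the coverage statement a curated
#' database lookup produces.
#'
#' @param mirnas Character vector of miRNA ids (raw or normalized; normalized
#'   internally).
#' @param map A `target_map` from [build_target_map()].
#' @param evidence_filter `"both"` (default), `"validated"` or `"predicted"`.
#' @return A list of class `target_union`: `genes` (sorted character vector),
#'   `per_mirna` (tibble `mirna_id`, `n_targets`, list-column `targets`),
#'   `n_queried`, `n_present`, `missing`, and a `coverage` string like
#'   `"3 of 5 present"`.
#' @export
union_targets <- function(mirnas, map, evidence_filter = "both") {
  core <- normalize_mirna_id(mirnas)$core
  map <- filter_evidence(map, evidence_filter)
  hit <- map[map$mirna_id %in% core, ]
  per_mirna <- hit |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(n_targets = dplyr::n_distinct(.data$gene_symbol),
                     targets = list(sort(unique(.data$gene_symbol))),
                     .groups = "drop")
  present <- unique(hit$mirna_id)
  structure(list(
    genes = sort(unique(hit$gene_symbol)),
    per_mirna = per_mirna,
    n_queried = length(unique(core)),
    n_present = length(present),
    missing = setdiff(unique(core), present),
    coverage = sprintf("%d of %d present", length(present),
                       length(unique(core)))
  ), class = "target_union")
}

#' @export
print.target_union <- function(x, ...) {
  cat(sprintf("<target_union> %d genes from %s miRNAs (%s)\n",
              length(x$genes), x$n_present, x$coverage))
  invisible(x)
}

#' @export
tidy.target_union <- function(x, ...) x$per_mirna
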
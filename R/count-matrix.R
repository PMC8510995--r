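# Count container shared by the miRNA and mRNA arms of the pipeline.

#' Build a count matrix with sample conditions
#'
#' Bundles an integer feature-by-sample count table with a two-level sample
#' condition map and (optionally) per-feature lengths in base pairs. This is
#' the input container for [size_factors()], [fpkm()], [estimate_dispersion()]
#' and [wald_test()].
#'
#' @param counts A data frame whose first column holds feature ids and whose
#'   remaining columns hold non-negative integer counts (one column per
#'   sample), or an integer matrix with feature row names and sample column
#'   names.
#' @param condition A data frame with columns `sample_id` and `condition`
#'   covering every sample in `counts`; `condition` must take exactly two
#'   values.
#' @param reference The condition label to treat as the reference group.
#'   Defaults to the first level of `factor(condition$condition)`.
#' @param lengths Optional data frame with columns `feature_id` (or `gene_id`)
#'   and `length_bp`, required later for [fpkm()].
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `condition` (named factor, levels
#'   `c(reference, treatment)`), and `lengths_bp` (named numeric or `NULL`).
#' @export
#' @examples
#' cts <- tibble::tibble(feature_id = c("g1", "g2"),
#'                       s1 = c(5L, 10L), s2 = c(7L, 14L))
#' cond <- tibble::tibble(sample_id = c("s1", "s2"),
#'                        condition = c("ctrl", "case"))
#' count_matrix(cts, cond, reference = "ctrl")
count_matrix <- function(counts, condition, reference = NULL, lengths = NULL) {
  if (is.data.frame(counts)) {
    feature_id <- as.character(counts[[1]])
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- feature_id
  } else if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      abort("A count matrix must carry feature row names and sample column names.",
            class = "mirlink_input_error")
    }
  } else {
    abort("`counts` must be a data frame or a matrix.",
          class = "mirlink_input_error")
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    abort("Counts must be non-negative integers with no missing values.",
          class = "mirlink_input_error")
  }

  if (!is.data.frame(condition) ||
      !all(c("sample_id", "condition") %in% names(condition))) {
    abort("`condition` needs columns `sample_id` and `condition`.",
          class = "mirlink_input_error")
  }
  cond <- stats::setNames(as.character(condition$condition),
                          as.character(condition$sample_id))
  missing <- setdiff(colnames(m), names(cond))
  if (length(missing) > 0) {
    abort(paste0("Samples without a condition: ",
                 paste(missing, collapse = ", ")),
          class = "mirlink_input_error")
  }
  cond <- cond[colnames(m)]
  lev <- sort(unique(cond))
  if (length(lev) != 2) {
    abort("Exactly two conditions are required.", class = "mirlink_input_error")
  }
  reference <- reference %||% lev[1]
  if (!reference %in% lev) {
    abort(sprintf("Reference condition '%s' not found among: %s.",
                  reference, paste(lev, collapse = ", ")),
          class = "mirlink_input_error")
  }
  cond <- factor(cond, levels = c(reference, setdiff(lev, reference)))
  if (any(table(cond) == 0)) {
    abort("Both conditions must have at least one sample.",
          class = "mirlink_input_error")
  }

  lengths_bp <- NULL
  if (!is.null(lengths)) {
    if (is.data.frame(lengths)) {
      idcol <- intersect(c("feature_id", "gene_id"), names(lengths))[1]
      if (is.na(idcol) || !"length_bp" %in% names(lengths)) {
        abort("`lengths` needs columns `feature_id`/`gene_id` and `length_bp`.",
              class = "mirlink_input_error")
      }
      lengths_bp <- stats::setNames(as.numeric(lengths$length_bp),
                                    as.character(lengths[[idcol]]))
    } else {
      lengths_bp <- lengths
    }
  }

  structure(list(counts = m, condition = cond, lengths_bp = lengths_bp),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("<count_matrix> %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tidy a count matrix into long form
#'
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `condition`,
#'   `count`.
#' @export
tidy.count_matrix <- function(x, ...) {
  tibble(
    feature_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    condition = rep(as.character(x$condition), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
}

# ---- plain-text readers/writers ---------------------------------------------

#' Read and write pipeline TSV tables
#'
#' `read_counts_tsv()` expects a header line with the feature-id column first
#' and one integer column per sample. `read_condition_tsv()` expects columns
#' `sample_id` and `condition`; `read_lengths_tsv()` expects `gene_id` and
#' `length_bp`. The writers emit the same layouts.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_counts_tsv
#' @export
read_condition_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "condition") %in% names(tbl))) {
    abort("Condition table needs columns `sample_id` and `condition`.",
          class = "mirlink_format_error")
  }
  tbl
}

#' @rdname read_counts_tsv
#' @export
read_lengths_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!any(c("gene_id", "feature_id") %in% names(tbl)) ||
      !"length_bp" %in% names(tbl)) {
    abort("Length table needs columns `gene_id` and `length_bp`.",
          class = "mirlink_format_error")
  }
  tbl
}

#' @rdname read_counts_tsv
#' @param x Table to write.
#' @export
write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
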
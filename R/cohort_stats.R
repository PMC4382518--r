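# Cohort-level 3b.3n statistics over k-turn sequence collections.
#
# Natural k-turn families (e.g. SAM-I riboswitch vs U4 snRNA alignments)
# differ sharply in their 3b.3n composition; these routines tabulate the 16
# ordered pairs across a cohort, summarize rule-engine fractions, and lay
# the counts out along a configurable folding-ability ranking.

#' Read a k-turn cohort from a Stockholm alignment
#'
#' Each alignment row yields a partial k-turn carrying only the bases at the
#' mapped columns.  Rows with a gap at a mapped 3b/3n column are kept and
#' flagged unclassifiable (never silently dropped: cohort percentages depend
#' on the denominator).  Letters outside A/C/G/U/T (IUPAC ambiguity codes)
#' are mapped to N and counted as unclassifiable.
#'
#' @param path Stockholm file (Rfam dialect; multi-block supported).
#' @param column_map named integer vector mapping position labels to 1-based
#'   alignment columns (as displayed by alignment viewers); must include
#'   `3b` and `3n`.
#' @param min_coverage minimum fraction of mapped columns that must be
#'   non-gap for a row to be kept (default 0: no filtering).
#' @return List of `kturn_site` objects (fields `name`, `bases`).
#' @export
read_stockholm_cohort <- function(path, column_map, min_coverage = 0) {
  if (is.null(names(column_map)) || any(!nzchar(names(column_map))))
    kt_stop("kt_config_error", "column_map must be a named vector (label -> column)")
  column_map <- vapply(column_map, as.integer, integer(1))
  if (!all(c("3b", "3n") %in% names(column_map)))
    kt_stop("kt_config_error", "column_map must map at least '3b' and '3n'")
  if (any(is.na(column_map)) || any(column_map < 1L))
    kt_stop("kt_config_error", "column_map columns must be positive integers")
  if (!file.exists(path)) kt_stop("kt_input_error", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^#\\s*STOCKHOLM", lines[1]))
    kt_stop("kt_format_error", "line 1: missing '# STOCKHOLM' header")

  seqs <- list()
  order_seen <- character(0)
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^#", ln) || grepl("^//", ln)) next
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) != 2L)
      kt_stop("kt_format_error",
              sprintf("line %d: expected '<name> <aligned sequence>'", i))
    nm <- toks[1]
    if (is.null(seqs[[nm]])) order_seen <- c(order_seen, nm)
    seqs[[nm]] <- paste0(seqs[[nm]] %||% "", toks[2])
  }
  if (length(seqs) == 0L)
    kt_stop("kt_format_error", "Stockholm file contains no sequence rows")

  width <- unique(nchar(unlist(seqs)))
  if (length(width) != 1L)
    kt_stop("kt_format_error", "alignment rows have unequal lengths")
  if (any(column_map > width))
    kt_stop("kt_config_error",
            sprintf("column_map references column %d but alignment width is %d",
                    max(column_map), width))

  sites <- lapply(order_seen, function(nm) {
    row <- toupper(seqs[[nm]])
    row <- chartr("T", "U", row)
    row <- gsub("[.~]", "-", row)
    bases <- vapply(column_map, function(cc) substr(row, cc, cc), character(1))
    bases[!bases %in% KT_CODES] <- "N"
    names(bases) <- names(column_map)
    structure(list(name = nm, bases = bases), class = "kturn_site")
  })
  if (min_coverage > 0) {
    keep <- vapply(sites, function(s)
      mean(s$bases != "-") >= min_coverage, logical(1))
    sites <- sites[keep]
  }
  sites
}

#' @export
pair_at.kturn_site <- function(x, position = 3L, ...) {
  lb <- paste0(position, "b"); ln <- paste0(position, "n")
  if (!all(c(lb, ln) %in% names(x$bases)))
    kt_stop("kt_annotation_error",
            sprintf("site '%s' carries no %s/%s labels", x$name, lb, ln))
  kt_pair(x$bases[[lb]], x$bases[[ln]], position)
}

#' Tabulate 3b.3n pairs across a cohort
#'
#' @param cohort list of `kturn` or `kturn_site` objects.
#' @param position NC-helix position to tabulate (default 3).
#' @param cohort_name label carried into reports.
#' @return Object of class `pair_count_table`: integer `counts` over the 16
#'   ordered pair codes plus `"unclassifiable"`, and `total`.
#' @export
tabulate_pairs <- function(cohort, position = 3L, cohort_name = "") {
  keys <- c(all_pair_codes(), "unclassifiable")
  counts <- stats::setNames(integer(length(keys)), keys)
  for (x in cohort) {
    p <- pair_at(x, position)
    key <- if (p$b %in% c("N", "-") || p$n %in% c("N", "-")) "unclassifiable"
           else pair_code(p)
    counts[key] <- counts[key] + 1L
  }
  structure(list(counts = counts, total = length(cohort),
                 cohort_name = cohort_name, position = position),
            class = "pair_count_table")
}

#' @export
print.pair_count_table <- function(x, ...) {
  cat(sprintf("3b·3n counts%s (n = %d):\n",
              if (nzchar(x$cohort_name)) paste0(" for ", x$cohort_name) else "",
              x$total))
  nz <- x$counts[x$counts > 0]
  for (k in names(nz)) {
    disp <- if (k == "unclassifiable") k
            else format_pair(kt_pair(substr(k, 1, 1), substr(k, 2, 2)))
    cat(sprintf("  %-15s %6d  (%.3f)\n", disp, nz[[k]], nz[[k]] / x$total))
  }
  invisible(x)
}

#' Summarize a cohort's 3b.3n composition and rule-engine fractions
#'
#' @param table a [tabulate_pairs()] result with `total > 0`.
#' @return Object of class `cohort_summary`: fractions `frac_AG`,
#'   `frac_3nG`, `frac_3bC`, `frac_folders`, `frac_nonfolders`,
#'   `frac_indeterminate`, `frac_unclassifiable` (the last four sum to 1).
#' @export
summarize_cohort <- function(table) {
  stopifnot(inherits(table, "pair_count_table"))
  if (table$total <= 0L)
    kt_stop("kt_empty_error", "cannot summarize an empty cohort")
  counts <- table$counts
  total <- table$total
  codes <- all_pair_codes()
  klass <- vapply(codes, function(code)
    classify_pair(kt_pair(substr(code, 1, 1), substr(code, 2, 2)))$klass,
    character(1))
  frac_of <- function(sel) sum(counts[codes[sel]]) / total
  structure(list(
    cohort_name = table$cohort_name,
    total = total,
    frac_AG = counts[["AG"]] / total,
    frac_3nG = frac_of(substr(codes, 2, 2) == "G"),
    frac_3bC = frac_of(substr(codes, 1, 1) == "C"),
    frac_folders = frac_of(klass == "ion_folder"),
    frac_nonfolders = frac_of(klass == "non_folder"),
    frac_indeterminate = frac_of(klass == "indeterminate"),
    frac_unclassifiable = counts[["unclassifiable"]] / total
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort%s (n = %d):\n",
              if (nzchar(x$cohort_name)) paste0(" ", x$cohort_name) else "",
              x$total))
  for (f in c("frac_AG", "frac_3nG", "frac_3bC", "frac_folders",
              "frac_nonfolders", "frac_indeterminate", "frac_unclassifiable"))
    cat(sprintf("  %-20s %.4f\n", f, x[[f]]))
  invisible(x)
}

#' Default folding-spectrum ranking of the 16 ordered pairs
#'
#' Ion folders first (the left, readily folded end), then indeterminate,
#' then non-folders; alphabetical by code within each block.  The measured
#' left-to-right order of the variant scan is a figure property, so the
#' ranking is configurable wherever it is consumed.
#'
#' @return Character vector of the 16 two-letter pair codes.
#' @export
default_pair_ranking <- function() {
  rt <- rule_table()
  blocks <- c("ion_folder", "indeterminate", "non_folder")
  unlist(lapply(blocks, function(k) sort(rt$code[rt$klass == k])),
         use.names = FALSE)
}

#' Lay cohort counts out along a folding-ability ranking
#'
#' @param table a [tabulate_pairs()] result.
#' @param ranking permutation of the 16 pair codes (left = most readily
#'   folded); default [default_pair_ranking()].
#' @return Data frame with columns `code`, `pair`, `count`, `fraction`,
#'   `klass` in ranking order (unclassifiable row appended last).
#' @export
folding_spectrum <- function(table, ranking = default_pair_ranking()) {
  stopifnot(inherits(table, "pair_count_table"))
  if (length(ranking) != 16L || !setequal(ranking, all_pair_codes()) ||
      anyDuplicated(ranking))
    kt_stop("kt_config_error", "ranking must be a permutation of the 16 pair codes")
  rt <- rule_table()
  rows <- data.frame(
    code = ranking,
    pair = rt$pair[match(ranking, rt$code)],
    count = as.integer(table$counts[ranking]),
    fraction = as.numeric(table$counts[ranking]) / table$total,
    klass = rt$klass[match(ranking, rt$code)],
    stringsAsFactors = FALSE)
  uncls <- table$counts[["unclassifiable"]]
  rbind(rows, data.frame(code = "unclassifiable", pair = "unclassifiable",
                         count = as.integer(uncls),
                         fraction = uncls / table$total,
                         klass = "unclassifiable",
                         stringsAsFactors = FALSE))
}

#' Read a column map from a plain config file
#'
#' Lines of the form `label=column` (1-based columns, `#` comments allowed).
#'
#' @param path config file path.
#' @return Named integer vector suitable for [read_stockholm_cohort()].
#' @export
read_column_map <- function(path) {
  if (!file.exists(path)) kt_stop("kt_input_error", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    kt_stop("kt_config_error", "column map lines must be 'label=column'")
  vals <- suppressWarnings(as.integer(vapply(kv, function(p) trimws(p[2]),
                                             character(1))))
  if (anyNA(vals)) kt_stop("kt_config_error", "non-integer column in column map")
  stats::setNames(vals, vapply(kv, function(p) trimws(p[1]), character(1)))
}
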
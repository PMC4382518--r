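# Empirical 3b.3n sequence rules for ion-induced k-turn folding.
#
# Two ordered rules classify the 16 possible 3b.3n pairs:
#   rule 1 (takes precedence): a Watson-Crick pair (A-U, U-A, G-C, C-G) or
#     the G-U wobble (3b=G, 3n=U) cannot fold in metal ions alone;
#   rule 2: otherwise, 3n=G or 3b=C permits ion-induced folding.
# Pairs matched by neither rule are reported as indeterminate rather than
# guessed.  The precedence matters exactly once: C-G has 3n=G yet is a
# non-folder because rule 1 fires first.

RULE1_CODES <- c("AU", "UA", "GC", "CG", "GU")

#' Classify a 3b.3n pair under the ion-folding sequence rules
#'
#' @param pair a [kt_pair()] with unambiguous bases.
#' @return An object of class `kt_prediction` with fields `klass` (one of
#'   `"ion_folder"`, `"non_folder"`, `"indeterminate"`), `rule_trace` (data
#'   frame of rule firings), `empirical_category` and `pair`.
#' @examples
#' classify_pair(kt_pair("A", "G"))$klass  # "ion_folder"
#' classify_pair(kt_pair("C", "G"))$klass  # "non_folder" (rule 1 precedence)
#' @export
classify_pair <- function(pair) {
  stopifnot(inherits(pair, "kt_pair"))
  if (pair$b %in% c("N", "-") || pair$n %in% c("N", "-"))
    kt_stop("kt_classification_error",
            sprintf("cannot classify ambiguous pair %s", format_pair(pair)))
  code <- pair_code(pair)
  trace <- data.frame(rule = character(0), condition = character(0),
                      stringsAsFactors = FALSE)
  if (code %in% RULE1_CODES) {
    kind <- if (code == "GU") "G-U wobble" else "Watson-Crick pair"
    trace <- rbind(trace, data.frame(
      rule = "rule1",
      condition = sprintf("3b·3n=%s is a %s", format_pair(pair), kind),
      stringsAsFactors = FALSE))
    klass <- "non_folder"
  } else if (pair$n == "G" || pair$b == "C") {
    cond <- if (pair$n == "G") "3n=G" else "3b=C"
    trace <- rbind(trace, data.frame(
      rule = "rule2", condition = cond, stringsAsFactors = FALSE))
    klass <- "ion_folder"
  } else {
    klass <- "indeterminate"
  }
  structure(list(klass = klass, rule_trace = trace,
                 empirical_category = "unknown", pair = pair),
            class = "kt_prediction")
}

#' @export
print.kt_prediction <- function(x, ...) {
  cat(sprintf("3b·3n=%s -> %s", format_pair(x$pair), x$klass))
  if (nrow(x$rule_trace) > 0L)
    cat(sprintf("  [%s: %s]", x$rule_trace$rule[1], x$rule_trace$condition[1]))
  if (!identical(x$empirical_category, "unknown"))
    cat(sprintf("  (measured: %s)", x$empirical_category))
  cat("\n")
  invisible(x)
}

all_pair_codes <- function() {
  g <- expand.grid(b = KT_BASES, n = KT_BASES, stringsAsFactors = FALSE)
  paste0(g$b, g$n)
}

#' Measured folding-ability table for the 16 Kt-7 3b.3n variants
#'
#' Categories are anchored in the reported variant scan where the text pins
#' them down: A.G is readily folded (the natural, best-folding sequence);
#' the Watson-Crick pairs and G-U are poor folders, with G-C and C-G
#' especially bad.  All other entries ship as `"unknown"`; the measured
#' per-variant amplitudes are a figure property, so `overrides` accepts a
#' named vector (names like "AG") of figure-derived categories which are
#' recorded with provenance `"override"`.
#'
#' @param overrides optional named character vector of categories
#'   (`readily_folded`, `poorly_folded`, `intermediate`) keyed by two-letter
#'   pair code.
#' @return Data frame with columns `b`, `n`, `code`, `pair`, `category`,
#'   `provenance`, one row per ordered pair (16 rows).
#' @export
empirical_table <- function(overrides = NULL) {
  codes <- all_pair_codes()
  tab <- data.frame(b = substr(codes, 1, 1), n = substr(codes, 2, 2),
                    code = codes, stringsAsFactors = FALSE)
  tab$pair <- vapply(seq_len(nrow(tab)),
                     function(i) format_pair(kt_pair(tab$b[i], tab$n[i])),
                     character(1))
  tab$category <- "unknown"
  tab$provenance <- "unset"
  anchored <- c(AG = "readily_folded", GC = "poorly_folded",
                CG = "poorly_folded", AU = "poorly_folded",
                UA = "poorly_folded", GU = "poorly_folded")
  hit <- match(names(anchored), tab$code)
  tab$category[hit] <- unname(anchored)
  tab$provenance[hit] <- "text"
  if (!is.null(overrides)) {
    ok <- c("readily_folded", "poorly_folded", "intermediate", "unknown")
    if (is.null(names(overrides)) || !all(overrides %in% ok))
      kt_stop("kt_config_error", "overrides must be a named vector of categories")
    i <- match(names(overrides), tab$code)
    if (anyNA(i))
      kt_stop("kt_config_error",
              sprintf("unknown pair code(s) in overrides: %s",
                      paste(names(overrides)[is.na(i)], collapse = ", ")))
    tab$category[i] <- unname(overrides)
    tab$provenance[i] <- "override"
  }
  tab
}

#' Empirical category from a measured folding amplitude
#'
#' The variant scan shades sequences readily folded at amplitude >= 0.5 and
#' poorly folded at <= 0.3.  Whether the thresholds apply to the fitted
#' amplitude (delta E_FRET) or to the saturation endpoint E_FRET is not
#' fully determined by the text (the best folder's reported rise, 0.2 to
#' 0.56, has amplitude 0.36 but endpoint 0.56); the `on` argument records
#' which reading is being used and both thresholds are configurable.
#'
#' @param value the measured quantity.
#' @param readily,poorly thresholds (defaults 0.5 and 0.3).
#' @param on which reading of the thresholds the caller applies,
#'   `"delta"` (fitted amplitude) or `"endpoint"` (saturation efficiency).
#' @return One of `"readily_folded"`, `"intermediate"`, `"poorly_folded"`.
#' @export
empirical_category_from_amplitude <- function(value, readily = 0.5,
                                              poorly = 0.3,
                                              on = c("delta", "endpoint")) {
  on <- match.arg(on)
  if (!is.finite(value)) kt_stop("kt_input_error", "value must be finite")
  if (value >= readily) "readily_folded"
  else if (value <= poorly) "poorly_folded"
  else "intermediate"
}

#' Predict ion-induced folding of a k-turn from its 3b.3n pair
#'
#' @param kturn a `kturn` (must carry 3b/3n labels).
#' @param table an [empirical_table()] used to attach the measured category
#'   when the pair is tabulated.
#' @return A `kt_prediction`.
#' @examples
#' predict_folding(kt7_kturn())$klass  # "ion_folder"
#' @export
predict_folding <- function(kturn, table = empirical_table()) {
  pred <- classify_pair(pair_at(kturn, 3L))
  i <- match(pair_code(pred$pair), table$code)
  if (!is.na(i)) pred$empirical_category <- table$category[i]
  pred
}

#' Partition the 16 ordered pairs by rule class
#'
#' @return Named list of three lists of [kt_pair()]s:
#'   `ion_folder`, `non_folder`, `indeterminate` (disjoint, exhaustive).
#' @export
enumerate_rule_partition <- function() {
  out <- list(ion_folder = list(), non_folder = list(), indeterminate = list())
  for (code in all_pair_codes()) {
    p <- kt_pair(substr(code, 1, 1), substr(code, 2, 2))
    k <- classify_pair(p)$klass
    out[[k]] <- c(out[[k]], list(p))
  }
  out
}

#' Export the rule table
#'
#' One row per ordered pair with its class and the rule that fired, suitable
#' for writing as delimited text and for cohort ranking.
#'
#' @return Data frame with columns `code`, `pair`, `klass`, `rule`.
#' @export
rule_table <- function() {
  codes <- all_pair_codes()
  rows <- lapply(codes, function(code) {
    pred <- classify_pair(kt_pair(substr(code, 1, 1), substr(code, 2, 2)))
    data.frame(code = code, pair = format_pair(pred$pair),
               klass = pred$klass,
               rule = if (nrow(pred$rule_trace)) pred$rule_trace$rule[1] else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
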
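# Positional model of the kink-turn (k-turn) motif.
#
# A standard k-turn is a duplex interrupted on one strand (the "b", bulged,
# strand) by a three-nucleotide loop, followed on its 3' side by the
# non-canonical (NC) helix that opens with tandem G.A / A.G pairs.  Positions
# are labelled relative to the loop: L1..Lk for the loop itself, 1b, 2b, ...
# walking 5'->3' into the NC helix on the bulged strand, -1b, -2b, ... walking
# into the canonical (C) helix, and 1n, 2n, ... / -1n, ... for the partner
# positions on the non-bulged ("n") strand, numbered so that ib pairs with in.
# These labels are the user-facing coordinate system; integer indices are an
# implementation detail (0-based, half-open).

KT_BASES <- c("A", "C", "G", "U")
KT_CODES <- c(KT_BASES, "N", "-")

# Uppercase, T->U, '.'/'~' -> '-'; reject anything outside A/C/G/U/N/-.
normalize_bases <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  x <- gsub("[.~]", "-", x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), KT_CODES)
  if (length(bad) > 0L)
    kt_stop("kt_input_error",
            sprintf("%s contains unsupported code(s): %s (only A, C, G, U, T, N and gaps are accepted; other ambiguity codes are rejected)",
                    what, paste(bad, collapse = ", ")))
  x
}

#' Construct an ordered k-turn base pair
#'
#' An ordered pair of bases at a numbered NC-helix position: `b` is the base
#' on the bulged strand, `n` the base on the non-bulged strand.  The order is
#' never swapped: `kt_pair("A", "G")` means 3b=A, 3n=G when `position = 3`.
#'
#' @param b,n single bases (A, C, G, U; N or "-" are carried but flagged as
#'   unclassifiable downstream).
#' @param position integer position index within the NC helix (3 for the
#'   3b.3n pair that governs ion-induced folding).
#' @return An object of class `kt_pair`.
#' @examples
#' format_pair(kt_pair("A", "G"))  # "A·G"
#' @export
kt_pair <- function(b, n, position = 3L) {
  b <- normalize_bases(b, "b base"); n <- normalize_bases(n, "n base")
  if (nchar(b) != 1L || nchar(n) != 1L)
    kt_stop("kt_input_error", "kt_pair takes single bases")
  structure(list(b = b, n = n, position_index = as.integer(position)),
            class = "kt_pair")
}

pair_code <- function(pair) paste0(pair$b, pair$n)

#' Format a base pair in field notation
#'
#' Watson-Crick pairs (A-U, U-A, G-C, C-G) and the G-U wobble with G on the
#' bulged strand are written with a dash; all other juxtapositions with a
#' middle dot (e.g. "A·G").  Pairs involving N or a gap are rendered with
#' "?" and carry a `flagged` attribute.
#'
#' @param pair a [kt_pair()].
#' @return A character scalar; attribute `flagged` is `TRUE` for N/gap pairs.
#' @export
format_pair <- function(pair) {
  stopifnot(inherits(pair, "kt_pair"))
  code <- pair_code(pair)
  if (pair$b %in% c("N", "-") || pair$n %in% c("N", "-")) {
    out <- paste0(pair$b, "?", pair$n)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  sep <- if (code %in% c("AU", "UA", "GC", "CG", "GU")) "-" else "·"
  paste0(pair$b, sep, pair$n)
}

#' @export
print.kt_pair <- function(x, ...) {
  cat(sprintf("%db·%dn pair: %s\n", x$position_index, x$position_index,
              format_pair(x)))
  invisible(x)
}

# Partner index on the n strand for a b-strand index, assuming the duplex
# register is anchored at the b-strand 3' end (pairs with the n-strand 5'
# end) and the loop is unpaired.  All indices 0-based.
partner_index <- function(i, b_len, loop_start, loop_length) {
  if (i >= loop_start + loop_length) (b_len - 1L) - i
  else (b_len - 1L) - i - loop_length
}

#' Parse and positionally annotate a k-turn
#'
#' Assigns the standard position labels to a two-strand k-turn given the
#' location of the bulge loop on the b strand.  The pairing register is
#' anchored at the 3' end of the b strand (blunt end with the 5' end of the
#' n strand); loop nucleotides are unpaired, so labels on the n strand run
#' antiparallel: 1n, 2n, ... descend 3'->5' as 1b, 2b, ... ascend.
#'
#' @param b_strand bulge-containing strand, 5'->3' (character). T is
#'   normalized to U, lowercase is accepted.
#' @param n_strand non-bulged strand, 5'->3'.
#' @param loop_start 0-based offset of the first loop nucleotide within
#'   `b_strand` (internal coordinates are 0-based half-open; the position
#'   labels are the supported user-facing coordinates).
#' @param loop_length number of looped nucleotides (3 for a standard k-turn).
#' @param name free-text identifier.
#' @return An object of class `kturn` with fields `b`, `n`, `loop_start`,
#'   `loop_length`, `name` and a `labels` data frame (label, strand, index).
#' @examples
#' kt <- parse_kturn("GGCGAAGAACC", "GGGGAGCC", loop_start = 3, name = "Kt-7")
#' format_pair(pair_at(kt, 3))
#' @export
parse_kturn <- function(b_strand, n_strand, loop_start, loop_length = 3L,
                        name = "") {
  if (!is.character(b_strand) || !is.character(n_strand) ||
      length(b_strand) != 1L || length(n_strand) != 1L ||
      !nzchar(b_strand) || !nzchar(n_strand))
    kt_stop("kt_input_error", "both strands must be non-empty strings")
  b <- normalize_bases(b_strand, "b_strand")
  n <- normalize_bases(n_strand, "n_strand")
  loop_start <- as.integer(loop_start)
  loop_length <- as.integer(loop_length)
  if (is.na(loop_start) || loop_start < 0L || loop_length < 1L)
    kt_stop("kt_input_error", "loop_start must be >= 0 and loop_length >= 1")
  b_len <- nchar(b); n_len <- nchar(n)
  if (loop_start + loop_length > b_len)
    kt_stop("kt_input_error",
            sprintf("loop (start %d, length %d) extends beyond b_strand (length %d)",
                    loop_start, loop_length, b_len))

  lab <- character(0); str <- character(0); idx <- integer(0)
  add <- function(label, strand, index) {
    lab <<- c(lab, label); str <<- c(str, strand); idx <<- c(idx, index)
  }
  # loop labels, contiguous on the b strand
  for (j in seq_len(loop_length))
    add(paste0("L", j), "b", loop_start + j - 1L)
  # NC-helix side: jb 3' of the loop
  n_nc <- b_len - (loop_start + loop_length)
  for (j in seq_len(n_nc)) {
    bi <- loop_start + loop_length + j - 1L
    add(paste0(j, "b"), "b", bi)
    ni <- partner_index(bi, b_len, loop_start, loop_length)
    if (ni >= 0L && ni < n_len) add(paste0(j, "n"), "n", ni)
  }
  # C-helix side: -jb 5' of the loop
  for (j in seq_len(loop_start)) {
    bi <- loop_start - j
    add(paste0("-", j, "b"), "b", bi)
    ni <- partner_index(bi, b_len, loop_start, loop_length)
    if (ni >= 0L && ni < n_len) add(paste0("-", j, "n"), "n", ni)
  }
  labels <- data.frame(label = lab, strand = str, index = idx,
                       stringsAsFactors = FALSE)

  # the NC helix must pair at least through 3n when the b side reaches 3b
  for (j in seq_len(min(n_nc, 3L))) {
    want <- paste0(j, "n")
    if (!want %in% labels$label)
      kt_stop("kt_annotation_error",
              sprintf("n_strand too short to pair %s", want))
  }

  structure(list(name = name, b = b, n = n, loop_start = loop_start,
                 loop_length = loop_length, labels = labels),
            class = "kturn")
}

base_at <- function(kturn, strand, index) {
  s <- if (strand == "b") kturn$b else kturn$n
  substr(s, index + 1L, index + 1L)
}

label_lookup <- function(kturn, label) {
  i <- match(label, kturn$labels$label)
  if (is.na(i)) return(NULL)
  kturn$labels[i, ]
}

#' Base at a named k-turn position
#'
#' @param kturn a [parse_kturn()] object.
#' @param label a position label such as "3b", "L1" or "-1n".
#' @return Single-character base.
#' @export
kt_base <- function(kturn, label) {
  row <- label_lookup(kturn, label)
  if (is.null(row))
    kt_stop("kt_annotation_error", sprintf("no label '%s' in this k-turn", label))
  base_at(kturn, row$strand, row$index)
}

#' Ordered base pair at an NC-helix position
#'
#' @param x a `kturn` (or a partial `kturn_site` from an alignment cohort).
#' @param position integer position; 3 selects the 3b.3n pair.
#' @param ... unused.
#' @return A [kt_pair()].
#' @export
pair_at <- function(x, position = 3L, ...) UseMethod("pair_at")

#' @export
pair_at.kturn <- function(x, position = 3L, ...) {
  kt_pair(kt_base(x, paste0(position, "b")),
          kt_base(x, paste0(position, "n")), position)
}

#' Re-emit the strand texts of a k-turn
#'
#' Inverse of [parse_kturn()] up to the documented input normalization
#' (uppercasing, T to U).
#'
#' @param kturn a `kturn`.
#' @return Named character vector `c(b = ..., n = ...)`.
#' @export
kt_strands <- function(kturn) c(b = kturn$b, n = kturn$n)

#' Check a k-turn against the standard-motif definition
#'
#' A standard k-turn has a three-nucleotide loop followed by G.A and A.G
#' pairs at positions 1 and 2 of the NC helix.  Deviations are reported, not
#' raised.
#'
#' @param kturn a `kturn`.
#' @return Data frame with columns `label`, `expected`, `found`; zero rows
#'   for a standard k-turn.
#' @export
validate_standard <- function(kturn) {
  dev <- data.frame(label = character(0), expected = character(0),
                    found = character(0), stringsAsFactors = FALSE)
  note <- function(label, expected, found)
    rbind(dev, data.frame(label = label, expected = expected, found = found,
                          stringsAsFactors = FALSE))
  if (kturn$loop_length != 3L)
    dev <- note("loop", "3", sprintf("loop length %d != 3", kturn$loop_length))
  want <- list(`1` = c(b = "G", n = "A"), `2` = c(b = "A", n = "G"))
  for (pos in c(1L, 2L)) {
    w <- want[[as.character(pos)]]
    for (side in c("b", "n")) {
      label <- paste0(pos, side)
      found <- tryCatch(kt_base(kturn, label), kt_error = function(e) NA)
      if (is.na(found)) dev <- note(label, w[[side]], "absent")
      else if (found != w[[side]]) dev <- note(label, w[[side]], found)
    }
  }
  dev
}

#' @export
print.kturn <- function(x, ...) {
  cat(sprintf("k-turn '%s'\n", if (nzchar(x$name)) x$name else "<unnamed>"))
  mark <- strsplit(x$b, "")[[1]]
  loop <- seq(x$loop_start + 1L, x$loop_start + x$loop_length)
  mark[loop] <- tolower(mark[loop])
  cat(sprintf("  b 5'-%s-3'  (loop lowercase)\n", paste(mark, collapse = "")))
  cat(sprintf("  n 5'-%s-3'\n", x$n))
  p3 <- tryCatch(format_pair(pair_at(x, 3L)), kt_error = function(e) "<n/a>")
  cat(sprintf("  3b·3n = %s\n", p3))
  invisible(x)
}

# --- shipped reference constructs ------------------------------------------

#' Kt-7 reference k-turn
#'
#' The Haloarcula marismortui ribosomal Kt-7 motif as carried by the
#' crystallized self-complementary construct GGCGAAGAACCGGGGAGCC, split into
#' its bulged (GGCGAAGAACC) and non-bulged (GGGGAGCC) halves.  Its 3b.3n
#' pair is A.G, the best ion-folding sequence.
#'
#' @return A `kturn`.
#' @export
kt7_kturn <- function()
  parse_kturn("GGCGAAGAACC", "GGGGAGCC", loop_start = 3L, name = "Kt-7")

#' U4-like k-turn (synthetic context)
#'
#' A stand-in for the human U4 snRNA k-turn: the Kt-7 helical context with
#' the U4 3b.3n identity, G-C (a Watson-Crick pair, hence a non-folder in
#' metal ions alone).  The flanking sequence is synthetic; only the 3b.3n
#' identity and the conserved G.A/A.G pairs are meaningful.
#'
#' @return A `kturn`.
#' @export
u4_kturn <- function()
  parse_kturn("GGCGAAGAGCC", "GGCGAGCC", loop_start = 3L,
              name = "U4-like (synthetic context)")
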
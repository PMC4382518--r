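# Seeded generators for every input the pipeline consumes: noisy two-state
# titration curves, the 16-variant 3b.3n scan of a template k-turn,
# sequence cohorts with family-like 3b.3n composition, and small coordinate
# fixtures for the metal-coordination module.  All generators are
# deterministic given their seed and never touch the caller's RNG state.

#' Specify a synthetic titration experiment
#'
#' Exactly one of `KA` or `half_point` must be given (the other is derived
#' via `half_point = (1/KA)^(1/n)`).
#'
#' @param E0 baseline FRET efficiency.
#' @param dE amplitude at saturation.
#' @param KA apparent association constant; or
#' @param half_point half-completion concentration.
#' @param n Hill coefficient.
#' @param conc_min,conc_max,n_points,log_spacing concentration grid
#'   (default 12 log-spaced points; at least 5 required).
#' @param noise_sd homoscedastic Gaussian noise on E_FRET (>= 0).
#' @param seed integer seed.
#' @param ligand,unit labels carried onto the curve.
#' @return Object of class `titration_spec`.
#' @export
titration_spec <- function(E0 = 0.2, dE = 0.36, KA = NULL, half_point = NULL,
                           n = 1, conc_min = 1, conc_max = 5000,
                           n_points = 12L, log_spacing = TRUE,
                           noise_sd = 0, seed = 1L,
                           ligand = "Mg2+", unit = "uM") {
  if (is.null(KA) == is.null(half_point))
    kt_stop("kt_input_error", "give exactly one of KA or half_point")
  if (!is.finite(n) || n <= 0) kt_stop("kt_input_error", "n must be > 0")
  if (is.null(KA)) {
    if (half_point <= 0) kt_stop("kt_input_error", "half_point must be > 0")
    KA <- (1 / half_point)^n
  }
  if (KA <= 0) kt_stop("kt_input_error", "KA must be > 0")
  if (n_points < 5L) kt_stop("kt_input_error", "grid needs at least 5 points")
  if (noise_sd < 0) kt_stop("kt_input_error", "noise_sd must be >= 0")
  if (!is.finite(conc_min) || !is.finite(conc_max) || conc_min >= conc_max)
    kt_stop("kt_input_error", "need conc_min < conc_max")
  if (log_spacing && conc_min <= 0)
    kt_stop("kt_input_error", "log spacing requires conc_min > 0")
  structure(list(E0 = E0, dE = dE, KA = KA, n = n,
                 conc_min = conc_min, conc_max = conc_max,
                 n_points = as.integer(n_points), log_spacing = log_spacing,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 ligand = ligand, unit = unit),
            class = "titration_spec")
}

#' Titration spec emulating the natural Kt-7 Mg2+ response
#'
#' E_FRET rising from 0.2 to 0.56 (amplitude 0.36) with a half-point of
#' 70 uM and Hill coefficient 1, on a 12-point log-spaced grid.
#'
#' @param ... overrides passed to [titration_spec()].
#' @return A `titration_spec`.
#' @export
kt7_titration_spec <- function(...) {
  args <- list(...)
  defaults <- list(E0 = 0.2, dE = 0.36, half_point = 70, n = 1)
  if (any(c("KA", "half_point") %in% names(args)))
    defaults$half_point <- NULL
  do.call(titration_spec, utils::modifyList(defaults, args))
}

#' Simulate a titration curve
#'
#' @param spec a [titration_spec()].
#' @return A [titration_curve()]; `meta` records the generating parameters
#'   and seed.
#' @export
simulate_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  conc <- if (spec$log_spacing)
    exp(seq(log(spec$conc_min), log(spec$conc_max), length.out = spec$n_points))
  else seq(spec$conc_min, spec$conc_max, length.out = spec$n_points)
  e <- model_efret(spec$E0, spec$dE, spec$KA, spec$n, conc)
  if (spec$noise_sd > 0)
    e <- e + with_seed(spec$seed, stats::rnorm(length(e), 0, spec$noise_sd))
  e <- pmin(pmax(e, -0.1), 1.1)
  titration_curve(conc, e, ligand = spec$ligand, unit = spec$unit,
                  meta = list(generator = unclass(spec)))
}

#' Substitute the base pair at an NC-helix position
#'
#' @param kturn template `kturn`.
#' @param b,n replacement bases.
#' @param position NC-helix position (default 3).
#' @return A new `kturn` (re-parsed, labels intact).
#' @export
substitute_pair <- function(kturn, b, n, position = 3L) {
  b <- normalize_bases(b, "b base"); n <- normalize_bases(n, "n base")
  rb <- label_lookup(kturn, paste0(position, "b"))
  rn <- label_lookup(kturn, paste0(position, "n"))
  if (is.null(rb) || is.null(rn))
    kt_stop("kt_annotation_error",
            sprintf("template lacks %db/%dn labels", position, position))
  bs <- kturn$b; ns <- kturn$n
  substr(bs, rb$index + 1L, rb$index + 1L) <- b
  substr(ns, rn$index + 1L, rn$index + 1L) <- n
  parse_kturn(bs, ns, kturn$loop_start, kturn$loop_length,
              name = sprintf("%s_3bn=%s%s", kturn$name, b, n))
}

#' Enumerate all 16 3b.3n variants of a template k-turn
#'
#' The systematic variant scan: the 3b.3n position replaced by every
#' ordered combination of the four nucleotides (15 variants plus the
#' natural sequence, which is flagged).
#'
#' @param template a `kturn` with 3b/3n labels.
#' @return List of 16 entries, each `list(pair, kturn, natural)`.
#' @export
enumerate_3bn_variants <- function(template) {
  nat <- pair_at(template, 3L)
  lapply(all_pair_codes(), function(code) {
    b <- substr(code, 1, 1); n <- substr(code, 2, 2)
    list(pair = kt_pair(b, n),
         kturn = substitute_pair(template, b, n),
         natural = (b == nat$b && n == nat$n))
  })
}

#' Define a cohort 3b.3n composition profile
#'
#' @param name profile name.
#' @param probabilities named numeric over two-letter pair codes (e.g.
#'   `c(AG = 0.6, GG = 0.4)`); non-negative, summing to 1 within 1e-9.
#' @param template `kturn` into which pairs are substituted.
#' @return Object of class `cohort_profile`.
#' @export
cohort_profile <- function(name, probabilities, template) {
  if (is.null(names(probabilities)) ||
      !all(names(probabilities) %in% all_pair_codes()))
    kt_stop("kt_input_error",
            "probabilities must be named by two-letter pair codes")
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-9)
    kt_stop("kt_input_error",
            "probabilities must be non-negative and sum to 1 (within 1e-9)")
  p <- stats::setNames(numeric(16), all_pair_codes())
  p[names(probabilities)] <- probabilities
  structure(list(name = name, pair_probabilities = p, template = template),
            class = "cohort_profile")
}

#' SAM-I-riboswitch-like cohort profile (paper-inspired, synthetic)
#'
#' Emulates the reported biases of natural SAM-I k-turn cohorts
#' qualitatively: A.G dominant (probability 0.60) and a 3n=G marginal of
#' 0.95, with Watson-Crick pairs rare.  The exact per-pair frequency vector
#' of any real alignment snapshot is database-version dependent; these
#' numbers define the synthetic stated world, not a reproduction.
#'
#' @param template template `kturn` (default [kt7_kturn()]).
#' @return A [cohort_profile()].
#' @export
sam_like_profile <- function(template = kt7_kturn())
  cohort_profile("SAM-I-like (synthetic)",
                 c(AG = 0.60, GG = 0.20, UG = 0.15, CA = 0.03, AA = 0.013,
                   GC = 0.001, CG = 0.001, UA = 0.005),
                 template)

#' U4-snRNA-like cohort profile (paper-inspired, synthetic)
#'
#' Mass concentrated on the non-folding Watson-Crick/wobble pairs G-C and
#' G-U (together 0.97, matching the reported ~97% predicted non-folders),
#' with A.G vanishingly rare.
#'
#' @param template template `kturn` (default [u4_kturn()]).
#' @return A [cohort_profile()].
#' @export
u4_like_profile <- function(template = u4_kturn())
  cohort_profile("U4-like (synthetic)",
                 c(GC = 0.72, GU = 0.25, GG = 0.012, UU = 0.0177,
                   AG = 0.0003),
                 template)

#' Generate a synthetic k-turn cohort
#'
#' Draws `n` sequences i.i.d. from the profile's pair probabilities and
#' substitutes each drawn pair into the template.
#'
#' @param profile a [cohort_profile()].
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @return List of `kturn` objects named `seq_1 ... seq_n`.
#' @export
generate_cohort <- function(profile, n, seed = 1L) {
  stopifnot(inherits(profile, "cohort_profile"))
  if (n < 1L) kt_stop("kt_input_error", "n must be >= 1")
  codes <- names(profile$pair_probabilities)
  draw <- with_seed(seed, sample(codes, n, replace = TRUE,
                                 prob = profile$pair_probabilities))
  variants <- stats::setNames(lapply(codes, function(code)
    substitute_pair(profile$template, substr(code, 1, 1), substr(code, 2, 2))),
    codes)
  out <- lapply(seq_len(n), function(i) {
    kt <- variants[[draw[i]]]
    kt$name <- sprintf("seq_%d", i)
    kt
  })
  out
}

# --- alignment / FASTA writers --------------------------------------------

#' Write a cohort as a Stockholm alignment
#'
#' Each row is the b strand followed by the n strand; all cohort members
#' must share the template geometry so columns align.  The matching column
#' map is given by [stockholm_column_map()].
#'
#' @param cohort list of `kturn` of identical strand lengths.
#' @param path output file.
#' @param id alignment identifier written as `#=GF ID`.
#' @export
write_cohort_stockholm <- function(cohort, path, id = "kturn_cohort") {
  bl <- unique(vapply(cohort, function(k) nchar(k$b), integer(1)))
  nl <- unique(vapply(cohort, function(k) nchar(k$n), integer(1)))
  if (length(bl) != 1L || length(nl) != 1L)
    kt_stop("kt_input_error", "cohort members must share strand lengths")
  rows <- vapply(cohort, function(k)
    sprintf("%-12s %s%s", k$name, k$b, k$n), character(1))
  writeLines(c("# STOCKHOLM 1.0", sprintf("#=GF ID %s", id), rows, "//"),
             path)
  invisible(path)
}

#' Column map matching [write_cohort_stockholm()]
#'
#' @param template the cohort's template `kturn`.
#' @param labels which position labels to map (default the NC-helix pairs
#'   1..3 on both strands).
#' @return Named integer vector of 1-based alignment columns.
#' @export
stockholm_column_map <- function(template,
                                 labels = c("1b", "2b", "3b",
                                            "1n", "2n", "3n")) {
  off_b <- 0L; off_n <- nchar(template$b)
  cols <- vapply(labels, function(lb) {
    row <- label_lookup(template, lb)
    if (is.null(row))
      kt_stop("kt_annotation_error", sprintf("template lacks label '%s'", lb))
    as.integer(row$index + 1L + if (row$strand == "b") off_b else off_n)
  }, integer(1))
  stats::setNames(cols, labels)
}

#' Write k-turns as FASTA
#'
#' Two records per k-turn (b then n strand); description lines carry
#' `loop_start= loop_len= strand=` tokens so [read_kturn_fasta()] can
#' reconstruct the annotation.
#'
#' @param kturns list of `kturn`.
#' @param path output file.
#' @export
write_kturn_fasta <- function(kturns, path) {
  seqs <- character(0); nms <- character(0)
  for (k in kturns) {
    nm <- if (nzchar(k$name)) k$name else "kturn"
    nms <- c(nms,
             sprintf("%s_b loop_start=%d loop_len=%d strand=b", nm,
                     k$loop_start, k$loop_length),
             sprintf("%s_n strand=n", nm))
    seqs <- c(seqs, k$b, k$n)
  }
  x <- Biostrings::BStringSet(seqs)
  names(x) <- nms
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read k-turns from FASTA
#'
#' Consecutive record pairs form one k-turn: a b-strand record whose
#' description carries `loop_start=<i>` (0-based), `loop_len=<k>` and
#' optionally `strand=b`, followed by its n-strand record.  When the tokens
#' are absent, `loop_start`/`loop_length` defaults are used.
#'
#' @param path FASTA file.
#' @param loop_start,loop_length defaults for records without tokens.
#' @return List of `kturn`.
#' @export
read_kturn_fasta <- function(path, loop_start = 3L, loop_length = 3L) {
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e)
                  kt_stop("kt_format_error",
                          sprintf("cannot read FASTA '%s': %s", path,
                                  conditionMessage(e))))
  if (length(x) == 0L)
    kt_stop("kt_input_error", sprintf("no sequences in '%s'", path))
  if (length(x) %% 2L != 0L)
    kt_stop("kt_format_error",
            "FASTA must contain b/n record pairs (even record count)")
  token <- function(desc, key, default) {
    m <- regmatches(desc, regexec(paste0(key, "=([^[:space:]]+)"), desc))[[1]]
    if (length(m) == 2L) m[2] else default
  }
  out <- list()
  for (i in seq(1L, length(x), by = 2L)) {
    desc_b <- names(x)[i]
    nm <- sub("_b$", "", strsplit(desc_b, "\\s+")[[1]][1])
    ls <- as.integer(token(desc_b, "loop_start", loop_start))
    ll <- as.integer(token(desc_b, "loop_len", loop_length))
    out[[length(out) + 1L]] <-
      parse_kturn(as.character(x[[i]]), as.character(x[[i + 1L]]),
                  loop_start = ls, loop_length = ll, name = nm)
  }
  out
}

# --- coordinate fixtures ---------------------------------------------------

octahedron_axes <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

fixture_atoms <- function(kind) {
  atom <- function(atom_name, element, residue_name, chain, resno, xyz)
    data.frame(atom_name = atom_name, altloc = " ",
               residue_name = residue_name, chain = chain,
               residue_number = as.integer(resno),
               x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
               element = element, stringsAsFactors = FALSE)
  if (kind == "ideal_octahedron") {
    rows <- list(atom("MG", "MG", "MG", "A", 101, c(0, 0, 0)))
    ax <- octahedron_axes() * 2.10
    for (i in seq_len(6))
      rows[[length(rows) + 1L]] <- atom("O", "O", "HOH", "W", 200 + i, ax[i, ])
    return(do.call(rbind, rows))
  }
  if (kind == "two_ion_kturn_like") {
    # Synthetic pattern fixture (not deposited coordinates): two octahedral
    # metals in canonical Mg-O geometry (2.10 A); M1 bonds the O6 atoms of
    # both G2n and G3n in cis, M2 bonds G3n O6 only, so G3n O6 bridges both
    # ions.  Guanines are reduced to their O6 atoms.
    s60 <- sqrt(3) / 2
    m1 <- c(2.1, 0, 0)
    m2 <- 2.1 * c(-0.5, s60, 0)
    u1 <- c(0.5, -s60, 0)           # M2 -> G3n O6 direction
    u2 <- c(s60, 0.5, 0)
    rows <- list(
      atom("O6", "O", "G", "N", 2, c(2.1, 2.1, 0)),   # G2n O6
      atom("O6", "O", "G", "N", 3, c(0, 0, 0)),       # G3n O6 (shared)
      atom("MG", "MG", "MG", "A", 101, m1),
      atom("MG", "MG", "MG", "A", 102, m2),
      # remaining inner-sphere waters of M1
      atom("O", "O", "HOH", "W", 201, m1 + c(2.1, 0, 0)),
      atom("O", "O", "HOH", "W", 202, m1 + c(0, -2.1, 0)),
      atom("O", "O", "HOH", "W", 203, m1 + c(0, 0, 2.1)),
      atom("O", "O", "HOH", "W", 204, m1 + c(0, 0, -2.1)),
      # remaining inner-sphere waters of M2
      atom("O", "O", "HOH", "W", 205, m2 - 2.1 * u1),
      atom("O", "O", "HOH", "W", 206, m2 + 2.1 * u2),
      atom("O", "O", "HOH", "W", 207, m2 - 2.1 * u2),
      atom("O", "O", "HOH", "W", 208, m2 + c(0, 0, 2.1)),
      atom("O", "O", "HOH", "W", 209, m2 + c(0, 0, -2.1)))
    return(do.call(rbind, rows))
  }
  kt_stop("kt_input_error", sprintf("unknown fixture kind '%s'", kind))
}

#' Label map for the two-ion fixture
#'
#' @return Named character vector mapping `"chain:resno"` to position
#'   labels, for use with [guanine_O6_report()].
#' @export
two_ion_label_map <- function() c("N:2" = "G2n", "N:3" = "G3n")

write_pdb_atoms <- function(atoms, path) {
  recs <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    nm <- a$atom_name
    # PDB atom-name column convention: 1-2 char element names start col 13
    nm_fmt <- if (nchar(nm) >= 4L) substr(nm, 1, 4)
              else if (nchar(trimws(a$element)) == 2L) sprintf("%-4s", nm)
              else sprintf(" %-3s", nm)
    sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (a$residue_name %in% c("MG", "HOH", "WAT", "NA", "K", "MN"))
              "HETATM" else "ATOM",
            i, nm_fmt, " ", a$residue_name, a$chain, a$residue_number,
            a$x, a$y, a$z, a$occupancy, 0, a$element)
  }, character(1))
  writeLines(c(recs, "END"), path)
}

write_cif_atoms <- function(atoms, path) {
  tags <- c("group_PDB", "id", "type_symbol", "label_atom_id",
            "label_alt_id", "label_comp_id", "label_asym_id",
            "label_seq_id", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy")
  rows <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    paste(if (a$residue_name %in% c("MG", "HOH", "WAT", "NA", "K", "MN"))
            "HETATM" else "ATOM",
          i, a$element, a$atom_name, ".", a$residue_name, a$chain,
          a$residue_number, sprintf("%.3f", a$x), sprintf("%.3f", a$y),
          sprintf("%.3f", a$z), sprintf("%.2f", a$occupancy))
  }, character(1))
  writeLines(c("data_kturnfold_fixture", "#", "loop_",
               paste0("_atom_site.", tags), rows, "#"), path)
}

#' Write a synthetic coordinate fixture
#'
#' `"ideal_octahedron"`: one Mg2+ with six waters at 2.10 A on the axes.
#' `"two_ion_kturn_like"`: a synthetic emulation of the two-ion guanine-O6
#' contact pattern seen in the NC-helix major groove (M1 bonded to G2n and
#' G3n O6, M2 to G3n O6); constructed geometry, not deposited coordinates.
#'
#' @param kind fixture name.
#' @param path output file.
#' @param format `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_fixture_structure <- function(kind = c("ideal_octahedron",
                                             "two_ion_kturn_like"),
                                    path, format = c("pdb", "cif")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  atoms <- fixture_atoms(kind)
  ok <- tryCatch(suppressWarnings({
    if (format == "pdb") write_pdb_atoms(atoms, path)
    else write_cif_atoms(atoms, path)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) kt_stop("kt_io_error", sprintf("cannot write fixture to '%s'", path))
  invisible(path)
}
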
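# Inner-sphere metal coordination in RNA coordinate files.
#
# Detects metal ions (Mg2+, Na+, K+, Mn2+ by default), collects their
# inner-sphere O/N ligands within a distance cutoff, scores octahedral
# coordination geometry from the cis ligand-metal-ligand angles, and reports
# direct metal contacts to guanine O6 atoms -- the interaction underlying the
# 3n=G ion-folding rule, where hydrated ions in the NC-helix major groove
# exchange inner-sphere waters for the O6 atoms of G2n and G3n.

GUANINE_RESNAMES <- c("G", "GUA", "RG", "DG")
WATER_RESNAMES <- c("HOH", "WAT", "H2O")

#' Read atoms from a PDB or mmCIF coordinate file
#'
#' Format is auto-detected from the extension (`.pdb`/`.ent` vs
#' `.cif`/`.mmcif`) or, failing that, from the content.  Alternate locations
#' are resolved to the highest-occupancy conformer (ties broken by altloc
#' identifier order).
#'
#' @param path coordinate file.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return Data frame with columns `atom_name`, `element`, `residue_name`,
#'   `chain`, `residue_number`, `x`, `y`, `z`, `occupancy`, `altloc`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) kt_stop("kt_input_error", sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb"
              else if (ext %in% c("cif", "mmcif")) "cif"
              else if (any(grepl("^_atom_site\\.", lines))) "cif"
              else "pdb"
  }
  atoms <- if (format == "pdb") parse_pdb_lines(lines) else parse_cif_lines(lines)
  resolve_altloc(atoms)
}

parse_pdb_lines <- function(lines) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel))
    kt_stop("kt_format_error", "no ATOM/HETATM records found (not a PDB file?)")
  ln <- lines[sel]
  lineno <- which(sel)
  field <- function(a, b) trimws(substr(ln, a, b))
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(field(a, b)))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      kt_stop("kt_format_error",
              sprintf("line %d: cannot parse %s from PDB record", lineno[bad[1]],
                      what))
    v
  }
  atom_name <- field(13, 16)
  element <- field(77, 78)
  # element column absent in minimal files: derive from the atom name
  fallback <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atom_name)))
  fallback <- ifelse(fallback %in% c("MG", "NA", "MN", "CL", "FE", "ZN", "BR"),
                     fallback, substr(fallback, 1, 1))
  element <- toupper(ifelse(nzchar(element), element, fallback))
  occ <- suppressWarnings(as.numeric(field(55, 60)))
  occ[!is.finite(occ)] <- 1
  data.frame(
    atom_name = atom_name,
    altloc = substr(ln, 17, 17),
    residue_name = field(18, 20),
    chain = field(22, 22),
    residue_number = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occupancy = occ,
    element = element,
    stringsAsFactors = FALSE)
}

parse_cif_lines <- function(lines) {
  tags_idx <- grep("^_atom_site\\.", lines)
  if (length(tags_idx) == 0L)
    kt_stop("kt_format_error", "no _atom_site loop found (not an mmCIF file?)")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tags_idx]))
  start <- max(tags_idx) + 1L
  rows <- list()
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^(_|loop_|#|data_)", ln)) break
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) != length(tags))
      kt_stop("kt_format_error",
              sprintf("line %d: %d tokens but %d _atom_site fields declared",
                      i, length(toks), length(tags)))
    rows[[length(rows) + 1L]] <- toks
  }
  if (length(rows) == 0L)
    kt_stop("kt_format_error", "_atom_site loop has no data rows")
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  get <- function(...) {
    for (nm in c(...)) if (nm %in% tags) {
      v <- m[, nm]
      v[v %in% c(".", "?")] <- ""
      return(v)
    }
    rep("", nrow(m))
  }
  xyz <- function(nm) {
    v <- suppressWarnings(as.numeric(get(nm)))
    if (any(!is.finite(v)))
      kt_stop("kt_format_error", sprintf("non-numeric %s in _atom_site loop", nm))
    v
  }
  occ <- suppressWarnings(as.numeric(get("occupancy")))
  occ[!is.finite(occ)] <- 1
  resno <- suppressWarnings(as.integer(get("auth_seq_id", "label_seq_id")))
  resno[is.na(resno)] <- 0L
  data.frame(
    atom_name = get("auth_atom_id", "label_atom_id"),
    altloc = get("label_alt_id"),
    residue_name = get("auth_comp_id", "label_comp_id"),
    chain = get("auth_asym_id", "label_asym_id"),
    residue_number = resno,
    x = xyz("Cartn_x"), y = xyz("Cartn_y"), z = xyz("Cartn_z"),
    occupancy = occ,
    element = toupper(get("type_symbol")),
    stringsAsFactors = FALSE)
}

resolve_altloc <- function(atoms) {
  atoms$altloc[atoms$altloc %in% c("", ".")] <- " "
  key <- paste(atoms$chain, atoms$residue_number, atoms$residue_name,
               atoms$atom_name, sep = "\r")
  o <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[o, , drop = FALSE]
  atoms <- atoms[!duplicated(key[o]), , drop = FALSE]
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Detect metal coordination sites
#'
#' One site per metal atom; ligands are all O and N atoms within the
#' inner-sphere cutoff, ordered by distance.  The default cutoff of 2.6
#' angstroms covers Mg-O (~2.05-2.15 A) and Na-O (~2.4 A) bonds, reflecting
#' that octahedrally hydrated sites in RNA are usually Mg2+ but cannot be
#' distinguished from Na+ on distances alone; the tool reports, never
#' resolves, that ambiguity.
#'
#' @param atoms a [read_structure()] table.
#' @param metal_elements element symbols treated as metals.
#' @param cutoff inner-sphere distance cutoff in angstroms, in (1.5, 3.5).
#' @param octahedral_tolerance mean cis-angle deviation (degrees) below
#'   which a 6-coordinate site is called octahedral.
#' @return List of `coordination_site` objects (`metal_id` M1, M2, ... in
#'   file order) with fields `metal`, `ligands` (data frame with
#'   `distance`), `cis_angle_deviation`, `is_octahedral`, `o6_contacts`.
#' @export
find_metal_sites <- function(atoms, metal_elements = c("MG", "NA", "K", "MN"),
                             cutoff = 2.6, octahedral_tolerance = 15) {
  if (!is.finite(cutoff) || cutoff <= 1.5 || cutoff >= 3.5)
    kt_stop("kt_precondition_error",
            "inner-sphere cutoff must lie in (1.5, 3.5) angstroms")
  metal_elements <- toupper(metal_elements)
  if (nrow(atoms) == 0L) return(list())
  is_metal <- toupper(atoms$element) %in% metal_elements
  is_lig <- toupper(atoms$element) %in% c("O", "N") & !is_metal
  metals <- atoms[is_metal, , drop = FALSE]
  ligpool <- atoms[is_lig, , drop = FALSE]
  if (nrow(metals) == 0L) return(list())
  lig_xyz <- atom_xyz(ligpool)
  sites <- vector("list", nrow(metals))
  for (k in seq_len(nrow(metals))) {
    mrow <- metals[k, , drop = FALSE]
    mx <- as.numeric(mrow[, c("x", "y", "z")])
    d <- sqrt(colSums((t(lig_xyz) - mx)^2))
    sel <- which(d <= cutoff)
    # order by distance; sub-angstrom-rounding ties broken by identity so
    # the ordering is stable under rigid-body transforms
    sel <- sel[order(round(d[sel], 6), ligpool$chain[sel],
                     ligpool$residue_number[sel], ligpool$atom_name[sel])]
    ligands <- ligpool[sel, , drop = FALSE]
    ligands$distance <- d[sel]
    rownames(ligands) <- NULL
    site <- structure(list(metal_id = sprintf("M%d", k), metal = mrow,
                           ligands = ligands,
                           cis_angle_deviation = NA_real_,
                           is_octahedral = FALSE, o6_contacts = NULL),
                      class = "coordination_site")
    if (nrow(ligands) >= 2L) {
      sc <- octahedral_score(site, tolerance = octahedral_tolerance)
      site$cis_angle_deviation <- sc$deviation
      site$is_octahedral <- sc$is_octahedral
    }
    g <- ligands[ligands$residue_name %in% GUANINE_RESNAMES &
                   trimws(ligands$atom_name) == "O6", , drop = FALSE]
    site$o6_contacts <- g
    sites[[k]] <- site
  }
  sites
}

#' Score octahedral coordination geometry
#'
#' Angles are measured at the metal between each pair of ligands; pairs
#' closer than 135 degrees are counted as cis (an ideal octahedron has 12
#' cis pairs at 90 degrees and 3 trans pairs at 180).  The score is the
#' mean absolute deviation of cis angles from 90 degrees.
#'
#' @param site a `coordination_site` with at least 2 ligands.
#' @param tolerance degrees; a 6-coordinate site within this mean deviation
#'   is called octahedral.
#' @return List with `deviation` (degrees), `is_octahedral`, `n_cis`.
#' @export
octahedral_score <- function(site, tolerance = 15) {
  stopifnot(inherits(site, "coordination_site"))
  nl <- nrow(site$ligands)
  if (is.null(nl) || nl < 2L)
    kt_stop("kt_geometry_error", "octahedral score requires >= 2 ligands")
  m <- as.numeric(site$metal[, c("x", "y", "z")])
  v <- sweep(atom_xyz(site$ligands), 2, m)
  v <- v / sqrt(rowSums(v^2))
  angles <- numeric(0)
  for (i in seq_len(nl - 1L)) for (j in seq(i + 1L, nl)) {
    cosang <- max(-1, min(1, sum(v[i, ] * v[j, ])))
    angles <- c(angles, acos(cosang) * 180 / pi)
  }
  cis <- angles[angles < 135]
  deviation <- if (length(cis) > 0L) mean(abs(cis - 90)) else NA_real_
  list(deviation = deviation,
       is_octahedral = (nl == 6L && is.finite(deviation) &&
                          deviation <= tolerance),
       n_cis = length(cis))
}

#' @export
print.coordination_site <- function(x, ...) {
  cat(sprintf("%s: %s %s/%d  %d ligand(s)", x$metal_id,
              x$metal$element, x$metal$chain, x$metal$residue_number,
              nrow(x$ligands)))
  if (is.finite(x$cis_angle_deviation))
    cat(sprintf("  cis dev %.2f deg  octahedral=%s",
                x$cis_angle_deviation, x$is_octahedral))
  cat(sprintf("  guanine O6 contacts: %d\n", nrow(x$o6_contacts)))
  invisible(x)
}

#' Report inner-sphere guanine O6 contacts
#'
#' @param sites a [find_metal_sites()] result.
#' @param label_map optional named character vector mapping `"chain:resno"`
#'   to k-turn position labels (e.g. `c("N:3" = "G3n")`).
#' @return Data frame with one row per metal-O6 contact: `metal_id`,
#'   `metal_element`, `chain`, `residue_number`, `residue_name`,
#'   `position_label`, `distance`.
#' @export
guanine_O6_report <- function(sites, label_map = NULL) {
  empty <- data.frame(metal_id = character(0), metal_element = character(0),
                      chain = character(0), residue_number = integer(0),
                      residue_name = character(0),
                      position_label = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  rows <- lapply(sites, function(s) {
    g <- s$o6_contacts
    if (is.null(g) || nrow(g) == 0L) return(NULL)
    key <- paste(g$chain, g$residue_number, sep = ":")
    lbl <- if (is.null(label_map)) rep(NA_character_, nrow(g))
           else unname(label_map[key])
    data.frame(metal_id = s$metal_id, metal_element = s$metal$element,
               chain = g$chain, residue_number = g$residue_number,
               residue_name = g$residue_name, position_label = lbl,
               distance = g$distance, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ligands shared between metal sites
#'
#' Names every ligand atom lying within the inner-sphere cutoff of more
#' than one metal (e.g. a guanine O6 bridging two ions).
#'
#' @param sites a [find_metal_sites()] result.
#' @return Data frame with `chain`, `residue_number`, `residue_name`,
#'   `atom_name`, `metals` (comma-separated metal ids), `n_metals`.
#' @export
shared_ligand_report <- function(sites) {
  recs <- lapply(sites, function(s) {
    if (nrow(s$ligands) == 0L) return(NULL)
    data.frame(metal_id = s$metal_id, chain = s$ligands$chain,
               residue_number = s$ligands$residue_number,
               residue_name = s$ligands$residue_name,
               atom_name = trimws(s$ligands$atom_name),
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs) || nrow(recs) == 0L)
    return(data.frame(chain = character(0), residue_number = integer(0),
                      residue_name = character(0), atom_name = character(0),
                      metals = character(0), n_metals = integer(0),
                      stringsAsFactors = FALSE))
  key <- paste(recs$chain, recs$residue_number, recs$residue_name,
               recs$atom_name, sep = "\r")
  agg <- lapply(split(recs, key), function(g) {
    data.frame(chain = g$chain[1], residue_number = g$residue_number[1],
               residue_name = g$residue_name[1], atom_name = g$atom_name[1],
               metals = paste(sort(unique(g$metal_id)), collapse = ","),
               n_metals = length(unique(g$metal_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[out$n_metals > 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a delimited metal-site report
#'
#' @param sites a [find_metal_sites()] result.
#' @param path output TSV path.
#' @param seed optional seed echoed in the header.
#' @export
write_site_report <- function(sites, path, seed = NULL) {
  hdr <- kt_version_header(seed)
  rows <- vapply(sites, function(s)
    paste(s$metal_id, s$metal$element, s$metal$chain, s$metal$residue_number,
          nrow(s$ligands),
          formatC(s$cis_angle_deviation, digits = 4, format = "f"),
          s$is_octahedral, nrow(s$o6_contacts), sep = "\t"),
    character(1))
  writeLines(c(hdr,
               paste("metal_id", "element", "chain", "resno", "n_ligands",
                     "cis_angle_deviation", "is_octahedral", "n_O6_contacts",
                     sep = "\t"),
               rows), path)
  invisible(path)
}
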
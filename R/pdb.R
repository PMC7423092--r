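#' Parse a PDB coordinate file
#'
#' Reads fixed-width PDB v3.3 ATOM/HETATM records, resolves alternate
#' locations, annotates each standard-residue heavy atom with its atom type
#' and folded electron count, and collects the unit cell and space group
#' from CRYST1. Only the first MODEL is used when several are present.
#'
#' Alternate locations are resolved per atom site by keeping the
#' highest-occupancy conformer (ties broken by altloc letter); the retained
#' conformer keeps its stated occupancy. Hydrogens are dropped (their
#' electrons are folded into the bonded heavy atoms by the typing table).
#' Heavy atoms of standard residues that cannot be typed, and all
#' non-water hetero atoms, are kept in `$hetero` with element-only electron
#' counts; waters (HOH/WAT/DOD) in `$waters` with 10 electrons each.
#'
#' @param path Path to a PDB file, or a character vector of PDB lines via
#'   `text`.
#' @param text Optional character vector of PDB lines (overrides `path`).
#' @param lenient If `TRUE`, malformed ATOM records are skipped with a
#'   warning instead of failing.
#' @return An object of class `ed_structure`: list with tibbles `atoms`
#'   (typed protein atoms), `waters`, `hetero`, plus `cell` ([unit_cell()]
#'   or `NULL`), `spacegroup` (Hermann-Mauguin symbol or `NA`).
#' @export
read_pdb_structure <- function(path = NULL, text = NULL, lenient = FALSE) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  # first MODEL only
  imodel <- which(rec == "MODEL ")
  if (length(imodel) > 1) {
    iend <- which(rec == "ENDMDL")
    stop_at <- if (length(iend)) iend[1] else imodel[2]
    keep <- seq_along(lines) < stop_at | !(rec %in% c("ATOM  ", "HETATM", "ANISOU"))
    lines <- lines[keep]; rec <- rec[keep]
  }
  cell <- NULL; sg <- NA_character_
  icr <- which(rec == "CRYST1")
  if (length(icr)) {
    l <- lines[icr[1]]
    num <- function(a, b) suppressWarnings(as.numeric(substr(l, a, b)))
    cell <- unit_cell(num(7, 15), num(16, 24), num(25, 33),
                      num(34, 40), num(41, 47), num(48, 54))
    sg <- trimws(substr(l, 56, 66))
    if (!nzchar(sg)) sg <- NA_character_
  }
  iat <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(iat)) abort("no ATOM/HETATM records found: empty structure")
  al <- lines[iat]
  numf <- function(a, b) suppressWarnings(as.numeric(substr(al, a, b)))
  atoms <- tibble(
    record = rec[iat],
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    name = trimws(substr(al, 13, 16)),
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resseq = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode = substr(al, 27, 27),
    x = numf(31, 38), y = numf(39, 46), z = numf(47, 54),
    occ = numf(55, 60), b = numf(61, 66),
    element = trimws(substr(al, 77, 78)),
    line = iat
  )
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z) |
    !nzchar(atoms$name)
  if (any(bad)) {
    msg <- sprintf("malformed ATOM/HETATM record at line %s",
                   paste(atoms$line[bad], collapse = ", "))
    if (lenient) warn(paste0(msg, " (skipped)")) else abort(msg)
    atoms <- atoms[!bad, ]
  }
  atoms$occ[!is.finite(atoms$occ)] <- 1
  atoms$b[!is.finite(atoms$b)] <- 0
  atoms$element <- ifelse(nzchar(atoms$element), toupper(atoms$element),
                          infer_element(al[match(atoms$line, iat)], atoms$name))
  # altloc resolution: keep the highest-occupancy conformer per atom site
  atoms <- atoms %>%
    group_by(.data$chain, .data$resseq, .data$icode, .data$resname, .data$name) %>%
    arrange(desc(.data$occ), .data$altloc, .by_group = TRUE) %>%
    filter(row_number() == 1L) %>%
    ungroup() %>%
    arrange(.data$line) %>%
    select(-"line")
  atoms <- atoms %>% filter(.data$element != "H", .data$element != "D")
  is_water <- atoms$resname %in% c("HOH", "WAT", "DOD")
  is_std <- atoms$resname %in% standard_residues() & atoms$record == "ATOM  "
  typed <- atoms[is_std, ] %>%
    mutate(atom_type = classify_atom(.data$resname, .data$name),
           z_e = electron_count(.data$resname, .data$name, .data$element))
  untyped <- typed %>% filter(is.na(.data$atom_type))
  typed <- typed %>% filter(!is.na(.data$atom_type)) %>% select(-"record")
  waters <- atoms[is_water, ] %>%
    mutate(z_e = 10L) %>% select(-"record")       # O with both hydrogens folded
  hetero <- bind_rows(
    atoms[!is_std & !is_water, ],
    untyped %>% select(-"atom_type", -"z_e") %>% mutate(record = "ATOM  ")
  ) %>%
    mutate(z_e = as.integer(element_z(.data$element))) %>% select(-"record")
  if (any(is.na(hetero$z_e))) {
    warn(sprintf("%d hetero atoms with unknown element dropped from F000",
                 sum(is.na(hetero$z_e))))
    hetero <- hetero %>% filter(!is.na(.data$z_e))
  }
  structure(list(atoms = typed, waters = waters, hetero = hetero,
                 cell = cell, spacegroup = sg), class = "ed_structure")
}

# Element inference from the atom-name columns when 77-78 are blank:
# a character in column 13 means a two-letter element (metals) for HETATM-style
# names; otherwise the first alphabetic character of the justified name.
infer_element <- function(raw_lines, name) {
  col13 <- substr(raw_lines, 13, 13)
  two <- col13 != " " & !grepl("[0-9]", col13) &
    toupper(substr(raw_lines, 13, 14)) %in% c("FE", "ZN", "MG", "MN", "CU",
                                              "NI", "CO", "NA", "CL", "CA", "BR", "SE")
  first <- toupper(sub("^[0-9]*", "", name))
  ifelse(two, toupper(substr(raw_lines, 13, 14)), substr(first, 1, 1))
}

#' @export
print.ed_structure <- function(x, ...) {
  cat(sprintf("<ed_structure> %d typed protein atoms, %d waters, %d hetero atoms\n",
              nrow(x$atoms), nrow(x$waters), nrow(x$hetero)))
  if (!is.null(x$cell)) {
    cat(sprintf("  space group: %s\n", x$spacegroup)); print(x$cell)
  }
  invisible(x)
}

#' Write a structure back to PDB format
#'
#' Emits fixed-width v3.3 ATOM/HETATM records (plus CRYST1 when a cell is
#' present). Parsing the output reproduces the model content consumed by
#' the analysis.
#'
#' @param structure An `ed_structure`.
#' @param path Output file path; omit to return the lines invisibly.
#' @return Character vector of PDB lines, invisibly when written to a file.
#' @export
write_pdb_structure <- function(structure, path = NULL) {
  out <- character(0)
  if (!is.null(structure$cell)) {
    cl <- structure$cell
    sg <- if (is.na(structure$spacegroup)) "P 1" else structure$spacegroup
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                          cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma, sg, 1L))
  }
  fmt <- function(df, record) {
    if (!nrow(df)) return(character(0))
    name4 <- ifelse(nchar(df$name) >= 4, substr(df$name, 1, 4),
                    paste0(" ", formatC(df$name, width = -3)))
    sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, df$serial, name4, " ", df$resname, df$chain, df$resseq,
            df$icode, df$x, df$y, df$z, df$occ, df$b, df$element)
  }
  out <- c(out,
           fmt(structure$atoms, "ATOM"),
           fmt(structure$hetero, "HETATM"),
           fmt(structure$waters, "HETATM"),
           "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
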
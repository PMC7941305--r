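#' Element-labelled atomic coordinates
#'
#' Minimal coordinate container used by the intensity calculator: element
#' symbols, Cartesian coordinates in Angstrom and an occupancy weight.
#' Chain/residue semantics are deliberately not carried; scattering depends
#' only on elements and positions.
#'
#' @param element character vector of element symbols (e.g. `"C"`, `"Tb"`).
#' @param x,y,z numeric coordinates in Angstrom.
#' @param occupancy numeric in `[0, 1]`; multiplies the atomic form factor.
#' @param label free-text label for the set.
#' @return An object of class `atom_set` (a data frame).
#' @export
atom_set <- function(element, x, y, z, occupancy = 1, label = "") {
  element <- normalize_element(element)
  n <- length(element)
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  occupancy <- rep_len(as.numeric(occupancy), n)
  if (n < 1L) stop("empty atom set")
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("coordinate vectors must match the number of elements")
  if (any(!is.finite(c(x, y, z))))
    stop("coordinates must be finite")
  if (any(!is.finite(occupancy)) || any(occupancy < 0) || any(occupancy > 1))
    stop("occupancy must be in [0, 1]")
  unknown <- setdiff(unique(element), supported_elements())
  if (length(unknown))
    stop("unsupported element symbol(s): ", paste(unknown, collapse = ", "))
  structure(data.frame(element = element, x = x, y = y, z = z,
                       occupancy = occupancy, stringsAsFactors = FALSE),
            class = c("atom_set", "data.frame"), label = label)
}

#' @export
print.atom_set <- function(x, ...) {
  tab <- table(x$element)
  cat(sprintf("Atom set%s: %d atoms (%s)\n",
              if (nzchar(attr(x, "label"))) paste0(" '", attr(x, "label"), "'") else "",
              nrow(x),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

## "FE" -> "Fe" etc.
normalize_element <- function(e) {
  e <- trimws(as.character(e))
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}

## Infer the element from a PDB atom name when the element column is blank.
## Convention: columns 13-14 hold the (right-justified) element; a leading
## digit is a Greek-position prefix on hydrogens.
element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- normalize_element(substr(nm, 1, 2))
  one <- normalize_element(substr(nm, 1, 1))
  ifelse(two %in% supported_elements() & nchar(nm) > 1 &
           !(one %in% c("C", "N", "O", "H", "P", "S")),
         two, one)
}

#' Read atomic coordinates from PDB or mmCIF
#'
#' PDB files are parsed with \pkg{bio3d} (first model only; alternate
#' location `A` or blank kept; blank occupancies default to 1).  For mmCIF,
#' the `atom_site` category is read with a header-driven loop parser, so any
#' column order is accepted.  Elements are taken from the element column
#' (`type_symbol` in mmCIF) and fall back to the atom-name convention when
#' that column is absent or blank.
#'
#' @param path path to the coordinate file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @param exclude_water drop water molecules (residue name HOH/WAT/DOD)?
#' @return An [atom_set()].
#' @export
read_atoms <- function(path, format = c("auto", "pdb", "mmcif"),
                       exclude_water = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  tab <- if (format == "pdb") read_atoms_pdb(path) else read_atoms_cif(path)
  if (exclude_water)
    tab <- tab[!(toupper(tab$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no atoms found in ", path)
  blank <- is.na(tab$element) | trimws(tab$element) %in% c("", ".", "?")
  elem <- ifelse(blank, element_from_name(tab$name),
                 normalize_element(tab$element))
  occ <- ifelse(is.na(tab$occupancy), 1, tab$occupancy)
  atom_set(elem, tab$x, tab$y, tab$z, occupancy = pmin(pmax(occ, 0), 1),
           label = basename(path))
}

read_atoms_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  data.frame(element = a$elesy, name = a$elety, resid = a$resid,
             x = a$x, y = a$y, z = a$z, occupancy = a$o,
             stringsAsFactors = FALSE)
}

## Minimal mmCIF atom_site reader: only the loop_ table of the atom_site
## category, with columns located by their _atom_site.* headers.
read_atoms_cif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", trimws(lines))
  if (!length(hdr_idx))
    stop("no atom_site records found in ", path)
  hdr <- trimws(lines[hdr_idx])
  cols <- sub("^_atom_site\\.", "", hdr)
  body_start <- max(hdr_idx) + 1L
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_"))
      break
    body <- c(body, ln)
  }
  if (!length(body))
    stop("empty atom_site loop in ", path)
  fields <- strsplit(body, "[ \t]+")
  nf <- lengths(fields)
  fields <- fields[nf == length(cols)]
  if (!length(fields))
    stop("malformed atom_site rows in ", path)
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  get <- function(nm) if (nm %in% cols) m[, nm] else rep(NA_character_, nrow(m))
  ## keep first model, altloc '.' or 'A'
  model <- get("pdbx_PDB_model_num")
  if (!all(is.na(model))) {
    first <- model[which(!is.na(model))[1]]
    keep <- is.na(model) | model == first
    m <- m[keep, , drop = FALSE]
  }
  alt <- get("label_alt_id")
  keep <- is.na(alt) | alt %in% c(".", "?", "A", "")
  m <- m[keep, , drop = FALSE]
  num <- function(v) suppressWarnings(as.numeric(v))
  pick <- function(...) {
    nm <- intersect(c(...), cols)
    if (length(nm)) m[, nm[1]] else rep(NA_character_, nrow(m))
  }
  if (!all(c("Cartn_x", "Cartn_y", "Cartn_z") %in% cols))
    stop("atom_site loop in ", path, " lacks Cartesian coordinates")
  data.frame(element = pick("type_symbol"),
             name = pick("label_atom_id", "auth_atom_id"),
             resid = pick("label_comp_id", "auth_comp_id"),
             x = num(m[, "Cartn_x"]), y = num(m[, "Cartn_y"]),
             z = num(m[, "Cartn_z"]),
             occupancy = num(pick("occupancy")),
             stringsAsFactors = FALSE)
}

#' Convert an mmCIF coordinate file to fixed-column PDB
#'
#' Writes one `ATOM` record per `atom_site` row (first model, altloc `A` or
#' blank), preserving elements and coordinates to 3 decimals.  Atom serial
#' numbers beyond the fixed-column limit of 99999 are renumbered modulo
#' 99999 with a warning; hybrid-36 encoding is not attempted.
#'
#' @param infile input mmCIF path.
#' @param outfile output PDB path.
#' @return Invisibly, `outfile`.
#' @export
cif_to_pdb <- function(infile, outfile) {
  tab <- read_atoms_cif(infile)
  if (nrow(tab) == 0L) stop("no atoms found in ", infile)
  n <- nrow(tab)
  serial <- seq_len(n)
  if (n > 99999L) {
    warning("atom serial numbers exceed the PDB fixed-column limit; ",
            "renumbering modulo 99999")
    serial <- (serial - 1L) %% 99999L + 1L
  }
  bad <- abs(tab$x) >= 10000 | abs(tab$y) >= 10000 | abs(tab$z) >= 10000
  if (any(bad)) {
    warning(sum(bad), " atom(s) with coordinates overflowing the PDB ",
            "fixed columns were skipped")
    tab <- tab[!bad, , drop = FALSE]
    serial <- serial[!bad]
  }
  elem <- ifelse(is.na(tab$element) | !nzchar(trimws(tab$element)),
                 element_from_name(tab$name), normalize_element(tab$element))
  name4 <- vapply(tab$name, function(nm) {
    nm <- trimws(nm)
    if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
  }, character(1))
  resid <- ifelse(is.na(tab$resid), "UNK", tab$resid)
  occ <- ifelse(is.na(tab$occupancy), 1, tab$occupancy)
  lines <- sprintf("ATOM  %5d %-4s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   serial, name4, substr(resid, 1, 3), "A",
                   (seq_len(nrow(tab)) - 1L) %% 9999L + 1L,
                   tab$x, tab$y, tab$z, occ, 0, toupper(elem))
  writeLines(c(lines, "END"), outfile)
  invisible(outfile)
}
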
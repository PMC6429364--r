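# PDB and PQR I/O. Parsing and fixed-width record formatting are delegated
# to bio3d; mt_structure adds charge/radius/segment/group annotation on top.

#' Read a structure from a PDB file
#'
#' ATOM/HETATM records are read in file order; in multi-model files the
#' first model is used. Elements are inferred from the atom name when the
#' element column is blank; van der Waals radii come from a bundled
#' per-element table and charges default to zero (see [assign_ionization()]
#' and [read_pqr()] for charge assignment).
#'
#' @param path PDB file.
#' @return An `mt_structure`.
#' @export
read_structure <- function(path) {
  check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  mt_structure(tibble(
    eleno = a$eleno, elety = trimws(a$elety),
    element = ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                     infer_element(a$elety), toupper(trimws(a$elesy))),
    x = a$x, y = a$y, z = a$z,
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, resname = trimws(a$resid)
  ))
}

# cheap structural sanity scan so malformed records fail with a line number
check_pdb_records <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0("empty PDB file: ", path))
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) abort(paste0("no ATOM/HETATM records in: ", path))
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(sprintf("malformed PDB record at line %d (too short)", i))
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      abort(sprintf("malformed PDB record at line %d (bad coordinates)", i))
    }
  }
  invisible(TRUE)
}

#' Write a structure to a PDB file
#'
#' @param s an `mt_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(s))),
                   type = rep("ATOM", nrow(s)),
                   eleno = s$eleno, elety = s$elety,
                   resno = s$resno, resid = s$resname, chain = s$chain,
                   elesy = s$element)
  invisible(path)
}

#' Read a PQR-dialect file
#'
#' Whitespace-separated ATOM records where the occupancy and B-factor
#' columns are replaced by per-atom partial charge and radius. A chain
#' column may or may not be present; both layouts are accepted.
#'
#' @param path PQR file.
#' @return An `mt_structure` with `charge` and `radius` taken from the file.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(lines) == 0) abort(paste0("no ATOM records in: ", path))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (!all(nf %in% c(10L, 11L))) {
    abort(sprintf("malformed PQR record at line %d (expected 10 or 11 fields)",
                  which(!nf %in% c(10L, 11L))[1]))
  }
  parse_row <- function(f) {
    has_chain <- length(f) == 11L
    tibble(
      eleno = as.integer(f[2]), elety = f[3], resname = f[4],
      chain = if (has_chain) f[5] else "",
      resno = as.integer(f[if (has_chain) 6 else 5]),
      x = as.numeric(f[if (has_chain) 7 else 6]),
      y = as.numeric(f[if (has_chain) 8 else 7]),
      z = as.numeric(f[if (has_chain) 9 else 8]),
      charge = as.numeric(f[if (has_chain) 10 else 9]),
      radius = as.numeric(f[if (has_chain) 11 else 10])
    )
  }
  mt_structure(bind_rows(lapply(fields, parse_row)))
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame over the shared topology; coordinates
#' are lossless to the format's 3-decimal precision. With `by_run = TRUE`
#' one file per replicate run is written (suffix `_run<k>`), preserving
#' run identity.
#'
#' @param e an `mt_ensemble`.
#' @param path output file (used as a stem when `by_run = TRUE`).
#' @param by_run write one file per replicate run.
#' @return The written path(s), invisibly.
#' @export
write_ensemble <- function(e, path, by_run = FALSE) {
  stopifnot(inherits(e, "mt_ensemble"))
  if (by_run) {
    stem <- sub("\\.pdb$", "", path)
    paths <- character(0)
    for (r in unique(e$run)) {
      p <- sprintf("%s_run%d.pdb", stem, r)
      write_model_blocks(e, which(e$run == r), p)
      paths <- c(paths, p)
    }
    return(invisible(paths))
  }
  write_model_blocks(e, seq_len(n_frames(e)), path)
  invisible(path)
}

write_model_blocks <- function(e, frame_ids, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  s <- e$topology
  for (fi in frame_ids) {
    writeLines(sprintf("MODEL     %4d", fi), con)
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = tmp,
                     xyz = as.vector(t(e$xyz[fi, , ])),
                     type = rep("ATOM", nrow(s)),
                     eleno = s$eleno, elety = s$elety,
                     resno = s$resno, resid = s$resname, chain = s$chain,
                     elesy = s$element, end = FALSE)
    writeLines(readLines(tmp, warn = FALSE), con)
    unlink(tmp)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

#' Read an ensemble from a multi-model PDB file
#'
#' @param path multi-model PDB file.
#' @param run run label to assign to all frames (default 1).
#' @return An `mt_ensemble`.
#' @export
read_ensemble <- function(path, run = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- read_structure(path)
  nfr <- nrow(pdb$xyz)
  xyz <- array(0, dim = c(nfr, nrow(topo), 3))
  for (fi in seq_len(nfr)) {
    xyz[fi, , ] <- matrix(pdb$xyz[fi, ], ncol = 3, byrow = TRUE)
  }
  mt_ensemble(topo, xyz, run = rep(as.integer(run), nfr))
}
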
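#' Create an atom set
#'
#' The basic container for a structure: one ball per atom, with centers and
#' radii in Angstrom and optional per-atom labels used for lumen annotation.
#'
#' @param centers numeric matrix (n x 3) of atom centers, Angstrom.
#' @param radii numeric vector of positive atom radii, Angstrom.
#' @param labels optional data.frame with columns `atom`, `resid`, `resno`,
#'   `chain` (one row per atom); `NULL` for unlabeled input such as xyzr.
#' @return an object of class `atom_set`.
#' @export
atom_set <- function(centers, radii, labels = NULL) {
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  if (ncol(centers) != 3L) stop("centers must have 3 columns")
  if (length(radii) != nrow(centers))
    stop("centers and radii lengths differ")
  if (!all(is.finite(centers))) stop("non-finite atom coordinates")
  if (!all(is.finite(radii)) || any(radii <= 0))
    stop("atom radii must be positive and finite")
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (nrow(labels) != nrow(centers))
      stop("labels must have one row per atom")
  }
  structure(list(centers = centers, radii = as.double(radii),
                 labels = labels),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms, radii %.2f-%.2f A%s\n",
              nrow(x$centers), min(x$radii), max(x$radii),
              if (is.null(x$labels)) " (unlabeled)" else ""))
  invisible(x)
}

#' Read an xyzr file
#'
#' One atom per non-empty line, whitespace-separated `x y z r` (Angstrom).
#' Lines starting with `#` are comments; extra trailing columns are ignored.
#'
#' @param path path to an xyzr file.
#' @return an [atom_set] with empty labels.
#' @export
read_xyzr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("no atom records in ", path)
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(fields) < 4L)
      stop(sprintf("line %d: expected at least 4 fields, got %d",
                   i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields[1:4]))
    if (anyNA(vals))
      stop(sprintf("line %d: non-numeric field in '%s'", i, lines[i]))
    vals
  })
  m <- do.call(rbind, rows)
  if (any(m[, 4L] <= 0))
    stop("non-positive radius at line ",
         keep[which(m[, 4L] <= 0)[1L]])
  atom_set(m[, 1:3, drop = FALSE], m[, 4L])
}

#' Write an xyzr file
#'
#' @param atoms an [atom_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyzr <- function(atoms, path) {
  m <- cbind(atoms$centers, atoms$radii)
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.6f", r),
                                            collapse = " ")), path)
  invisible(path)
}

#' Per-element van der Waals radius table
#'
#' Bundled fallback radii (Angstrom) used to annotate PDB atoms; specific
#' `(residue, atom)` overrides can be layered on top with a CSV file whose
#' columns are `resid`, `atom`, `radius`.
#'
#' @param overrides optional path to a CSV of per-(residue, atom) radii.
#' @param default radius assigned to unrecognized elements.
#' @return a `radius_table` object with a `$lookup(resid, atom, element)`
#'   function returning one radius per atom and logging unknown atoms.
#' @export
radius_table <- function(overrides = NULL, default = 1.7) {
  element_r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                 K = 2.75, NA_ = 2.27, MG = 1.73, CA = 2.31, ZN = 1.39,
                 FE = 1.95, MN = 1.96, CU = 1.40)
  over <- NULL
  if (!is.null(overrides)) {
    over <- read.csv(overrides, stringsAsFactors = FALSE)
    need <- c("resid", "atom", "radius")
    if (!all(need %in% names(over)))
      stop("override CSV must have columns resid, atom, radius")
    if (any(over$radius <= 0)) stop("override radii must be positive")
  }
  lookup <- function(resid, atom, element = NULL) {
    n <- length(atom)
    r <- rep(NA_real_, n)
    if (!is.null(over) && nrow(over) > 0L) {
      key <- paste(toupper(resid), toupper(atom))
      okey <- paste(toupper(over$resid), toupper(over$atom))
      hit <- match(key, okey)
      r[!is.na(hit)] <- over$radius[hit[!is.na(hit)]]
    }
    miss <- which(is.na(r))
    if (length(miss)) {
      el <- if (!is.null(element)) toupper(element[miss]) else rep("", length(miss))
      # fall back to guessing the element from the atom name
      guess <- toupper(sub("^[0-9]*", "", atom[miss]))
      el[!nzchar(el)] <- substr(guess[!nzchar(el)], 1L, 1L)
      el[el == "NA"] <- "NA_"
      r2 <- element_r[el]
      unk <- is.na(r2)
      # two-letter element symbols (CL, BR, ...) hidden in atom names
      if (any(unk)) {
        two <- substr(guess[unk], 1L, 2L)
        r2[unk] <- element_r[two]
      }
      still <- is.na(r2)
      if (any(still)) {
        message(sum(still), " atom(s) with unknown element assigned default ",
                "radius ", default, " A")
        r2[still] <- default
      }
      r[miss] <- unname(r2)
    }
    r
  }
  structure(list(lookup = lookup, default = default,
                 elements = element_r), class = "radius_table")
}

#' Read frames from a (multi-model) PDB file
#'
#' Parses `ATOM`/`HETATM` records with [bio3d::read.pdb()], drops solvent and
#' ion residues, and assigns one radius per atom from a radius table.  A
#' model-less file yields a single frame.
#'
#' @param path path to a PDB file.
#' @param table a [radius_table]; the bundled element table by default.
#' @param exclude residue names to drop (waters and common ions by default).
#' @return list of [atom_set] objects, one per MODEL.
#' @export
read_pdb_frames <- function(path, table = radius_table(),
                            exclude = c("HOH", "WAT", "TIP3", "SOL", "K",
                                        "CL", "NA", "MG", "CA", "ZN",
                                        "POT", "CLA", "SOD")) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- !(toupper(at$resid) %in% toupper(exclude))
  if (!any(keep))
    stop("no atoms left after excluding solvent/ion residues")
  at <- at[keep, , drop = FALSE]
  radii <- table$lookup(at$resid, at$elety, at$elesy)
  labels <- data.frame(atom = at$elety, resid = at$resid,
                       resno = at$resno, chain = at$chain,
                       stringsAsFactors = FALSE)
  nframes <- nrow(pdb$xyz)
  xyz_idx <- bio3d::atom2xyz(which(keep))
  lapply(seq_len(nframes), function(f) {
    co <- matrix(pdb$xyz[f, xyz_idx], ncol = 3L, byrow = TRUE)
    atom_set(co, radii, labels)
  })
}
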
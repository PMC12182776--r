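#' @importFrom stats sd complete.cases setNames cor quantile rnorm runif
#' @importFrom utils read.table write.table
NULL

# let data.table's `[` dispatch work from this namespace
.datatable.aware <- TRUE

# ---- chemistry tables -------------------------------------------------------

# Side-chain polarity classes. His is treated as charged and Trp as polar by
# default (the convention used by contact-based affinity models); both are
# overridable through classify_residue() arguments.
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.POLARITY <- c(
  ARG = "charged", LYS = "charged", ASP = "charged", GLU = "charged",
  HIS = "charged",
  ASN = "polar", GLN = "polar", SER = "polar", THR = "polar",
  TYR = "polar", CYS = "polar", TRP = "polar",
  ALA = "apolar", GLY = "apolar", ILE = "apolar", LEU = "apolar",
  MET = "apolar", PHE = "apolar", PRO = "apolar", VAL = "apolar")

# van der Waals radii by element (Angstrom); config-overridable in sasa().
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)

# Theoretical maximum residue SASA (Angstrom^2), used for relative exposure.
.MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
               GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
               LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
               SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

.WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Classify residues by side-chain polarity
#'
#' Maps three-letter residue codes onto the charged / polar / apolar
#' partition used to type intermolecular contacts. Histidine is charged and
#' tryptophan polar by default; both assignments can be switched because
#' published class tables differ on them.
#'
#' @param name3 character vector of three-letter residue codes.
#' @param his_charged treat HIS as charged (`TRUE`, default) or polar.
#' @param trp_polar treat TRP as polar (`TRUE`, default) or apolar.
#' @return character vector of classes among `"charged"`, `"polar"`,
#'   `"apolar"`; unrecognized codes yield `"unknown"` (never silently
#'   apolar).
#' @examples
#' classify_residue(c("ARG", "SER", "LEU"))
#' @export
classify_residue <- function(name3, his_charged = TRUE, trp_polar = TRUE) {
  tab <- .POLARITY
  if (!his_charged) tab[["HIS"]] <- "polar"
  if (!trp_polar) tab[["TRP"]] <- "apolar"
  out <- unname(tab[toupper(name3)])
  out[is.na(out)] <- "unknown"
  out
}

# ---- structure container ----------------------------------------------------

.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "element",
                "x", "y", "z", "o", "b")

#' Construct a structure object from an atom table
#'
#' The container is a flat atom-level data frame (one row per atom) in the
#' style of crystallographic toolkits, carrying author chain/residue
#' numbering. Row order defines atom and residue order.
#'
#' @param atoms data frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety` (PDB atom name), `element`, `x`, `y`, `z`, `o` (occupancy),
#'   `b` (B-factor, also reused as an annotation slot).
#' @param id label for the structure.
#' @param source provenance note (file path or entry id).
#' @return an object of class `epi_structure`.
#' @export
new_structure <- function(atoms, id = "", source = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, .ATOM_COLS]
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(is.na(atoms$element) | atoms$element == ""))
    stop("empty element symbols in atom table")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id, source = source),
            class = "epi_structure")
}

#' @export
print.epi_structure <- function(x, ...) {
  ch <- chain_ids(x)
  nres <- vapply(ch, function(cc) {
    a <- x$atoms[x$atoms$chain == cc, ]
    nrow(unique(a[, c("resno", "insert")]))
  }, integer(1))
  cat(sprintf("<epi_structure %s> %d atoms, %d chain(s)\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              nrow(x$atoms), length(ch)))
  cat(paste(sprintf("  chain %s: %d residues", ch, nres), collapse = "\n"),
      "\n")
  invisible(x)
}

#' @export
is_structure <- function(x) inherits(x, "epi_structure")

#' Chain identifiers of a structure
#' @param struct an `epi_structure`.
#' @return character vector of chain ids in order of first appearance.
#' @export
chain_ids <- function(struct) unique(struct$atoms$chain)

#' Atom coordinates as a matrix
#' @param struct an `epi_structure`.
#' @return numeric n x 3 matrix.
#' @export
coords <- function(struct) {
  m <- as.matrix(struct$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

`coords<-` <- function(struct, value) {
  stopifnot(nrow(value) == nrow(struct$atoms), ncol(value) == 3)
  struct$atoms$x <- value[, 1]
  struct$atoms$y <- value[, 2]
  struct$atoms$z <- value[, 3]
  struct
}

# Positional residue identity: chain + author number + insertion code.
.make_key <- function(chain, resno, insert) {
  ic <- ifelse(is.na(insert) | insert == "", "", insert)
  paste0(chain, ":", resno, ic)
}

#' Residue table of a structure
#'
#' One row per residue in atom order, with the positional key used
#' throughout the package for set and frequency operations (the residue
#' name is retained for reporting only).
#'
#' @param struct an `epi_structure`.
#' @return data frame with columns `key`, `chain`, `resno`, `insert`,
#'   `resid`.
#' @export
residue_keys <- function(struct) {
  a <- struct$atoms
  key <- .make_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = a$chain[first],
             resno = a$resno[first], insert = a$insert[first],
             resid = a$resid[first], stringsAsFactors = FALSE)
}

# per-atom residue keys
.atom_keys <- function(struct) {
  .make_key(struct$atoms$chain, struct$atoms$resno, struct$atoms$insert)
}

#' Drop chains from a structure
#'
#' Removes named chains (e.g. a heterodimer partner or bound antibodies
#' before docking). Unknown chain ids are an error, since they usually
#' signal mislabeled input.
#'
#' @param struct an `epi_structure`.
#' @param chain_ids character vector of chain ids to remove (may be empty).
#' @return the structure without the named chains.
#' @export
drop_chains <- function(struct, chain_ids) {
  if (length(chain_ids) == 0) return(struct)
  present <- unique(struct$atoms$chain)
  unknown <- setdiff(chain_ids, present)
  if (length(unknown))
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  keep <- !(struct$atoms$chain %in% chain_ids)
  new_structure(struct$atoms[keep, , drop = FALSE], id = struct$id,
                source = struct$source)
}

#' Keep only the named chains
#' @param struct an `epi_structure`.
#' @param chain_ids chains to retain.
#' @return the reduced structure.
#' @export
keep_chains <- function(struct, chain_ids) {
  present <- unique(struct$atoms$chain)
  unknown <- setdiff(chain_ids, present)
  if (length(unknown))
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  keep <- struct$atoms$chain %in% chain_ids
  new_structure(struct$atoms[keep, , drop = FALSE], id = struct$id,
                source = struct$source)
}

#' Concatenate structures into one
#' @param ... `epi_structure` objects with disjoint chain ids.
#' @param id label for the result.
#' @return combined `epi_structure`.
#' @export
concat_structures <- function(..., id = "") {
  xs <- list(...)
  all_chains <- unlist(lapply(xs, chain_ids))
  if (anyDuplicated(all_chains))
    stop("duplicate chain ids across structures")
  new_structure(do.call(rbind, lapply(xs, function(s) s$atoms)), id = id)
}

#' One-letter sequence of a chain
#'
#' Sequence is taken over residues having a CA atom, in file order;
#' non-standard residues map to `X`.
#'
#' @param struct an `epi_structure`.
#' @param chain chain id.
#' @return list with `sequence` (single string) and `residues` (the residue
#'   table rows, aligned with the sequence).
#' @export
structure_sequence <- function(struct, chain) {
  a <- struct$atoms[struct$atoms$chain == chain & struct$atoms$elety == "CA", ]
  if (!nrow(a)) stop("chain ", chain, " has no CA atoms")
  key <- .make_key(a$chain, a$resno, a$insert)
  a <- a[!duplicated(key), ]
  one <- suppressWarnings(bio3d::aa321(a$resid))
  one[is.na(one) | !nzchar(one)] <- "X"
  list(sequence = paste(one, collapse = ""),
       residues = data.frame(key = .make_key(a$chain, a$resno, a$insert),
                             chain = a$chain, resno = a$resno,
                             insert = a$insert, resid = a$resid,
                             x = a$x, y = a$y, z = a$z,
                             stringsAsFactors = FALSE))
}

# ---- PDB I/O ----------------------------------------------------------------

.guess_element <- function(elety) {
  nm <- gsub("^[0-9 ']+", "", toupper(trimws(elety)))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("SE", "CL", "BR", "FE", "ZN", "MG", "NA", "MN"),
                two, substr(nm, 1, 1))
  # distal hydrogens named like "HG1" start with H already; nothing else to do
  out
}

#' Read a PDB file into a structure
#'
#' ATOM records are parsed into the atom-table hierarchy. Alternate
#' locations are resolved to the highest-occupancy conformer (ties go to
#' the first encountered). Waters are always excluded; other HETATM groups
#' (ligands, glycans) are excluded unless `keep_het = TRUE`. Hydrogens are
#' retained in the table but excluded from distance work downstream by
#' default.
#'
#' @param path PDB file path.
#' @param model model number for multi-model files (1-based; default 1).
#' @param keep_het retain non-water HETATM records (default `FALSE`).
#' @return an `epi_structure`.
#' @export
read_pdb <- function(path, model = 1, keep_het = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  src <- path
  if (length(model_starts)) {
    if (model > length(model_starts))
      stop("requested model ", model, " but file has only ",
           length(model_starts), " model(s)")
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(model_starts)) ends <- c(ends, length(lines))
    block <- lines[(model_starts[model] + 1):(ends[model] - 1)]
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(block, "END"), tmp)
    pdb_path <- tmp
  } else {
    if (model != 1)
      stop("requested model ", model, " but file has a single model")
    pdb_path <- path
  }
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(pdb_path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # waters out unconditionally; HETATM optional
  at <- at[!(toupper(at$resid) %in% .WATER_RESIDUES), , drop = FALSE]
  if (!keep_het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no polymer ATOM records retained from ", path)
  # altloc resolution: highest occupancy, ties -> first occurrence
  at$o[is.na(at$o)] <- 1
  gid <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(gid, levels = unique(gid)), -at$o,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]
  # restore original file order
  at <- at[order(as.numeric(rownames(at))), , drop = FALSE]
  element <- toupper(trimws(at$elesy))
  bad <- is.na(element) | element == ""
  element[bad] <- .guess_element(at$elety[bad])
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = at$insert, resid = at$resid,
                      elety = at$elety, element = element,
                      x = at$x, y = at$y, z = at$z,
                      o = at$o, b = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  new_structure(atoms, id = sub("\\.pdb$", "", basename(path)), source = src)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM records (occupancy and B-factor with two
#' decimals, coordinates with three), with TER records between chains.
#' `read_pdb(write_pdb(s))` preserves chains, residue keys and heavy-atom
#' coordinates to three decimals.
#'
#' @param struct an `epi_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(struct, path) {
  a <- struct$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = a$chain, insert = ifelse(a$insert == "", NA,
                                                      a$insert),
                     o = a$o, b = a$b, elesy = a$element,
                     chainter = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write PDB to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Apply a rigid transform to a structure
#'
#' @param struct an `epi_structure`.
#' @param rotation 3 x 3 proper rotation matrix (row-vector convention:
#'   `y = x %*% rotation + translation`).
#' @param translation length-3 numeric vector (Angstrom).
#' @return transformed structure.
#' @export
transform_structure <- function(struct, rotation, translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  xyz <- coords(struct) %*% rotation
  xyz <- sweep(xyz, 2, translation, `+`)
  coords(struct) <- xyz
  struct
}

# random proper rotation (used by the synthetic module and tests)
.random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
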
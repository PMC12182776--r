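# Geometric interface characterization: distance contacts, contact typing,
# hydrogen bonds, salt bridges, and solvent-accessible surface area.

#' Contact-detection configuration
#'
#' @param residue_cutoff distance (Angstrom) defining an interface residue,
#'   inclusive at the boundary (default 2.5).
#' @param imc_cutoff distance defining an intermolecular contact, strict at
#'   the boundary (default 5.5).
#' @param heavy_only exclude hydrogens from all distance work (default
#'   `TRUE`; docking inputs derived from EM structures carry no reliable
#'   hydrogens).
#' @return a list of class `contact_config`.
#' @export
contact_config <- function(residue_cutoff = 2.5, imc_cutoff = 5.5,
                           heavy_only = TRUE) {
  stopifnot(residue_cutoff > 0, residue_cutoff <= imc_cutoff)
  structure(list(residue_cutoff = residue_cutoff, imc_cutoff = imc_cutoff,
                 heavy_only = heavy_only), class = "contact_config")
}

# ---- spatial index ----------------------------------------------------------

# Cell-list neighbor search: returns all index pairs (i from A, j from B)
# with Euclidean distance <= cutoff. Atoms are hashed to cubic cells of
# edge `cutoff`; candidates come from the 27 neighboring cells of each B
# atom, found by a keyed data.table join.
.neighbor_pairs <- function(a_xyz, b_xyz, cutoff) {
  stopifnot(cutoff > 0)
  na <- nrow(a_xyz); nb <- nrow(b_xyz)
  if (na == 0 || nb == 0)
    return(data.table::data.table(i = integer(0), j = integer(0),
                                  dist = numeric(0)))
  h <- cutoff
  A <- data.table::data.table(
    i = seq_len(na),
    cx = as.integer(floor(a_xyz[, 1] / h)),
    cy = as.integer(floor(a_xyz[, 2] / h)),
    cz = as.integer(floor(a_xyz[, 3] / h)))
  data.table::setkey(A, cx, cy, cz)
  offs <- as.matrix(expand.grid(ox = -1:1, oy = -1:1, oz = -1:1))
  K <- nrow(offs)
  bx <- as.integer(floor(b_xyz[, 1] / h))
  by <- as.integer(floor(b_xyz[, 2] / h))
  bz <- as.integer(floor(b_xyz[, 3] / h))
  Bexp <- data.table::data.table(
    j = rep(seq_len(nb), each = K),
    cx = rep(bx, each = K) + rep.int(offs[, 1], nb),
    cy = rep(by, each = K) + rep.int(offs[, 2], nb),
    cz = rep(bz, each = K) + rep.int(offs[, 3], nb))
  cand <- A[Bexp, on = c("cx", "cy", "cz"), nomatch = NULL,
            allow.cartesian = TRUE]
  if (!nrow(cand))
    return(data.table::data.table(i = integer(0), j = integer(0),
                                  dist = numeric(0)))
  d2 <- (a_xyz[cand$i, 1] - b_xyz[cand$j, 1])^2 +
        (a_xyz[cand$i, 2] - b_xyz[cand$j, 2])^2 +
        (a_xyz[cand$i, 3] - b_xyz[cand$j, 3])^2
  keep <- d2 <= cutoff * cutoff
  data.table::data.table(i = cand$i[keep], j = cand$j[keep],
                         dist = sqrt(d2[keep]))
}

# atom rows included in distance work
.included <- function(struct, heavy_only) {
  a <- struct$atoms
  if (heavy_only) a <- a[toupper(a$element) != "H", , drop = FALSE]
  if (!nrow(a)) stop("structure has no atoms after hydrogen filtering")
  a
}

# ---- contacts ---------------------------------------------------------------

#' Receptor residues in contact with a ligand
#'
#' A receptor residue is an interface residue when at least one of its
#' included atoms lies within `cutoff` (inclusive) of any included ligand
#' atom — the rule used to build per-pose contact-residue lists.
#'
#' @param receptor,ligand `epi_structure` objects (the two binding
#'   partners).
#' @param cutoff distance in Angstrom (default 2.5, inclusive).
#' @param heavy_only exclude hydrogens (default `TRUE`).
#' @return residue table (as [residue_keys()]) of contacting receptor
#'   residues, with a `min_distance` column.
#' @export
contact_residues <- function(receptor, ligand, cutoff = 2.5,
                             heavy_only = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ra <- .included(receptor, heavy_only)
  la <- .included(ligand, heavy_only)
  pr <- .neighbor_pairs(as.matrix(ra[, c("x", "y", "z")]),
                        as.matrix(la[, c("x", "y", "z")]), cutoff)
  empty <- data.frame(key = character(0), chain = character(0),
                      resno = integer(0), insert = character(0),
                      resid = character(0), min_distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pr)) return(empty)
  rkey <- .make_key(ra$chain, ra$resno, ra$insert)
  dt <- data.table::data.table(k = rkey[pr$i], dist = pr$dist)
  agg <- dt[, list(min_distance = min(dist)), by = "k"]
  data.table::setnames(agg, "k", "key")
  first <- !duplicated(rkey)
  info <- data.frame(key = rkey[first], chain = ra$chain[first],
                     resno = ra$resno[first], insert = ra$insert[first],
                     resid = ra$resid[first], stringsAsFactors = FALSE)
  out <- merge(info, as.data.frame(agg), by = "key", sort = FALSE)
  out <- out[order(match(out$key, info$key)), ]
  rownames(out) <- NULL
  out
}

#' Intermolecular residue-residue contacts with polarity typing
#'
#' One contact per receptor-ligand residue pair having at least one
#' included atom pair closer than `cutoff` (strict by default, matching the
#' "less than 5.5 A" convention). Each pair carries the minimum atom-atom
#' distance and the polarity classes of both partners.
#'
#' @param receptor,ligand `epi_structure` objects.
#' @param cutoff distance in Angstrom (default 5.5).
#' @param heavy_only exclude hydrogens (default `TRUE`).
#' @param boundary `"strict"` (`<`, default) or `"inclusive"` (`<=`).
#' @param his_charged,trp_polar forwarded to [classify_residue()].
#' @return data frame of contacts: receptor/ligand keys and residue names,
#'   `min_distance`, `class_receptor`, `class_ligand` and the unordered
#'   `class_pair` label (e.g. `"charged-polar"`).
#' @export
intermolecular_contacts <- function(receptor, ligand, cutoff = 5.5,
                                    heavy_only = TRUE,
                                    boundary = c("strict", "inclusive"),
                                    his_charged = TRUE, trp_polar = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  boundary <- match.arg(boundary)
  ra <- .included(receptor, heavy_only)
  la <- .included(ligand, heavy_only)
  pr <- .neighbor_pairs(as.matrix(ra[, c("x", "y", "z")]),
                        as.matrix(la[, c("x", "y", "z")]), cutoff)
  empty <- data.frame(receptor_key = character(0),
                      receptor_resid = character(0),
                      ligand_key = character(0),
                      ligand_resid = character(0),
                      min_distance = numeric(0),
                      class_receptor = character(0),
                      class_ligand = character(0),
                      class_pair = character(0), stringsAsFactors = FALSE)
  if (!nrow(pr)) return(empty)
  rkey <- .make_key(ra$chain, ra$resno, ra$insert)
  lkey <- .make_key(la$chain, la$resno, la$insert)
  dt <- data.table::data.table(rk = rkey[pr$i], lk = lkey[pr$j],
                               dist = pr$dist)
  agg <- as.data.frame(dt[, list(min_distance = min(dist)),
                          by = c("rk", "lk")])
  if (boundary == "strict") agg <- agg[agg$min_distance < cutoff, ,
                                       drop = FALSE]
  if (!nrow(agg)) return(empty)
  rres <- ra$resid[match(agg$rk, rkey)]
  lres <- la$resid[match(agg$lk, lkey)]
  cr <- classify_residue(rres, his_charged, trp_polar)
  cl <- classify_residue(lres, his_charged, trp_polar)
  pair <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "-"),
                 cr, cl, USE.NAMES = FALSE)
  out <- data.frame(receptor_key = agg$rk, receptor_resid = rres,
                    ligand_key = agg$lk, ligand_resid = lres,
                    min_distance = agg$min_distance,
                    class_receptor = cr, class_ligand = cl,
                    class_pair = pair, stringsAsFactors = FALSE)
  out <- out[order(out$receptor_key, out$ligand_key), ]
  rownames(out) <- NULL
  out
}

#' Summarize typed contacts
#'
#' Two roll-ups of the class-pair contact counts are reported because both
#' readings of a charged/polar/apolar breakdown occur in practice: counts
#' per unordered class pair, and per-class participation (contacts
#' involving at least one residue of that class).
#'
#' @param contacts output of [intermolecular_contacts()].
#' @return list with `total`, `by_pair` (named counts for the six
#'   unordered pairs) and `participation` (named counts for the three
#'   classes).
#' @export
contact_class_summary <- function(contacts) {
  pairs <- c("apolar-apolar", "apolar-charged", "apolar-polar",
             "charged-charged", "charged-polar", "polar-polar")
  by_pair <- setNames(integer(length(pairs)), pairs)
  tb <- table(contacts$class_pair)
  by_pair[names(tb)[names(tb) %in% pairs]] <-
    as.integer(tb[names(tb) %in% pairs])
  classes <- c("charged", "polar", "apolar")
  participation <- vapply(classes, function(cl)
    sum(contacts$class_receptor == cl | contacts$class_ligand == cl),
    integer(1))
  list(total = nrow(contacts), by_pair = by_pair,
       participation = participation)
}

# ---- hydrogen bonds ---------------------------------------------------------

# Heavy-atom donor/acceptor assignments for the 20 standard residues.
# Backbone: N donates (except proline), O and OXT accept.
.SC_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", HIS = c("ND1",
  "NE2"), LYS = "NZ", SER = "OG", THR = "OG1", TRP = "NE1", TYR = "OH",
  CYS = "SG")
.SC_ACCEPTORS <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

.hb_atoms <- function(struct, role) {
  a <- .included(struct, heavy_only = TRUE)
  key <- .make_key(a$chain, a$resno, a$insert)
  tab <- if (role == "donor") .SC_DONORS else .SC_ACCEPTORS
  sc <- mapply(function(res, ety) ety %in% (tab[[res]] %||% character(0)),
               a$resid, a$elety, USE.NAMES = FALSE)
  bb <- if (role == "donor") {
    a$elety == "N" & a$resid != "PRO"
  } else {
    a$elety %in% c("O", "OXT")
  }
  idx <- which(sc | bb)
  data.frame(key = key[idx], resid = a$resid[idx], atom = a$elety[idx],
             x = a$x[idx], y = a$y[idx], z = a$z[idx],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric hydrogen bonds across an interface
#'
#' Donor-acceptor heavy-atom pairs on opposite binding partners within
#' `cutoff` (default 3.5 Angstrom). The criterion is distance-only because
#' docking inputs usually lack hydrogens; donors and acceptors follow
#' standard residue chemistry (backbone N donates except in proline,
#' backbone O accepts).
#'
#' @param receptor,ligand `epi_structure` objects.
#' @param cutoff donor-acceptor distance cutoff (default 3.5, inclusive).
#' @return data frame with donor/acceptor residue keys, atom names,
#'   `distance`, and `donor_side` (`"receptor"` or `"ligand"`).
#' @export
hydrogen_bonds <- function(receptor, ligand, cutoff = 3.5) {
  one_way <- function(don, acc, side) {
    if (!nrow(don) || !nrow(acc)) return(NULL)
    pr <- .neighbor_pairs(as.matrix(don[, c("x", "y", "z")]),
                          as.matrix(acc[, c("x", "y", "z")]), cutoff)
    if (!nrow(pr)) return(NULL)
    data.frame(donor_key = don$key[pr$i], donor_atom = don$atom[pr$i],
               acceptor_key = acc$key[pr$j],
               acceptor_atom = acc$atom[pr$j],
               distance = pr$dist, donor_side = side,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_way(.hb_atoms(receptor, "donor"), .hb_atoms(ligand, "acceptor"),
            "receptor"),
    one_way(.hb_atoms(ligand, "donor"), .hb_atoms(receptor, "acceptor"),
            "ligand"))
  if (is.null(out))
    out <- data.frame(donor_key = character(0), donor_atom = character(0),
                      acceptor_key = character(0),
                      acceptor_atom = character(0), distance = numeric(0),
                      donor_side = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$donor_key, out$acceptor_key, out$donor_atom,
                   out$acceptor_atom), ]
  rownames(out) <- NULL
  out
}

# ---- salt bridges -----------------------------------------------------------

# charged-group centers; residues with missing side-chain atoms are skipped
.charge_centers <- function(struct, his_charged = TRUE) {
  defs <- list(
    ARG = list(type = "basic", atoms = c("CZ", "NH1", "NH2")),
    LYS = list(type = "basic", atoms = "NZ"),
    ASP = list(type = "acidic", atoms = c("OD1", "OD2")),
    GLU = list(type = "acidic", atoms = c("OE1", "OE2")))
  if (his_charged)
    defs$HIS <- list(type = "basic", atoms = c("ND1", "NE2"))
  a <- .included(struct, heavy_only = TRUE)
  key <- .make_key(a$chain, a$resno, a$insert)
  rows <- list()
  skipped <- character(0)
  for (k in unique(key[a$resid %in% names(defs)])) {
    sel <- a[key == k, , drop = FALSE]
    def <- defs[[sel$resid[1]]]
    grp <- sel[sel$elety %in% def$atoms, , drop = FALSE]
    if (nrow(grp) < length(def$atoms)) {
      skipped <- c(skipped, k)
      next
    }
    rows[[k]] <- data.frame(key = k, resid = sel$resid[1],
                            type = def$type, x = mean(grp$x),
                            y = mean(grp$y), z = mean(grp$z),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("salt-bridge centers skipped for residues with missing ",
            "side-chain atoms: ", paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(key = character(0), resid = character(0),
                      type = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Geometric salt bridges across an interface
#'
#' Basic (Arg/Lys, plus His when `his_charged`) and acidic (Asp/Glu)
#' side-chain charge centers on opposite partners within `cutoff` of each
#' other. Centers are the guanidinium centroid (Arg), NZ (Lys), ring-N
#' centroid (His) and carboxylate centroids (Asp/Glu).
#'
#' @param receptor,ligand `epi_structure` objects.
#' @param cutoff center-center distance cutoff (default 5.5, inclusive).
#' @param his_charged count His as basic (default `TRUE`).
#' @return data frame with `basic_key`, `acidic_key`, residue names,
#'   `center_distance` and `basic_side`.
#' @export
salt_bridges <- function(receptor, ligand, cutoff = 5.5,
                         his_charged = TRUE) {
  rc <- .charge_centers(receptor, his_charged)
  lc <- .charge_centers(ligand, his_charged)
  one_way <- function(bas, aci, side) {
    if (!nrow(bas) || !nrow(aci)) return(NULL)
    pr <- .neighbor_pairs(as.matrix(bas[, c("x", "y", "z")]),
                          as.matrix(aci[, c("x", "y", "z")]), cutoff)
    if (!nrow(pr)) return(NULL)
    data.frame(basic_key = bas$key[pr$i], basic_resid = bas$resid[pr$i],
               acidic_key = aci$key[pr$j], acidic_resid = aci$resid[pr$j],
               center_distance = pr$dist, basic_side = side,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_way(rc[rc$type == "basic", ], lc[lc$type == "acidic", ],
            "receptor"),
    one_way(lc[lc$type == "basic", ], rc[rc$type == "acidic", ],
            "ligand"))
  if (is.null(out))
    out <- data.frame(basic_key = character(0), basic_resid = character(0),
                      acidic_key = character(0),
                      acidic_resid = character(0),
                      center_distance = numeric(0),
                      basic_side = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$basic_key, out$acidic_key), ]
  rownames(out) <- NULL
  out
}

# ---- solvent-accessible surface area ---------------------------------------

# deterministic quasi-uniform sphere points (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Accessibility of each heavy atom is the fraction of `n_points`
#' quasi-uniform test points on its solvent-expanded sphere not buried in
#' any neighboring sphere, times the expanded-sphere area. Test points
#' lying exactly on a neighbor's surface (within 1e-6 Angstrom) count as
#' half-exposed, so coincident identical spheres share their surface
#' symmetrically.
#'
#' @param struct an `epi_structure`.
#' @param probe solvent probe radius (default 1.4 Angstrom).
#' @param n_points test points per atom (default 960).
#' @param radii named vector of van der Waals radii by element symbol;
#'   unknown elements fall back to 1.70 with a warning.
#' @return list with `per_atom` (Angstrom^2 per included atom, in atom
#'   order), `per_residue` (residue table with `sasa` column) and `total`.
#' @export
sasa <- function(struct, probe = 1.4, n_points = 960, radii = .VDW_RADII) {
  stopifnot(probe > 0, n_points >= 100)
  a <- .included(struct, heavy_only = TRUE)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  el <- toupper(a$element)
  r <- unname(radii[el])
  if (anyNA(r)) {
    warning("unknown vdW radius for element(s): ",
            paste(unique(el[is.na(r)]), collapse = ", "),
            "; using 1.70 A")
    r[is.na(r)] <- 1.70
  }
  re <- r + probe
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  nb <- .neighbor_pairs(xyz, xyz, max(re) * 2)
  nb <- nb[nb$i != nb$j & nb$dist < re[nb$i] + re[nb$j], ]
  nb_list <- split(nb$j, factor(nb$i, levels = seq_len(n)))
  tol <- 1e-6
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    js <- nb_list[[i]]
    sp <- pts * re[i]
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    w <- rep(1, n_points)
    for (j in js) {
      d <- sqrt((sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
                (sp[, 3] - xyz[j, 3])^2)
      inside <- d < re[j] - tol
      boundary <- !inside & d <= re[j] + tol
      w[inside] <- 0
      w[boundary] <- pmin(w[boundary], 0.5)
    }
    per_atom[i] <- mean(w) * 4 * pi * re[i]^2
  }
  key <- .make_key(a$chain, a$resno, a$insert)
  dt <- data.table::data.table(k = key, sasa = per_atom)
  agg <- as.data.frame(dt[, list(sasa = sum(sasa)), by = "k"])
  names(agg)[1] <- "key"
  first <- !duplicated(key)
  per_res <- data.frame(key = key[first], chain = a$chain[first],
                        resno = a$resno[first], insert = a$insert[first],
                        resid = a$resid[first], stringsAsFactors = FALSE)
  per_res <- merge(per_res, agg, by = "key", sort = FALSE)
  per_res <- per_res[order(match(per_res$key, key[first])), ]
  rownames(per_res) <- NULL
  list(per_atom = per_atom, per_residue = per_res, total = sum(per_atom))
}

#' Non-interacting-surface composition of a complex
#'
#' Surface residues of the bound complex (relative SASA above
#' `rel_cutoff` of the residue's theoretical maximum) are by construction
#' outside the interface; their percentage composition by polarity class
#' feeds the contact-based affinity model.
#'
#' @param receptor,ligand `epi_structure` objects forming the complex.
#' @param rel_cutoff relative-SASA exposure threshold (default 0.05).
#' @param probe,n_points passed to [sasa()].
#' @param his_charged,trp_polar passed to [classify_residue()].
#' @return named numeric vector `c(apolar = %, charged = %)` with
#'   attribute `n_nis` (number of surface residues).
#' @export
nis_fractions <- function(receptor, ligand, rel_cutoff = 0.05,
                          probe = 1.4, n_points = 960,
                          his_charged = TRUE, trp_polar = TRUE) {
  complex_ <- concat_structures(receptor, ligand, id = "complex")
  sr <- sasa(complex_, probe = probe, n_points = n_points)
  pr <- sr$per_residue
  mx <- .MAX_SASA[pr$resid]
  mx[is.na(mx)] <- mean(.MAX_SASA)
  rel <- pr$sasa / mx
  nis <- pr[rel > rel_cutoff, , drop = FALSE]
  if (!nrow(nis))
    stop("degenerate input: no solvent-exposed residues found")
  cls <- classify_residue(nis$resid, his_charged, trp_polar)
  out <- c(apolar = 100 * mean(cls == "apolar"),
           charged = 100 * mean(cls == "charged"))
  attr(out, "n_nis") <- nrow(nis)
  out
}
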
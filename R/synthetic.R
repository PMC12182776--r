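# Synthetic receptors and docking-pose ensembles with planted epitopes.
#
# The generator emulates the statistical structure of a ranked
# protein-protein docking output: an ordered set of poses in one receptor
# frame, an epitope patch contacted with elevated probability, sparse
# background (decoy) contacts elsewhere, a two-chain antibody ligand and a
# rank-consistent score column. Contacts are planted geometrically (ligand
# pseudo-atoms placed at sampled distances inside the contact cutoff) so
# the pipeline is exercised through real distance computation.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline targets: ensembles of
#' 100 ranked models, an epitope of two 12-residue patches plus one
#' 3-residue patch, epitope contact probability 0.3 against a 0.02
#' background, and a two-chain ligand.
#'
#' @param seed integer RNG seed; identical configurations reproduce
#'   identical ensembles.
#' @param n_receptor_residues receptor length (default 200; numbering
#'   starts at 23, the first residue after a cleaved signal peptide).
#' @param n_models number of poses (default 100).
#' @param epitope integer vector of 1-based residue indices along the
#'   chain; default two patches of 12 and one of 3, mutually well
#'   separated.
#' @param epitope_contact_prob per-pose contact probability for epitope
#'   residues (default 0.3).
#' @param background_contact_prob same for non-epitope residues
#'   (default 0.02).
#' @param ligand_chains two ligand chain ids (default H, L).
#' @param score_noise_sd score noise SD (default 1). Scores carry no
#'   information about contact truth; set `couple_scores = TRUE` to make
#'   better-ranked poses more epitope-faithful.
#' @param couple_scores couple scores to planted contacts (default
#'   `FALSE`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_receptor_residues = 200, n_models = 100,
                       epitope = NULL, epitope_contact_prob = 0.3,
                       background_contact_prob = 0.02,
                       ligand_chains = c("H", "L"), score_noise_sd = 1,
                       couple_scores = FALSE) {
  stopifnot(n_receptor_residues >= 20, n_models >= 1,
            epitope_contact_prob >= 0, epitope_contact_prob <= 1,
            background_contact_prob >= 0, background_contact_prob <= 1,
            length(ligand_chains) == 2)
  if (is.null(epitope)) {
    # two major patches and one minor, placed at ~20/50/80% of the chain
    # so they are spatially distinct on the default fold; patch sizes
    # 12/12/3 at the default length, scaled down for short receptors
    n <- n_receptor_residues
    s_major <- max(1L, min(12L, n %/% 16L))
    s_minor <- max(1L, min(3L, n %/% 64L))
    starts <- pmax(1L, as.integer(floor(n * c(0.205, 0.505, 0.805))))
    epitope <- c(seq.int(starts[1], length.out = s_major),
                 seq.int(starts[2], length.out = s_major),
                 seq.int(starts[3], length.out = s_minor))
  }
  if (any(epitope < 1) || any(epitope > n_receptor_residues))
    stop("epitope indices outside the receptor")
  structure(list(seed = as.integer(seed),
                 n_receptor_residues = n_receptor_residues,
                 n_models = n_models, epitope = sort(unique(epitope)),
                 epitope_contact_prob = epitope_contact_prob,
                 background_contact_prob = background_contact_prob,
                 ligand_chains = ligand_chains,
                 score_noise_sd = score_noise_sd,
                 couple_scores = couple_scores), class = "sim_config")
}

# deterministic pseudo-fold: a gentle open helix with exact 3.8 A virtual
# CA-CA bonds; sequence separation translates into spatial separation, so
# chain-contiguous epitope patches form compact, mutually distant sites.
.helix_frame <- function(n) {
  theta_step <- 20 * pi / 180
  radius <- 8
  chord <- 2 * radius * sin(theta_step / 2)
  rise <- sqrt(3.8^2 - chord^2)
  i <- seq_len(n) - 1
  theta <- i * theta_step
  ca <- cbind(radius * cos(theta), radius * sin(theta), i * rise)
  r_out <- cbind(cos(theta), sin(theta), 0)
  # tangent along the chain (normalized central difference)
  t_raw <- ca[pmin(seq_len(n) + 1, n), ] - ca[pmax(seq_len(n) - 1, 1), ]
  t_hat <- t_raw / sqrt(rowSums(t_raw^2))
  list(ca = ca, r_out = r_out, t_hat = t_hat)
}

#' Generate a synthetic receptor structure
#'
#' A single-chain coarse model: CA trace with exact 3.8 Angstrom virtual
#' bonds on a deterministic open-helix fold, plus minimal backbone (N, C,
#' O) and side-chain placeholder (CB) atoms. Residue identities are drawn
#' from the 20 standard amino acids under the configured seed, so polarity
#' classes are well populated. Numbering starts at 23.
#'
#' @param config a [sim_config()].
#' @return an `epi_structure` with chain `"A"`.
#' @export
make_receptor <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_receptor_residues
  set.seed(config$seed)
  resid <- sample(.AA3, n, replace = TRUE)
  fr <- .helix_frame(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ca <- fr$ca[i, ]; t_ <- fr$t_hat[i, ]; r_ <- fr$r_out[i, ]
    atoms <- rbind(N = ca - 1.2 * t_,
                   CA = ca,
                   C = ca + 1.1 * t_ - 0.3 * r_,
                   O = ca + 1.3 * t_ - 1.2 * r_)
    elety <- c("N", "CA", "C", "O")
    element <- c("N", "C", "C", "O")
    if (resid[i] != "GLY") {
      atoms <- rbind(atoms, CB = ca - 1.5 * r_)
      elety <- c(elety, "CB")
      element <- c(element, "C")
    }
    rows[[i]] <- data.frame(chain = "A", resno = 22 + i, insert = "",
                            resid = resid[i], elety = elety,
                            element = element, x = atoms[, 1],
                            y = atoms[, 2], z = atoms[, 3], o = 1, b = 0,
                            stringsAsFactors = FALSE)
  }
  new_structure(do.call(rbind, rows), id = "synthetic-receptor",
                source = sprintf("sim_config(seed=%d)", config$seed))
}

#' Generate a ranked docking ensemble with a planted epitope
#'
#' For each pose, every epitope residue is independently placed in contact
#' (a ligand pseudo-atom at a sampled distance within the 2.5 Angstrom
#' rule, on the solvent-facing side of the residue) with probability
#' `epitope_contact_prob`, and every background residue with
#' `background_contact_prob`. Ligand atoms alternate between the two
#' ligand chains, which also carry two distant anchor atoms so both chains
#' always exist. Scores are monotone decreasing in rank. The planted truth
#' is attached as the `truth` attribute.
#'
#' @param receptor output of [make_receptor()] under the same config.
#' @param config a [sim_config()].
#' @return a `docking_ensemble` with attribute `truth` (list with
#'   `epitope_keys`, `epitope_index`, contact probabilities).
#' @export
make_ensemble <- function(receptor, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_res <- config$n_receptor_residues
  rk <- residue_keys(receptor)
  if (nrow(rk) != n_res) stop("receptor does not match config")
  set.seed(config$seed + 1L)
  fr <- .helix_frame(n_res)
  epi <- config$epitope
  bg <- setdiff(seq_len(n_res), epi)
  zmax <- max(fr$ca[, 3])
  anchors <- data.frame(
    chain = config$ligand_chains, resno = c(900L, 900L), insert = "",
    resid = "GLY", elety = "CA", element = "C",
    x = 0, y = 0, z = c(zmax + 50, zmax + 60), o = 1, b = 0,
    stringsAsFactors = FALSE)
  epi_hits_all <- matrix(runif(config$n_models * length(epi)) <
                           config$epitope_contact_prob,
                         nrow = config$n_models)
  bg_hits_all <- matrix(runif(config$n_models * length(bg)) <
                          config$background_contact_prob,
                        nrow = config$n_models)
  poses <- vector("list", config$n_models)
  for (m in seq_len(config$n_models)) {
    hit <- c(epi[epi_hits_all[m, ]], bg[bg_hits_all[m, ]])
    hit <- sort(hit)
    lig <- anchors
    if (length(hit)) {
      d <- runif(length(hit), 2.0, 2.45)
      pos <- fr$ca[hit, , drop = FALSE] + fr$r_out[hit, , drop = FALSE] * d
      lig <- rbind(data.frame(
        chain = config$ligand_chains[(seq_along(hit) %% 2L) + 1L],
        resno = seq_along(hit), insert = "", resid = "GLY",
        elety = "CA", element = "C", x = pos[, 1], y = pos[, 2],
        z = pos[, 3], o = 1, b = 0, stringsAsFactors = FALSE), anchors)
    }
    poses[[m]] <- list(rank = m, score = NA_real_,
                       structure = new_structure(
                         rbind(receptor$atoms, lig),
                         id = sprintf("pose_%d", m)),
                       n_planted = length(hit),
                       n_planted_epitope = sum(epi_hits_all[m, ]))
  }
  base <- 60 - 0.3 * (seq_len(config$n_models) - 1)
  noise <- rnorm(config$n_models, 0, config$score_noise_sd)
  if (config$couple_scores) {
    fidelity <- vapply(poses, function(p) p$n_planted_epitope, numeric(1))
    raw <- base + noise + 0.5 * fidelity
  } else {
    raw <- base + noise
  }
  scores <- sort(raw, decreasing = TRUE)
  for (m in seq_len(config$n_models)) poses[[m]]$score <- scores[m]
  ens <- docking_ensemble(poses, receptor_chain = "A",
                          ligand_chains = config$ligand_chains,
                          label = sprintf("synthetic-seed%d", config$seed))
  attr(ens, "truth") <- list(
    epitope_index = epi,
    epitope_keys = rk$key[epi],
    epitope_contact_prob = config$epitope_contact_prob,
    background_contact_prob = config$background_contact_prob)
  ens
}

#' Construct a two-partner complex with planted hydrogen bonds and salt
#' bridges
#'
#' Builds interaction sites on a wide grid (one donor-acceptor or
#' basic-acidic pair per site, 25 Angstrom apart so sites cannot
#' cross-talk): `n_hbonds` Ser-OG to Glu-OE1 pairs inside 3.5 Angstrom,
#' `n_bridges` basic-acidic charge-center pairs inside 5.5 Angstrom
#' (cycling Lys / Arg / His and alternating which partner carries the
#' base), plus near-miss decoys placed just outside each threshold (3.55
#' and 5.55 Angstrom).
#'
#' @param n_hbonds planted hydrogen bonds (default 7).
#' @param n_bridges planted salt bridges (default 3).
#' @param n_decoy_hbonds,n_decoy_bridges near-miss decoys (default 2
#'   each).
#' @return list with `structure` (chains A = receptor, H/L = ligand),
#'   `receptor_chain`, `ligand_chains` and `truth` (planted counts).
#' @export
make_complex_with_bonds <- function(n_hbonds = 7, n_bridges = 3,
                                    n_decoy_hbonds = 2,
                                    n_decoy_bridges = 2) {
  site <- 0L
  rec_rows <- list(); lig_rows <- list()
  lig_chain <- function(k) c("H", "L")[(k %% 2L) + 1L]
  add_rec <- function(resid, elety, element, xyz, resno) {
    rec_rows[[length(rec_rows) + 1L]] <<- data.frame(
      chain = "A", resno = resno, insert = "", resid = resid,
      elety = elety, element = element, x = xyz[, 1], y = xyz[, 2],
      z = xyz[, 3], o = 1, b = 0, stringsAsFactors = FALSE)
  }
  add_lig <- function(resid, elety, element, xyz, resno, ch) {
    lig_rows[[length(lig_rows) + 1L]] <<- data.frame(
      chain = ch, resno = resno, insert = "", resid = resid,
      elety = elety, element = element, x = xyz[, 1], y = xyz[, 2],
      z = xyz[, 3], o = 1, b = 0, stringsAsFactors = FALSE)
  }
  hb_site <- function(d) {
    site <<- site + 1L
    x0 <- 25 * site
    # receptor SER: CA + OG; ligand GLU: CD + OE1/OE2, OE1 at distance d
    add_rec("SER", c("CA", "OG"), c("C", "O"),
            rbind(c(x0, -1.8, 0), c(x0, 0, 0)), site)
    add_lig("GLU", c("CD", "OE1", "OE2"), c("C", "O", "O"),
            rbind(c(x0, d + 1.3, 1.0), c(x0, d, 0),
                  c(x0, d + 1.0, 2.0)),
            site, lig_chain(site))
  }
  sb_site <- function(d, kind, basic_on_receptor) {
    site <<- site + 1L
    x0 <- 25 * site
    basic <- switch(kind,
      LYS = list(resid = "LYS", elety = c("CA", "NZ"),
                 element = c("C", "N"),
                 xyz = rbind(c(x0, -2, 0), c(x0, 0, 0)),
                 center_y = 0),
      ARG = list(resid = "ARG", elety = c("CA", "CZ", "NH1", "NH2"),
                 element = c("C", "C", "N", "N"),
                 xyz = rbind(c(x0, -2, 0), c(x0, 0.8, 0),
                             c(x0, 1.5, 1.1), c(x0, 1.5, -1.1)),
                 center_y = (0.8 + 1.5 + 1.5) / 3),
      HIS = list(resid = "HIS", elety = c("CA", "ND1", "NE2"),
                 element = c("C", "N", "N"),
                 xyz = rbind(c(x0, -2, 0), c(x0, 0.5, 1.1),
                             c(x0, 0.5, -1.1)),
                 center_y = 0.5))
    acid_y <- basic$center_y + d
    acid <- list(resid = "ASP", elety = c("CA", "CG", "OD1", "OD2"),
                 element = c("C", "C", "O", "O"),
                 xyz = rbind(c(x0, acid_y + 2.5, 0),
                             c(x0, acid_y + 1.2, 0),
                             c(x0, acid_y, 1.1), c(x0, acid_y, -1.1)))
    if (basic_on_receptor) {
      add_rec(basic$resid, basic$elety, basic$element, basic$xyz, site)
      add_lig(acid$resid, acid$elety, acid$element, acid$xyz, site,
              lig_chain(site))
    } else {
      add_rec(acid$resid, acid$elety, acid$element, acid$xyz, site)
      add_lig(basic$resid, basic$elety, basic$element, basic$xyz, site,
              lig_chain(site))
    }
  }
  for (k in seq_len(n_hbonds)) hb_site(2.7 + 0.1 * (k %% 5))
  for (k in seq_len(n_decoy_hbonds)) hb_site(3.55)
  kinds <- c("LYS", "ARG", "HIS")
  for (k in seq_len(n_bridges))
    sb_site(3.9 + 0.15 * (k %% 3), kinds[(k - 1) %% 3 + 1], k %% 2 == 1)
  for (k in seq_len(n_decoy_bridges))
    sb_site(5.55, kinds[(k - 1) %% 3 + 1], k %% 2 == 0)
  # ensure both ligand chains exist even for tiny requests
  far <- max(25 * (site + 1), 50)
  add_lig("GLY", "CA", "C", rbind(c(far, 40, 0)), 900L, "H")
  add_lig("GLY", "CA", "C", rbind(c(far, 50, 0)), 901L, "L")
  atoms <- rbind(do.call(rbind, rec_rows), do.call(rbind, lig_rows))
  list(structure = new_structure(atoms, id = "planted-complex"),
       receptor_chain = "A", ligand_chains = c("H", "L"),
       truth = list(n_hbonds = n_hbonds, n_salt_bridges = n_bridges,
                    n_decoy_hbonds = n_decoy_hbonds,
                    n_decoy_bridges = n_decoy_bridges))
}
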
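# Interface geometry: contacts, typing, hydrogen bonds, salt bridges, SASA.

two_residue_fixture <- function(d) {
  rec <- new_structure(atoms_at("A", 1, "GLY", "CA", "C",
                                rbind(c(0, 0, 0))))
  lig <- new_structure(atoms_at("H", 1, "GLY", "CA", "C",
                                rbind(c(d, 0, 0))))
  list(rec = rec, lig = lig)
}

test_that("the 2.5 A residue-contact rule is inclusive at the boundary", {
  fx <- two_residue_fixture(2.4)
  expect_equal(contact_residues(fx$rec, fx$lig, 2.5)$key, "A:1")
  fx <- two_residue_fixture(2.5)
  expect_equal(contact_residues(fx$rec, fx$lig, 2.5)$key, "A:1")
  fx <- two_residue_fixture(2.6)
  expect_equal(nrow(contact_residues(fx$rec, fx$lig, 2.5)), 0)
  expect_error(contact_residues(fx$rec, fx$lig, -1), "positive")
})

test_that("the intermolecular-contact rule is strict at its boundary", {
  fx <- two_residue_fixture(5.5)
  expect_equal(nrow(intermolecular_contacts(fx$rec, fx$lig, 5.5)), 0)
  expect_equal(nrow(intermolecular_contacts(fx$rec, fx$lig, 5.5,
                                            boundary = "inclusive")), 1)
  fx <- two_residue_fixture(5.4)
  imc <- intermolecular_contacts(fx$rec, fx$lig, 5.5)
  expect_equal(nrow(imc), 1)
  expect_equal(imc$min_distance, 5.4)
})

test_that("contacts carry unordered polarity class pairs", {
  rec <- new_structure(atoms_at("A", 10, "ARG", "NH1", "N",
                                rbind(c(0, 0, 0))))
  lig <- new_structure(atoms_at("H", 5, "ASP", "OD1", "O",
                                rbind(c(4, 0, 0))))
  imc <- intermolecular_contacts(rec, lig)
  expect_equal(nrow(imc), 1)
  expect_equal(imc$class_pair, "charged-charged")
  sm <- contact_class_summary(imc)
  expect_equal(unname(sm$by_pair["charged-charged"]), 1L)
  expect_equal(sm$total, 1)
  # class pair is unordered: swapping partners gives the same label
  imc2 <- intermolecular_contacts(lig, rec)
  expect_equal(imc2$class_pair, imc$class_pair)
})

test_that("spatial-index contact search equals the all-pairs oracle", {
  set.seed(101)
  for (rep_ in 1:10) {
    rec <- random_structure(60, "A", box = 25)
    lig <- random_structure(15, "H", box = 25)
    for (cutoff in c(2.5, 3.5, 5.5)) {
      got <- contact_residues(rec, lig, cutoff)
      want <- oracle_contacts(rec, lig, cutoff, inclusive = TRUE)
      expect_setequal(got$key, want$keys)
      if (nrow(got)) {
        expect_equal(got$min_distance[order(got$key)],
                     as.numeric(want$min_distance[sort(got$key)]),
                     tolerance = 1e-9)
      }
      imc <- intermolecular_contacts(rec, lig, cutoff)
      want_pairs <- oracle_contact_pairs(rec, lig, cutoff,
                                         inclusive = FALSE)
      got_ids <- paste(imc$receptor_key, imc$ligand_key, sep = "|")
      expect_setequal(got_ids, names(want_pairs))
      expect_equal(imc$min_distance[order(got_ids)],
                   unname(want_pairs[sort(got_ids)]), tolerance = 1e-9)
    }
  }
})

test_that("larger contact structure matches the oracle too", {
  set.seed(102)
  rec <- random_structure(300, "A", box = 45)
  lig <- random_structure(50, "H", box = 45)
  got <- contact_residues(rec, lig, 2.5)
  want <- oracle_contacts(rec, lig, 2.5, inclusive = TRUE)
  expect_setequal(got$key, want$keys)
})

test_that("contact sets are monotone in the cutoff", {
  set.seed(103)
  rec <- random_structure(80, "A", box = 25)
  lig <- random_structure(20, "H", box = 25)
  keys <- lapply(c(2.5, 3.5, 5.5), function(cc)
    contact_residues(rec, lig, cc)$key)
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
})

test_that("interaction sets are invariant under common rigid transforms", {
  cx <- make_complex_with_bonds()
  rec <- keep_chains(cx$structure, "A")
  lig <- keep_chains(cx$structure, c("H", "L"))
  hb0 <- hydrogen_bonds(rec, lig)
  sb0 <- salt_bridges(rec, lig)
  imc0 <- intermolecular_contacts(rec, lig)
  set.seed(104)
  for (rep_ in 1:3) {
    R <- random_rotation_matrix(); tr <- rnorm(3, 0, 30)
    rec2 <- transform_structure(rec, R, tr)
    lig2 <- transform_structure(lig, R, tr)
    hb <- hydrogen_bonds(rec2, lig2)
    expect_equal(hb[, c("donor_key", "acceptor_key")],
                 hb0[, c("donor_key", "acceptor_key")])
    expect_equal(hb$distance, hb0$distance, tolerance = 1e-6)
    sb <- salt_bridges(rec2, lig2)
    expect_equal(sb[, c("basic_key", "acidic_key")],
                 sb0[, c("basic_key", "acidic_key")])
    imc <- intermolecular_contacts(rec2, lig2)
    expect_equal(nrow(imc), nrow(imc0))
  }
})

test_that("hydrogen bonds follow donor/acceptor chemistry and distance", {
  mk <- function(d) {
    rec <- new_structure(atoms_at("A", 1, "SER", c("CA", "OG"),
                                  c("C", "O"),
                                  rbind(c(-1.5, 0, 0), c(0, 0, 0))))
    lig <- new_structure(atoms_at("H", 1, "GLU", c("CD", "OE1"),
                                  c("C", "O"),
                                  rbind(c(d + 1.3, 0, 0), c(d, 0, 0))))
    hydrogen_bonds(rec, lig)
  }
  expect_equal(nrow(mk(2.8)), 1)
  expect_equal(mk(2.8)$donor_atom, "OG")
  expect_equal(mk(2.8)$acceptor_atom, "OE1")
  expect_equal(nrow(mk(3.6)), 0)
  # leucine side chains cannot hydrogen-bond
  rec <- new_structure(atoms_at("A", 1, "LEU", c("CA", "CD1"),
                                c("C", "C"),
                                rbind(c(0, 0, 0), c(1, 0, 0))))
  lig <- new_structure(atoms_at("H", 1, "LEU", c("CA", "CD1"),
                                c("C", "C"),
                                rbind(c(3, 0, 0), c(2, 0, 0))))
  expect_equal(nrow(hydrogen_bonds(rec, lig)), 0)
})

test_that("planted hydrogen bonds and salt bridges are recovered exactly", {
  cx <- make_complex_with_bonds(n_hbonds = 7, n_bridges = 3,
                                n_decoy_hbonds = 2, n_decoy_bridges = 2)
  rec <- keep_chains(cx$structure, cx$receptor_chain)
  lig <- keep_chains(cx$structure, cx$ligand_chains)
  hb <- hydrogen_bonds(rec, lig)
  sb <- salt_bridges(rec, lig)
  expect_equal(nrow(hb), cx$truth$n_hbonds)
  expect_equal(nrow(sb), cx$truth$n_salt_bridges)
  expect_true(all(hb$distance <= 3.5))
  expect_true(all(sb$center_distance <= 5.5))
  # empty request gives empty detections
  cx0 <- make_complex_with_bonds(n_hbonds = 0, n_bridges = 0,
                                 n_decoy_hbonds = 2, n_decoy_bridges = 2)
  rec0 <- keep_chains(cx0$structure, "A")
  lig0 <- keep_chains(cx0$structure, c("H", "L"))
  expect_equal(nrow(hydrogen_bonds(rec0, lig0)), 0)
  expect_equal(nrow(salt_bridges(rec0, lig0)), 0)
})

test_that("salt bridges need a basic and an acidic partner", {
  rec <- new_structure(atoms_at("A", 1, "LYS", c("CA", "NZ"),
                                c("C", "N"),
                                rbind(c(-2, 0, 0), c(0, 0, 0))))
  gln <- new_structure(atoms_at("H", 1, "GLN", c("CD", "NE2", "OE1"),
                                c("C", "N", "O"),
                                rbind(c(3, 0, 0), c(3.9, 0, 1),
                                      c(3.9, 0, -1))))
  expect_equal(nrow(salt_bridges(rec, gln)), 0)
  asp <- new_structure(atoms_at("H", 1, "ASP", c("CG", "OD1", "OD2"),
                                c("C", "O", "O"),
                                rbind(c(5, 0, 0), c(3.9, 1.1, 0),
                                      c(3.9, -1.1, 0))))
  sb <- salt_bridges(rec, asp)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$center_distance, 3.9, tolerance = 1e-9)
  # His is basic only under the his_charged convention
  his <- new_structure(atoms_at("A", 2, "HIS", c("CA", "ND1", "NE2"),
                                c("C", "N", "N"),
                                rbind(c(-2, 0, 0), c(0, 1.1, 0),
                                      c(0, -1.1, 0))))
  expect_equal(nrow(salt_bridges(his, asp)), 1)
  expect_equal(nrow(salt_bridges(his, asp, his_charged = FALSE)), 0)
})

test_that("bonded residues are a subset of 5.5 A contact residues", {
  cx <- make_complex_with_bonds()
  rec <- keep_chains(cx$structure, "A")
  lig <- keep_chains(cx$structure, c("H", "L"))
  imc <- intermolecular_contacts(rec, lig, 5.5)
  imc_res <- unique(c(imc$receptor_key, imc$ligand_key))
  hb <- hydrogen_bonds(rec, lig)
  sb <- salt_bridges(rec, lig)
  expect_true(all(c(hb$donor_key, hb$acceptor_key) %in% imc_res))
  expect_true(all(c(sb$basic_key, sb$acidic_key) %in% imc_res))
})

test_that("SASA of an isolated atom matches the analytic sphere", {
  s <- new_structure(atoms_at("A", 1, "ALA", "C", "C",
                              rbind(c(0, 0, 0))))
  got <- sasa(s, probe = 1.4, n_points = 960)$total
  expect_equal(got, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.02)
})

test_that("coincident identical spheres share their surface equally", {
  s <- new_structure(atoms_at("A", 1:2, "ALA", c("C", "C"), c("C", "C"),
                              rbind(c(0, 0, 0), c(0, 0, 0))))
  res <- sasa(s, probe = 1.4, n_points = 960)
  iso <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(res$per_atom[1], iso / 2, tolerance = 1e-9)
  expect_equal(res$per_atom[2], iso / 2, tolerance = 1e-9)
})

test_that("SASA converges to a high-resolution self-reference", {
  set.seed(105)
  xyz <- matrix(runif(30, 0, 4), 10, 3)
  s <- new_structure(atoms_at("A", 1:10, "ALA", rep("C", 10),
                              rep("C", 10), xyz))
  lo <- sasa(s, n_points = 960)$total
  hi <- sasa(s, n_points = 10000)$total
  expect_equal(lo, hi, tolerance = 0.03)
})

test_that("surface composition fractions are bounded and match a recount", {
  cfg <- sim_config(seed = 31, n_receptor_residues = 40)
  rec <- make_receptor(cfg)
  lig <- new_structure(atoms_at("H", 1, "GLY", "CA", "C",
                                rbind(c(30, 0, 0))))
  nf <- nis_fractions(rec, lig, n_points = 240)
  expect_true(all(nf >= 0 & nf <= 100))
  expect_lte(sum(nf), 100)
  # direct recount through the same exposure rule
  cx <- concat_structures(rec, lig)
  sr <- sasa(cx, n_points = 240)$per_residue
  mx <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
          GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
          LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
          SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
  surf <- sr[sr$sasa / mx[sr$resid] > 0.05, ]
  cls <- classify_residue(surf$resid)
  expect_equal(unname(nf["apolar"]), 100 * mean(cls == "apolar"),
               tolerance = 1e-9)
  expect_equal(unname(nf["charged"]), 100 * mean(cls == "charged"),
               tolerance = 1e-9)
})
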
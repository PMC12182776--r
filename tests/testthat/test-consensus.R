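# Consensus statistics: frequencies, top lists, Venn regions, overlap
# matrices, spatial groups and B-factor annotation.

# hand-built frequency table
ft_from_counts <- function(counts, label = "toy") {
  resno <- as.integer(sub("^A:", "", names(counts)))
  df <- data.frame(key = names(counts), chain = "A", resno = resno,
                   insert = "", resid = "ALA",
                   count = as.integer(counts), stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$resno), ]
  rownames(df) <- NULL
  structure(list(counts = df, n_models = 100, cutoff = 2.5,
                 label = label), class = "frequency_table")
}

test_that("contact frequencies count binary per-pose membership", {
  # 3 poses: pose 1 and 3 contact residue 1; pose 2 contacts residue 2
  cfg <- sim_config(seed = 61, n_receptor_residues = 30, n_models = 3,
                    epitope = 1, epitope_contact_prob = 0,
                    background_contact_prob = 0)
  rec <- make_receptor(cfg)
  ens <- make_ensemble(rec, cfg)
  plant <- function(pose, idx) {
    ca <- pose$structure$atoms
    target <- which(ca$chain == "A" & ca$elety == "CA")[idx]
    lig <- data.frame(chain = "H", resno = 500L, insert = "",
                      resid = "GLY", elety = "CA", element = "C",
                      x = ca$x[target] + 2.2, y = ca$y[target],
                      z = ca$z[target], o = 1, b = 0,
                      stringsAsFactors = FALSE)
    pose$structure <- new_structure(rbind(ca, lig))
    pose
  }
  # helix outward direction at residue 1 is +x, so +2.2 on x is a contact
  # for any residue on the first turn; use residue indexes 1 and 19 would
  # differ, so keep residue 1 and 2 instead and verify geometrically
  ens$poses[[1]] <- plant(ens$poses[[1]], 1)
  ens$poses[[3]] <- plant(ens$poses[[3]], 1)
  ft <- contact_frequencies(ens, consensus_config(n_models = 3))
  k1 <- residue_keys(rec)$key[1]
  expect_equal(ft$counts$count[ft$counts$key == k1], 2L)
  expect_false(any(ft$counts$count > 3))
  # residues never in contact are absent
  expect_lte(nrow(ft$counts), 2)
})

test_that("frequencies stay within [0, n_models] and are cutoff-monotone", {
  cfg <- sim_config(seed = 62, n_receptor_residues = 60, n_models = 20,
                    epitope = c(10:15), epitope_contact_prob = 0.5,
                    background_contact_prob = 0.05)
  rec <- make_receptor(cfg)
  ens <- make_ensemble(rec, cfg)
  f25 <- contact_frequencies(ens, consensus_config(n_models = 20,
                                                   residue_cutoff = 2.5))
  f55 <- contact_frequencies(ens, consensus_config(n_models = 20,
                                                   residue_cutoff = 5.5))
  expect_true(all(f25$counts$count >= 0 & f25$counts$count <= 20))
  m55 <- setNames(f55$counts$count, f55$counts$key)
  for (i in seq_len(nrow(f25$counts))) {
    k <- f25$counts$key[i]
    expect_true(k %in% names(m55))
    expect_lte(f25$counts$count[i], m55[[k]])
  }
})

test_that("frequencies are invariant under per-pose rigid scrambling", {
  cfg <- sim_config(seed = 63, n_receptor_residues = 50, n_models = 8,
                    epitope = c(5:10), epitope_contact_prob = 0.6)
  rec <- make_receptor(cfg)
  ens <- make_ensemble(rec, cfg)
  f0 <- contact_frequencies(ens, consensus_config(n_models = 8))
  set.seed(64)
  ens$poses <- lapply(ens$poses, function(p) {
    p$structure <- transform_structure(p$structure,
                                       random_rotation_matrix(),
                                       rnorm(3, 0, 15))
    p
  })
  f1 <- contact_frequencies(ens, consensus_config(n_models = 8))
  expect_equal(f1$counts, f0$counts)
})

test_that("top_residues sorts by count with the number tie-break", {
  ft <- ft_from_counts(c("A:329" = 20, "A:83" = 17, "A:311" = 17))
  top2 <- top_residues(ft, 2)
  expect_equal(top2$key, c("A:329", "A:83"))
  ties <- attr(top2, "boundary_ties")
  expect_equal(ties$key, "A:311")
  # k beyond the table returns the whole table unpadded
  expect_equal(nrow(top_residues(ft, 10)), 3)
  # random table equals a full-sort oracle
  set.seed(65)
  counts <- setNames(sample(0:40, 200, replace = TRUE),
                     paste0("A:", sample(1000, 200)))
  ftr <- ft_from_counts(counts)
  got <- top_residues(ftr, 20)
  ord <- order(-counts, as.integer(sub("A:", "", names(counts))))
  expect_equal(got$key, names(counts)[ord][1:20])
})

test_that("threshold consensus unions qualifying residues across tables", {
  t1 <- ft_from_counts(c("A:83" = 25, "A:128" = 33, "A:50" = 5))
  t2 <- ft_from_counts(c("A:128" = 21, "A:346" = 29, "A:60" = 19))
  un <- threshold_consensus(list(t1, t2), min_frequency = 20)
  expect_setequal(un$key, c("A:83", "A:128", "A:346"))
  expect_equal(un$max_count[un$key == "A:128"], 33L)
  expect_equal(nrow(threshold_consensus(list(t1, t2),
                                        min_frequency = 99)), 0)
  # brute-force filter + union oracle on random triplets
  set.seed(66)
  tables <- lapply(1:3, function(i)
    ft_from_counts(setNames(sample(0:40, 50, replace = TRUE),
                            paste0("A:", sample(200, 50)))))
  got <- threshold_consensus(tables, 20)$key
  want <- unique(unlist(lapply(tables, function(tb)
    tb$counts$key[tb$counts$count >= 20])))
  expect_setequal(got, want)
})

test_that("venn regions partition the union and match brute force", {
  ids <- paste0("A:", 1:20)
  same <- venn_regions(setNames(rep(list(ids), 5), paste0("m", 1:5)))
  expect_equal(sort(same$regions[["11111"]]), sort(ids))
  expect_equal(sum(lengths(same$regions)), 20)
  expect_equal(unname(same$k_of_n["5"]), 20L)
  disj <- venn_regions(list(a = paste0("A:", 1:3),
                            b = paste0("A:", 4:6)))
  expect_equal(sort(disj$regions[["10"]]), paste0("A:", 1:3))
  expect_equal(sort(disj$regions[["01"]]), paste0("A:", 4:6))
  expect_equal(length(disj$regions[["11"]]), 0)
  set.seed(67)
  for (rep_ in 1:20) {
    sets <- lapply(1:5, function(i)
      sample(paste0("A:", 1:40), sample(5:25, 1)))
    names(sets) <- paste0("s", 1:5)
    vr <- venn_regions(sets)
    expect_equal(sum(lengths(vr$regions)),
                 length(unique(unlist(sets))))
    want <- oracle_venn(sets)
    for (pat in names(want))
      expect_equal(sort(vr$regions[[pat]]), sort(want[[pat]]))
    # k-of-n counts match the region sizes
    for (k in 1:5) {
      nk <- sum(lengths(vr$regions[
        vapply(names(vr$regions), function(p)
          sum(strsplit(p, "")[[1]] == "1") == k, logical(1))]))
      expect_equal(unname(vr$k_of_n[as.character(k)]), nk)
    }
  }
  expect_error(venn_regions(list(a = "A:1")), "between 2 and 6")
})

test_that("shared top matrix is symmetric with diagonal k", {
  set.seed(68)
  tables <- lapply(1:6, function(i)
    ft_from_counts(setNames(sample(5:40, 60, replace = TRUE),
                            paste0("A:", sample(300, 60)))))
  names(tables) <- paste0("combo", 1:6)
  m <- shared_top_matrix(tables, k = 20)
  expect_equal(dim(m), c(6, 6))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(20L, 6))
  # pairwise set-intersection oracle
  tops <- lapply(tables, function(tb) top_residues(tb, 20)$key)
  for (i in 1:6)
    for (j in 1:6)
      expect_equal(m[i, j], length(intersect(tops[[i]], tops[[j]])))
  ident <- shared_top_matrix(list(a = tables[[1]], b = tables[[1]]), 20)
  expect_equal(ident["a", "b"], 20L)
})

test_that("spatial groups are connected components at the cutoff", {
  cfg <- sim_config(seed = 69)
  rec <- make_receptor(cfg)
  rk <- residue_keys(rec)
  # two chain-contiguous patches far apart -> two groups
  sel <- rk$key[c(10:14, 150:154)]
  gr <- spatial_groups(sel, rec, linkage_cutoff = 15)
  expect_length(gr, 2)
  expect_equal(lengths(lapply(gr, function(g) g$members$key)),
               c(5L, 5L))
  expect_equal(gr[[1]]$label, "I")
  # everything in one patch -> one group
  gr1 <- spatial_groups(rk$key[20:26], rec, linkage_cutoff = 15)
  expect_length(gr1, 1)
  # matches a union-find oracle on random subsets
  set.seed(70)
  for (rep_ in 1:5) {
    sel <- sort(sample(nrow(rk), 30))
    keys <- rk$key[sel]
    gr <- spatial_groups(keys, rec, linkage_cutoff = 12)
    ca <- rec$atoms[rec$atoms$elety == "CA", ]
    xyz <- as.matrix(ca[sel, c("x", "y", "z")])
    comp <- oracle_components(xyz, 12)
    expect_equal(length(gr), length(unique(comp)))
    sizes_got <- sort(lengths(lapply(gr, function(g) g$members$key)))
    expect_equal(sizes_got, sort(unname(table(comp))),
                 ignore_attr = TRUE)
  }
  # missing residues are excluded with a warning, never fatal
  expect_warning(gr2 <- spatial_groups(c(rk$key[1:4], "A:9999"), rec),
                 "missing")
  expect_equal(attr(gr2, "missing"), "A:9999")
})

test_that("frequency annotation lands in B-factors and round-trips", {
  cfg <- sim_config(seed = 71, n_receptor_residues = 30)
  rec <- make_receptor(cfg)
  rk <- residue_keys(rec)
  ft <- ft_from_counts(setNames(27L, rk$key[5]))
  ft$counts$chain <- rk$chain[5]; ft$counts$resno <- rk$resno[5]
  ann <- annotate_frequencies(rec, ft)
  in5 <- ann$atoms$resno == rk$resno[5]
  expect_true(all(ann$atoms$b[in5] == 27))
  expect_true(all(ann$atoms$b[!in5] == 0))
  expect_equal(attr(ann, "most_frequent")$key, rk$key[5])
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ann, f)
  back <- read_pdb(f)
  expect_equal(back$atoms$b, ann$atoms$b, tolerance = 1e-2)
  # empty table zeroes everything
  ft0 <- ft_from_counts(c("A:1" = 1))
  ft0$counts <- ft0$counts[0, ]
  ann0 <- annotate_frequencies(rec, ft0)
  expect_true(all(ann0$atoms$b == 0))
})

test_that("ensembles round-trip through the directory layout", {
  cfg <- sim_config(seed = 72, n_receptor_residues = 30, n_models = 4)
  rec <- make_receptor(cfg)
  ens <- make_ensemble(rec, cfg)
  d <- withr::local_tempdir()
  write_ensemble(ens, d)
  expect_true(file.exists(file.path(d, "scores.tsv")))
  expect_true(file.exists(file.path(d, "poses", "pose_1.pdb")))
  back <- read_ensemble(d, "A", c("H", "L"), label = "reread")
  expect_length(back$poses, 4)
  expect_equal(back$scores, ens$scores, tolerance = 1e-6)
  for (m in 1:4) {
    expect_equal(coords(back$poses[[m]]$structure),
                 coords(ens$poses[[m]]$structure), tolerance = 1e-3)
  }
})
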
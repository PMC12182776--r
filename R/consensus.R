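# Consensus epitope mapping: per-residue contact frequencies over ranked
# ensembles, top-k / threshold consensus lists, Venn overlaps,
# cross-combination shared-residue matrices, and spatial grouping of
# consensus residues into candidate binding sites.

#' Construct a docking ensemble
#'
#' A rank-ordered collection of docking poses sharing one receptor chain
#' topology, with per-pose scores (higher is better; ranks follow
#' descending score).
#'
#' @param poses list of poses, each a list with `rank`, `score` and
#'   `structure` (an `epi_structure` containing receptor and ligand
#'   chains).
#' @param receptor_chain receptor chain id.
#' @param ligand_chains ligand (antibody) chain ids.
#' @param label combination name, e.g. `"mab1 x model-A"`.
#' @return a list of class `docking_ensemble`.
#' @export
docking_ensemble <- function(poses, receptor_chain, ligand_chains,
                             label = "") {
  if (!length(poses)) stop("empty ensemble")
  ranks <- vapply(poses, function(p) as.integer(p$rank), integer(1))
  scores <- vapply(poses, function(p) as.numeric(p$score), numeric(1))
  if (anyDuplicated(ranks)) stop("pose ranks must be unique")
  ord <- order(ranks)
  poses <- poses[ord]
  scores <- scores[ord]
  if (is.unsorted(rev(scores))) {
    # ranks must follow descending score
    stop("pose scores must be non-increasing in rank order")
  }
  for (p in poses) {
    ch <- chain_ids(p$structure)
    if (!(receptor_chain %in% ch) || !all(ligand_chains %in% ch))
      stop("designated chains missing from pose structure")
  }
  structure(list(label = label, receptor_chain = receptor_chain,
                 ligand_chains = ligand_chains, poses = poses,
                 scores = scores), class = "docking_ensemble")
}

#' @export
print.docking_ensemble <- function(x, ...) {
  cat(sprintf("<docking_ensemble %s> %d poses, receptor %s, ligand %s\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              length(x$poses), x$receptor_chain,
              paste(x$ligand_chains, collapse = "/")))
  invisible(x)
}

#' Consensus-analysis configuration
#'
#' @param n_models number of top-ranked models to count over (default 100).
#' @param top_k size of the most-frequent-residue list (default 20).
#' @param min_frequency threshold for consensus membership (default 20).
#' @param residue_cutoff contact distance in Angstrom (default 2.5).
#' @return a list of class `consensus_config`.
#' @export
consensus_config <- function(n_models = 100, top_k = 20,
                             min_frequency = 20, residue_cutoff = 2.5) {
  stopifnot(n_models >= 1, top_k >= 1, min_frequency >= 0,
            residue_cutoff > 0)
  structure(list(n_models = n_models, top_k = top_k,
                 min_frequency = min_frequency,
                 residue_cutoff = residue_cutoff),
            class = "consensus_config")
}

# split one pose into receptor / ligand structures
.pose_partners <- function(pose, receptor_chain, ligand_chains) {
  list(receptor = keep_chains(pose$structure, receptor_chain),
       ligand = keep_chains(pose$structure, ligand_chains))
}

#' Per-residue contact frequencies across ranked models
#'
#' For each receptor residue, counts the number of the first
#' `min(n_models, #poses)` poses (in rank order) in which the residue is an
#' interface residue at `residue_cutoff`. Membership per pose is binary
#' regardless of how many atom contacts qualify, so counts never exceed
#' the number of models used.
#'
#' @param ensemble a `docking_ensemble`.
#' @param config a [consensus_config()].
#' @return a `frequency_table`: list with `counts` (residue table plus
#'   `count` column, count-descending), `n_models`, `cutoff`, `label`.
#' @export
contact_frequencies <- function(ensemble, config = consensus_config()) {
  stopifnot(inherits(ensemble, "docking_ensemble"))
  n_use <- min(config$n_models, length(ensemble$poses))
  if (n_use < config$n_models)
    message("ensemble has only ", n_use, " poses; counting over all of them")
  tallies <- new.env(parent = emptyenv())
  info <- list()
  for (m in seq_len(n_use)) {
    parts <- .pose_partners(ensemble$poses[[m]], ensemble$receptor_chain,
                            ensemble$ligand_chains)
    cr <- contact_residues(parts$receptor, parts$ligand,
                           cutoff = config$residue_cutoff)
    for (idx in seq_len(nrow(cr))) {
      k <- cr$key[idx]
      tallies[[k]] <- (tallies[[k]] %||% 0L) + 1L
      if (is.null(info[[k]]))
        info[[k]] <- cr[idx, c("chain", "resno", "insert", "resid")]
    }
  }
  keys <- ls(tallies)
  counts <- if (length(keys)) {
    data.frame(key = keys,
               do.call(rbind, info[keys]),
               count = vapply(keys, function(k) tallies[[k]], integer(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(0), chain = character(0),
               resno = integer(0), insert = character(0),
               resid = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  }
  counts <- counts[order(-counts$count, counts$resno, counts$chain), ]
  rownames(counts) <- NULL
  structure(list(counts = counts, n_models = n_use,
                 cutoff = config$residue_cutoff, label = ensemble$label),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table %s> %d residues over %d models (%.1f A)\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              nrow(x$counts), x$n_models, x$cutoff))
  print(utils::head(x$counts, 10))
  invisible(x)
}

#' Most frequent contact residues
#'
#' Residues sorted by count descending with ties broken by ascending
#' residue number then chain id; the first `k` are returned. Residues
#' excluded only by the tie-break at the k-th count are reported in the
#' `boundary_ties` attribute.
#'
#' @param table a `frequency_table`.
#' @param k list size (default 20). If `k` exceeds the table, the whole
#'   table is returned without padding.
#' @return data frame of the top residues with counts; attribute
#'   `boundary_ties` holds any tied-out residues.
#' @export
top_residues <- function(table, k = 20) {
  stopifnot(inherits(table, "frequency_table"), k >= 1)
  ct <- table$counts
  if (!nrow(ct)) stop("empty frequency table")
  ord <- order(-ct$count, ct$resno, ct$chain)
  ct <- ct[ord, ]
  rownames(ct) <- NULL
  if (k >= nrow(ct)) {
    attr(ct, "boundary_ties") <- ct[0, ]
    return(ct)
  }
  top <- ct[seq_len(k), ]
  ties <- ct[-seq_len(k), ]
  ties <- ties[ties$count == top$count[k], , drop = FALSE]
  rownames(top) <- rownames(ties) <- NULL
  attr(top, "boundary_ties") <- ties
  top
}

#' Threshold consensus residues across combinations
#'
#' Union, over several frequency tables, of residues whose count meets
#' `min_frequency`, deduplicated by positional residue key.
#'
#' @param tables list of `frequency_table` objects sharing receptor
#'   numbering.
#' @param min_frequency minimum count (default 20).
#' @return residue table of the deduplicated union, with a
#'   `max_count` column (the largest qualifying count seen per residue).
#' @export
threshold_consensus <- function(tables, min_frequency = 20) {
  if (inherits(tables, "frequency_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    stopifnot(inherits(tb, "frequency_table"))
    tb$counts[tb$counts$count >= min_frequency, , drop = FALSE]
  })
  all_ <- do.call(rbind, rows)
  if (!nrow(all_)) {
    out <- all_[, c("key", "chain", "resno", "insert", "resid")]
    out$max_count <- integer(0)
    return(out)
  }
  dt <- data.table::as.data.table(all_)
  agg <- as.data.frame(dt[, list(chain = chain[1], resno = resno[1],
                                 insert = insert[1], resid = resid[1],
                                 max_count = max(count)), by = "key"])
  agg <- agg[order(agg$resno, agg$chain), ]
  rownames(agg) <- NULL
  agg
}

#' Venn regions of residue sets
#'
#' Partitions the union of 2-6 residue sets into the `2^n - 1` disjoint
#' membership regions, keyed by binary membership pattern (e.g. `"10110"`
#' in set order), and summarizes how many residues are shared by exactly k
#' sets.
#'
#' @param sets named list of character vectors (residue keys).
#' @return list with `regions` (pattern -> sorted member vector, empty
#'   regions included), `k_of_n` (named count vector, k = 1..n) and
#'   `set_names`.
#' @export
venn_regions <- function(sets) {
  n <- length(sets)
  if (n < 2 || n > 6) stop("venn_regions needs between 2 and 6 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_len(n))
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row)
    paste(as.integer(row), collapse = ""))
  all_patterns <- vapply(seq_len(2^n - 1), function(m)
    paste(as.integer(intToBits(m)[n:1]), collapse = ""), character(1))
  regions <- setNames(lapply(all_patterns, function(p)
    universe[pattern == p]), all_patterns)
  k_count <- rowSums(membership)
  k_of_n <- vapply(seq_len(n), function(k) sum(k_count == k), integer(1))
  names(k_of_n) <- as.character(seq_len(n))
  list(regions = regions, k_of_n = k_of_n, set_names = names(sets))
}

#' Shared top-k residues between all combination pairs
#'
#' Entry (i, j) is the number of residue keys common to the top-k lists of
#' combinations i and j; the diagonal is each combination's own top-k size.
#'
#' @param tables named list of `frequency_table` objects.
#' @param k top-list size (default 20).
#' @return symmetric integer matrix with combination labels as dimnames.
#' @export
shared_top_matrix <- function(tables, k = 20) {
  if (length(tables) < 2) stop("need at least 2 frequency tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, function(tb)
      if (nzchar(tb$label)) tb$label else "combination", character(1))
  tops <- lapply(tables, function(tb) top_residues(tb, k)$key)
  n <- length(tops)
  m <- matrix(0L, n, n, dimnames = list(names(tables), names(tables)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      m[i, j] <- length(intersect(tops[[i]], tops[[j]]))
  m
}

#' Spatial grouping of consensus residues into candidate binding sites
#'
#' Single-linkage clustering on CA-CA distances: two residues are
#' connected when their CA atoms lie within `linkage_cutoff`, and groups
#' are the connected components, labeled by Roman numerals in order of
#' descending size (ties by ascending minimum residue number).
#'
#' @param residues character vector of residue keys, or a residue table
#'   with a `key` column.
#' @param reference `epi_structure` providing CA coordinates.
#' @param linkage_cutoff CA-CA connection distance (default 15 Angstrom).
#' @return list of groups, each with `label`, `members` (residue table
#'   with coordinates) and `centroid`; residues absent from the reference
#'   (e.g. in disordered gaps) are reported in the `missing` attribute and
#'   excluded, never fatal.
#' @export
spatial_groups <- function(residues, reference, linkage_cutoff = 15) {
  keys <- if (is.data.frame(residues)) residues$key else residues
  keys <- unique(keys)
  ca <- reference$atoms[reference$atoms$elety == "CA", , drop = FALSE]
  ckey <- .make_key(ca$chain, ca$resno, ca$insert)
  idx <- match(keys, ckey)
  missing_ <- keys[is.na(idx)]
  if (length(missing_))
    warning("residues missing from reference (excluded): ",
            paste(missing_, collapse = ", "))
  keys <- keys[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (!length(keys)) {
    out <- list()
    attr(out, "missing") <- missing_
    return(out)
  }
  xyz <- as.matrix(ca[idx, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= linkage_cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  groups <- split(seq_along(keys), comp)
  size <- vapply(groups, length, integer(1))
  min_resno <- vapply(groups, function(ii) min(ca$resno[idx[ii]]),
                      numeric(1))
  ord <- order(-size, min_resno)
  groups <- groups[ord]
  out <- lapply(seq_along(groups), function(g_i) {
    ii <- groups[[g_i]]
    members <- data.frame(key = keys[ii], chain = ca$chain[idx[ii]],
                          resno = ca$resno[idx[ii]],
                          insert = ca$insert[idx[ii]],
                          resid = ca$resid[idx[ii]],
                          x = ca$x[idx[ii]], y = ca$y[idx[ii]],
                          z = ca$z[idx[ii]], stringsAsFactors = FALSE)
    members <- members[order(members$resno, members$chain), ]
    rownames(members) <- NULL
    list(label = as.character(utils::as.roman(g_i)), members = members,
         centroid = colMeans(xyz[ii, , drop = FALSE]))
  })
  attr(out, "missing") <- missing_
  out
}

#' Annotate a structure with contact frequencies
#'
#' Writes each residue's contact count into the B-factor slot of all its
#' atoms (0 for uncontacted residues), which standard viewers render as a
#' white-to-red intensity scale. The most frequent residue(s) are attached
#' as the `most_frequent` attribute.
#'
#' @param reference `epi_structure` to annotate.
#' @param table a `frequency_table`.
#' @return annotated copy of `reference`.
#' @export
annotate_frequencies <- function(reference, table) {
  stopifnot(inherits(table, "frequency_table"))
  akey <- .atom_keys(reference)
  cnt <- setNames(table$counts$count, table$counts$key)
  b <- unname(cnt[akey])
  b[is.na(b)] <- 0
  unresolved <- setdiff(table$counts$key, unique(akey))
  if (length(unresolved))
    message("frequency table residues not in reference: ",
            paste(unresolved, collapse = ", "))
  reference$atoms$b <- as.numeric(b)
  if (nrow(table$counts)) {
    mx <- max(table$counts$count)
    attr(reference, "most_frequent") <-
      table$counts[table$counts$count == mx, , drop = FALSE]
  }
  reference
}

# ---- ensemble directory I/O -------------------------------------------------

#' Write an ensemble to the canonical directory layout
#'
#' Produces `poses/pose_<rank>.pdb` and `scores.tsv` (columns rank, score,
#' filename), the layout [read_ensemble()] consumes.
#'
#' @param ensemble a `docking_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(file.path(dir, "poses"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- lapply(ensemble$poses, function(p) {
    fn <- sprintf("pose_%d.pdb", p$rank)
    write_pdb(p$structure, file.path(dir, "poses", fn))
    data.frame(rank = p$rank, score = p$score, filename = fn)
  })
  write.table(do.call(rbind, rows), file.path(dir, "scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an ensemble from a directory
#'
#' Expects `scores.tsv` with columns `rank`, `score`, `filename`; pose
#' files are resolved relative to `dir/poses` (or `dir` itself), so
#' server-specific file names are supported as long as the scores file
#' maps them to ranks.
#'
#' @param dir ensemble directory.
#' @param receptor_chain,ligand_chains chain designations.
#' @param label combination name.
#' @return a `docking_ensemble`.
#' @export
read_ensemble <- function(dir, receptor_chain, ligand_chains, label = "") {
  sc_path <- file.path(dir, "scores.tsv")
  if (!file.exists(sc_path)) stop("no scores.tsv in ", dir)
  sc <- read.table(sc_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  sc <- sc[order(sc$rank), ]
  poses <- lapply(seq_len(nrow(sc)), function(i) {
    fn <- file.path(dir, "poses", sc$filename[i])
    if (!file.exists(fn)) fn <- file.path(dir, sc$filename[i])
    list(rank = sc$rank[i], score = sc$score[i],
         structure = read_pdb(fn))
  })
  docking_ensemble(poses, receptor_chain, ligand_chains, label = label)
}
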
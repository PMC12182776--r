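# Sequence-alignment-guided rigid-body superposition.
#
# The workflow mirrors the standard "align" behavior of molecular viewers:
# a global sequence alignment picks matched CA pairs, a Kabsch fit
# superposes them, and pairs deviating by more than sigma_cut standard
# deviations are rejected over up to `cycles` refit rounds.

#' Globally align two residue sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties over a
#' substitution matrix (BLOSUM62 by default), returning the matched
#' (non-gap) column pairs as 1-based positions in each input.
#'
#' @param mobile,reference one-letter amino-acid strings (or character
#'   vectors collapsed with no separator).
#' @param substitution_matrix name of a substitution matrix available to
#'   `Biostrings` (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties as positive costs
#'   (defaults 10 and 0.5).
#' @return list with `matched_pairs` (data frame of `mobile`, `reference`
#'   positions, strictly increasing in both), `score`, and
#'   `identity_fraction` (identities over matched pairs).
#' @export
align_sequences <- function(mobile, reference,
                            substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5) {
  mobile <- paste(mobile, collapse = "")
  reference <- paste(reference, collapse = "")
  if (!nzchar(mobile) || !nzchar(reference))
    stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(mobile), Biostrings::AAString(reference),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  gp <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  gs <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  i <- 0L; j <- 0L
  mi <- integer(0); mj <- integer(0)
  for (k in seq_along(gp)) {
    if (gp[k] != "-") i <- i + 1L
    if (gs[k] != "-") j <- j + 1L
    if (gp[k] != "-" && gs[k] != "-") {
      mi <- c(mi, i); mj <- c(mj, j)
    }
  }
  ident <- if (length(mi)) {
    mean(substring(mobile, mi, mi) == substring(reference, mj, mj))
  } else 0
  list(matched_pairs = data.frame(mobile = mi, reference = mj),
       score = Biostrings::score(pa),
       identity_fraction = ident)
}

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference` (row-vector convention: `mobile %*% rotation +
#' translation`). Uses the SVD solution with the determinant correction
#' that excludes reflections.
#'
#' @param mobile,reference n x 3 coordinate matrices with rows paired.
#' @return list with `rotation` (3 x 3, det +1), `translation`, `rmsd`
#'   (Angstrom, after the transform), `n` and `degenerate` (TRUE when the
#'   point set is collinear or worse, making the rotation non-unique).
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3)
    stop("mobile and reference must be n x 3 with matching n")
  n <- nrow(mobile)
  if (n < 3) stop("at least 3 paired points are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  degenerate <- sv$d[2] <= 1e-8 * max(sv$d[1], 1e-12)
  if (degenerate)
    warning("degenerate (collinear) point set; rotation not unique")
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- cr - drop(cm %*% R)
  dev <- P %*% R - Q
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums(dev^2))), n = n, degenerate = degenerate)
}

#' RMSD between two paired coordinate sets (no fitting)
#' @param a,b n x 3 matrices.
#' @return root-mean-square deviation in Angstrom.
#' @export
rmsd_coords <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

# matched CA coordinate pairs for shared chains of two structures
.matched_ca_pairs <- function(mobile, reference, chains = NULL) {
  if (is.null(chains)) {
    chains <- intersect(chain_ids(mobile), chain_ids(reference))
    if (!length(chains)) stop("no shared chain ids between structures")
    names(chains) <- chains
  } else if (is.null(names(chains))) {
    names(chains) <- chains
  }
  rows <- list()
  for (mc in names(chains)) {
    rc <- chains[[mc]]
    sm <- structure_sequence(mobile, mc)
    sr <- structure_sequence(reference, rc)
    al <- align_sequences(sm$sequence, sr$sequence)
    mp <- al$matched_pairs
    if (!nrow(mp)) next
    rows[[mc]] <- data.frame(
      mobile_key = sm$residues$key[mp$mobile],
      reference_key = sr$residues$key[mp$reference],
      mx = sm$residues$x[mp$mobile], my = sm$residues$y[mp$mobile],
      mz = sm$residues$z[mp$mobile],
      rx = sr$residues$x[mp$reference], ry = sr$residues$y[mp$reference],
      rz = sr$residues$z[mp$reference], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 3)
    stop("fewer than 3 matched CA pairs")
  rownames(out) <- NULL
  out
}

#' Sequence-guided structural superposition with outlier rejection
#'
#' Aligns the sequences of shared (or explicitly mapped) chains, fits the
#' matched CA pairs with [kabsch()], then iteratively rejects pairs whose
#' deviation exceeds `sigma_cut` standard deviations of the current cycle's
#' per-pair deviations and refits, up to `cycles` rounds or convergence.
#'
#' @param mobile,reference `epi_structure` objects.
#' @param chains optional chain mapping: a character vector of chain ids
#'   shared by both structures, or a named vector `c(mobileChain =
#'   referenceChain, ...)`. Default: all shared chain ids.
#' @param cycles maximum refinement cycles (default 5).
#' @param sigma_cut rejection multiplier on the deviation SD (default 2).
#' @param apply if `TRUE`, also return the transformed mobile structure.
#' @return list with `rotation`, `translation`, `rmsd` (over surviving
#'   pairs), `n_pairs_used`, `n_cycles`, `rejected_pairs` (data frame of
#'   rejected mobile/reference residue keys and deviations), and
#'   `transformed` when `apply = TRUE`.
#' @export
superpose_structures <- function(mobile, reference, chains = NULL,
                                 cycles = 5, sigma_cut = 2.0,
                                 apply = FALSE) {
  stopifnot(cycles >= 1)
  pairs <- .matched_ca_pairs(mobile, reference, chains)
  M <- as.matrix(pairs[, c("mx", "my", "mz")])
  R_ <- as.matrix(pairs[, c("rx", "ry", "rz")])
  keep <- rep(TRUE, nrow(pairs))
  fit <- NULL
  n_cycles <- 0L
  for (cyc in seq_len(cycles)) {
    fit <- kabsch(M[keep, , drop = FALSE], R_[keep, , drop = FALSE])
    n_cycles <- cyc
    dev_all <- sqrt(rowSums((sweep(M %*% fit$rotation, 2, fit$translation,
                                   `+`) - R_)^2))
    dev <- dev_all[keep]
    sig <- sd(dev)
    if (!is.finite(sig) || sig <= 1e-12) break
    drop_ <- keep & dev_all > sigma_cut * sig
    if (!any(drop_)) break
    if (sum(keep & !drop_) < 3) break
    keep <- keep & !drop_
  }
  dev_all <- sqrt(rowSums((sweep(M %*% fit$rotation, 2, fit$translation,
                                 `+`) - R_)^2))
  rejected <- data.frame(mobile_key = pairs$mobile_key[!keep],
                         reference_key = pairs$reference_key[!keep],
                         deviation = dev_all[!keep],
                         stringsAsFactors = FALSE)
  out <- list(rotation = fit$rotation, translation = fit$translation,
              rmsd = sqrt(mean(dev_all[keep]^2)),
              n_pairs_used = sum(keep), n_cycles = n_cycles,
              rejected_pairs = rejected)
  if (apply)
    out$transformed <- transform_structure(mobile, fit$rotation,
                                           fit$translation)
  out
}

#' Put every pose of an ensemble in the frame of a reference pose
#'
#' Each pose is rigidly transformed so that its receptor chain superposes
#' onto the receptor of the reference pose; the antibody chains are carried
#' by the same transform, so all intra-pose geometry (and therefore every
#' contact set) is preserved.
#'
#' @param ensemble a `docking_ensemble` (see [docking_ensemble()]).
#' @param reference_pose_index index of the pose whose receptor defines the
#'   common frame (default 1, i.e. the top-ranked model).
#' @param cycles,sigma_cut passed to [superpose_structures()].
#' @return the ensemble with transformed pose structures.
#' @export
standardize_ensemble <- function(ensemble, reference_pose_index = 1,
                                 cycles = 5, sigma_cut = 2.0) {
  n <- length(ensemble$poses)
  if (n == 0) stop("empty ensemble")
  if (reference_pose_index < 1 || reference_pose_index > n)
    stop("reference_pose_index out of range")
  rc <- ensemble$receptor_chain
  ref <- keep_chains(ensemble$poses[[reference_pose_index]]$structure, rc)
  ensemble$poses <- lapply(ensemble$poses, function(pose) {
    mob_rec <- keep_chains(pose$structure, rc)
    fit <- superpose_structures(mob_rec, ref, chains = rc,
                                cycles = cycles, sigma_cut = sigma_cut)
    pose$structure <- transform_structure(pose$structure, fit$rotation,
                                          fit$translation)
    pose
  })
  ensemble
}
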
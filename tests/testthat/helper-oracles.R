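# Independent oracles used across the suite. Each is deliberately written
# by a different route than the package implementation it checks.

# Gotoh quadratic-space global alignment with affine gaps: a gap of length
# L costs open + L * extend. Returns the optimal score only.
oracle_global_affine_score <- function(a, b, submat, open = 10,
                                       extend = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (a aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Horn's closed-form quaternion solution for optimal superposition RMSD.
oracle_quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(P, Q)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# All-pairs double-loop contact oracle: for every receptor residue, the
# minimum distance to any ligand atom, via the full distance matrix.
oracle_contacts <- function(receptor, ligand, cutoff,
                            inclusive = TRUE) {
  ra <- receptor$atoms[toupper(receptor$atoms$element) != "H", ]
  la <- ligand$atoms[toupper(ligand$atoms$element) != "H", ]
  rxyz <- as.matrix(ra[, c("x", "y", "z")])
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  d2 <- outer(rowSums(rxyz^2), rep(1, nrow(lxyz))) +
        outer(rep(1, nrow(rxyz)), rowSums(lxyz^2)) -
        2 * rxyz %*% t(lxyz)
  d <- sqrt(pmax(d2, 0))
  rkey <- paste0(ra$chain, ":", ra$resno, ifelse(ra$insert == "", "",
                                                 ra$insert))
  mind <- tapply(apply(d, 1, min), rkey, min)
  # residue-level min distance to the ligand
  hit <- if (inclusive) mind <= cutoff else mind < cutoff
  list(keys = sort(names(mind)[hit]),
       min_distance = mind[hit])
}

# residue-pair level oracle (min distance per receptor x ligand residue)
oracle_contact_pairs <- function(receptor, ligand, cutoff,
                                 inclusive = FALSE) {
  ra <- receptor$atoms[toupper(receptor$atoms$element) != "H", ]
  la <- ligand$atoms[toupper(ligand$atoms$element) != "H", ]
  rkey <- paste0(ra$chain, ":", ra$resno, ifelse(ra$insert == "", "",
                                                 ra$insert))
  lkey <- paste0(la$chain, ":", la$resno, ifelse(la$insert == "", "",
                                                 la$insert))
  out <- list()
  for (i in seq_len(nrow(ra))) {
    d <- sqrt((ra$x[i] - la$x)^2 + (ra$y[i] - la$y)^2 +
              (ra$z[i] - la$z)^2)
    for (j in seq_along(d)) {
      id <- paste(rkey[i], lkey[j], sep = "|")
      if (is.null(out[[id]]) || d[j] < out[[id]]) out[[id]] <- d[j]
    }
  }
  keep <- if (inclusive) unlist(out) <= cutoff else unlist(out) < cutoff
  res <- unlist(out)[keep]
  res[order(names(res))]
}

# brute-force Venn membership via per-element set scan
oracle_venn <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  pat <- vapply(universe, function(el)
    paste(vapply(sets, function(s) as.integer(el %in% s), integer(1)),
          collapse = ""), character(1))
  split(universe, pat)
}

# union-find connected components on a thresholded distance graph
oracle_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

# quick random structure: n_res residues of 1-3 atoms in a box
random_structure <- function(n_res, chain = "A", box = 30,
                             resno_start = 1) {
  rows <- lapply(seq_len(n_res), function(i) {
    k <- sample(1:3, 1)
    center <- runif(3, 0, box)
    data.frame(chain = chain, resno = resno_start + i - 1, insert = "",
               resid = sample(c("ALA", "ARG", "SER", "GLU", "LEU"), 1),
               elety = c("CA", "CB", "CG")[seq_len(k)],
               element = "C",
               x = center[1] + c(0, runif(2, -1, 1))[seq_len(k)],
               y = center[2] + c(0, runif(2, -1, 1))[seq_len(k)],
               z = center[3] + c(0, runif(2, -1, 1))[seq_len(k)],
               o = 1, b = 0, stringsAsFactors = FALSE)
  })
  new_structure(do.call(rbind, rows))
}

# minimal single-residue structure helper for geometric fixtures
atoms_at <- function(chain, resno, resid, elety, element, xyz) {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
             stringsAsFactors = FALSE)
}

random_rotation_matrix <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
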
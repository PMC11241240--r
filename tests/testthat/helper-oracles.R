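# independent oracles kept deliberately separate from the implementation

# Horn quaternion-method superposition RMSD (independent of the SVD route)
quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lambda) / nrow(P)
  sqrt(max(0, msd))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# brute-force symmetry RMSD: try every atom permutation that preserves
# element and adjacency (with bond order)
brute_force_sym_rmsd <- function(pose, ref, ligand) {
  n <- nrow(pose)
  adj <- matrix(0L, n, n)
  b <- ligand$bonds
  for (k in seq_len(nrow(b))) {
    adj[b$i[k], b$j[k]] <- b$order[k]
    adj[b$j[k], b$i[k]] <- b$order[k]
  }
  el <- ligand$atoms$element
  best <- Inf
  for (p in all_perms(n)) {
    p <- unlist(p)
    if (any(el[p] != el)) next
    if (any(adj[p, p] != adj)) next
    best <- min(best, sqrt(mean(rowSums((pose[p, , drop = FALSE] - ref)^2))))
  }
  best
}

# reference (priority-rule) contact typing applied pairwise by hand, used to
# cross-check detect_contacts on random mini fixtures
rigid_motion <- function(xyz, seed = 1L) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  sweep(xyz %*% t(R), 2, runif(3, -20, 20), "+")
}
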
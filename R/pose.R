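#' Docked-pose evaluation
#'
#' Pose quality against a reference complex is measured by superposing the
#' docked receptor's alpha carbons onto the reference receptor's
#' (least-squares Kabsch fit), applying the transform to the docked ligand,
#' and computing the heavy-atom RMSD between docked and reference ligand
#' coordinates, minimized over the ligand bond-graph automorphisms so that
#' chemically equivalent atoms (e.g. the two ortho carbons of a
#' para-disubstituted ring, or the three methyls of a tert-butyl) do not
#' inflate the deviation. Poses are binned as successful (< 2 Angstrom),
#' acceptable (2-3, boundaries included), or unsuccessful (> 3); sampling
#' quality uses the best pose anywhere in the ensemble, scoring quality the
#' best pose among the top-ranked (lowest-energy) subset.
#'
#' @name pose_eval
NULL

#' Alpha-carbon superposition (Kabsch)
#'
#' Residues are matched by BW position when both complexes are annotated
#' with at least 3 shared positions, otherwise by author number and
#' insertion code. Requires at least 3 matched CA atoms.
#'
#' @param mobile,reference \code{gifp_complex} objects.
#' @return list(rotation 3x3, centroid_mobile, centroid_reference, ca_rmsd,
#'   n_matched). Apply with \code{\link{apply_transform}}.
#' @export
superpose_ca <- function(mobile, reference) {
  get_ca <- function(cx) {
    a <- cx$atoms[cx$atoms$atom_name == "CA", , drop = FALSE]
    key <- .res_key(a$chain, a$resnum, a$icode)
    rk <- .res_key(cx$residues$chain, cx$residues$resnum, cx$residues$icode)
    bw <- cx$residues$bw[match(key, rk)]
    list(xyz = as.matrix(a[, c("x", "y", "z")]), bw = bw,
         auth = paste(a$resnum, a$icode))
  }
  m <- get_ca(mobile); r <- get_ca(reference)
  shared_bw <- intersect(m$bw[!is.na(m$bw)], r$bw[!is.na(r$bw)])
  if (length(shared_bw) >= 3L) {
    mi <- match(shared_bw, m$bw); ri <- match(shared_bw, r$bw)
  } else {
    shared <- intersect(m$auth, r$auth)
    mi <- match(shared, m$auth); ri <- match(shared, r$auth)
  }
  if (length(mi) < 3L) stop("fewer than 3 matched CA atoms")
  P <- m$xyz[mi, , drop = FALSE]; Q <- r$xyz[ri, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Pc %*% R
  list(rotation = R, centroid_mobile = cp, centroid_reference = cq,
       ca_rmsd = sqrt(mean(rowSums((fitted - Qc)^2))),
       n_matched = length(mi))
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param transform output of \code{\link{superpose_ca}}.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(sweep(xyz, 2, transform$centroid_mobile) %*% transform$rotation,
        2, transform$centroid_reference, "+")
}

# element- and bond-order-preserving automorphisms of the ligand bond graph
.ligand_automorphisms <- function(ligand, cap = 10000L) {
  n <- nrow(ligand$atoms)
  b <- ligand$bonds
  if (n > 64L) return(NULL)
  if (nrow(b) == 0L) return(list(seq_len(n)))
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  vcol <- as.integer(factor(ligand$atoms$element))
  ecol <- as.integer(b$order)
  maps <- igraph::graph.get.isomorphisms.vf2(
    g, g, vertex.color1 = vcol, vertex.color2 = vcol,
    edge.color1 = ecol, edge.color2 = ecol)
  if (length(maps) > cap) return(NULL)
  lapply(maps, as.integer)
}

#' Symmetry-aware ligand heavy-atom RMSD
#'
#' Both coordinate sets must be in the same (already superposed) frame: no
#' re-fitting is performed on the ligand atoms. The reported value is the
#' minimum RMSD over all element- and bond-order-preserving automorphisms of
#' the ligand bond graph; beyond \code{cap} automorphisms (or 64 heavy
#' atoms) the identity mapping is used with a warning.
#'
#' @param pose_coords,reference_coords n x 3 heavy-atom coordinate matrices
#'   in matching atom order.
#' @param ligand the ligand (atom/bond graph) the coordinates describe; when
#'   NULL only the identity mapping is used.
#' @param cap automorphism-count safety cap.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pose_coords, reference_coords, ligand = NULL,
                        cap = 10000L) {
  pose_coords <- as.matrix(pose_coords)
  reference_coords <- as.matrix(reference_coords)
  if (!all(dim(pose_coords) == dim(reference_coords))) {
    stop("pose and reference atom counts differ")
  }
  rmsd_perm <- function(perm) {
    sqrt(mean(rowSums((pose_coords[perm, , drop = FALSE] -
                         reference_coords)^2)))
  }
  perms <- if (is.null(ligand)) list(seq_len(nrow(pose_coords)))
           else .ligand_automorphisms(ligand, cap)
  if (is.null(perms)) {
    warning("automorphism count exceeds the safety cap; using identity mapping")
    perms <- list(seq_len(nrow(pose_coords)))
  }
  min(vapply(perms, rmsd_perm, 1.0))
}

#' Construct a pose set
#'
#' @param reference the reference \code{gifp_complex}.
#' @param pose_coords list of ligand coordinate matrices (same atom order as
#'   the reference ligand), already in the reference frame or to be
#'   superposed by the caller.
#' @param scores docking scores, one per pose; lower = more favorable. Poses
#'   are stored sorted by score.
#' @param n_top size of the "scoring" subset (default 5).
#' @return object of class \code{gifp_pose_set}.
#' @export
pose_set <- function(reference, pose_coords, scores = seq_along(pose_coords),
                     n_top = 5L) {
  stopifnot(inherits(reference, "gifp_complex"),
            length(pose_coords) == length(scores))
  nref <- nrow(reference$ligand$atoms)
  if (any(vapply(pose_coords, nrow, 1L) != nref)) {
    stop("pose atom counts differ from the reference ligand")
  }
  ord <- order(scores)
  structure(list(reference = reference, poses = pose_coords[ord],
                 scores = scores[ord],
                 n_sampled = length(pose_coords),
                 n_top = min(as.integer(n_top), length(pose_coords))),
            class = "gifp_pose_set")
}

#' RMSD band categorization
#'
#' @param rmsd non-negative RMSD value(s) in Angstrom.
#' @return "successful" (< 2), "acceptable" (2-3, boundaries included) or
#'   "unsuccessful" (> 3).
#' @export
categorize_rmsd <- function(rmsd) {
  if (any(rmsd < 0)) stop("negative RMSD")
  ifelse(rmsd < 2, "successful",
         ifelse(rmsd <= 3, "acceptable", "unsuccessful"))
}

#' Evaluate one pose set
#'
#' @param ps a \code{gifp_pose_set}.
#' @return list(rmsd per pose in score order, best_in_all, best_in_top,
#'   category_sampling, category_scoring).
#' @export
evaluate_pose_set <- function(ps) {
  stopifnot(inherits(ps, "gifp_pose_set"))
  ref_xyz <- as.matrix(ps$reference$ligand$atoms[, c("x", "y", "z")])
  rmsd <- vapply(ps$poses, function(p) {
    ligand_rmsd(p, ref_xyz, ps$reference$ligand)
  }, 1.0)
  best_all <- min(rmsd)
  best_top <- min(rmsd[seq_len(ps$n_top)])
  list(rmsd = rmsd, best_in_all = best_all, best_in_top = best_top,
       category_sampling = categorize_rmsd(best_all),
       category_scoring = categorize_rmsd(best_top))
}

#' Sampling and scoring success percentages over pose sets
#'
#' @param pose_sets list of \code{gifp_pose_set} objects.
#' @return data.frame with rows "sampling" and "scoring" and columns
#'   successful, acceptable, successful_acceptable, unsuccessful (percent of
#'   pose sets in each band), plus n.
#' @export
summarize_pose_sets <- function(pose_sets) {
  if (length(pose_sets) == 0L) stop("no pose sets supplied")
  evals <- lapply(pose_sets, evaluate_pose_set)
  pct <- function(vals) {
    n <- length(vals)
    c(successful = 100 * sum(vals < 2) / n,
      acceptable = 100 * sum(vals >= 2 & vals <= 3) / n,
      successful_acceptable = 100 * sum(vals <= 3) / n,
      unsuccessful = 100 * sum(vals > 3) / n)
  }
  samp <- pct(vapply(evals, `[[`, 1.0, "best_in_all"))
  scor <- pct(vapply(evals, `[[`, 1.0, "best_in_top"))
  out <- as.data.frame(rbind(sampling = samp, scoring = scor))
  out$n <- length(pose_sets)
  out
}
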
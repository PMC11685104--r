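# SE(3)-invariant graph featurization of RNA backbones: per-nucleotide local
# frames from successive P-P bond vectors, backbone dihedral angles, Gaussian
# radial-basis distance encodings, k-nearest-neighbour topology and relative
# orientation quaternions.

#' Local reference frames from P-atom coordinates
#'
#' For each interior residue the frame columns are the negative bisector
#' `b = (u_i - u_{i+1}) / ||.||` of the incoming and outgoing unit bond
#' vectors between successive P atoms, the plane normal
#' `n = (u_i x u_{i+1}) / ||.||`, and `b x n`. First and last residues of
#' each contiguous segment get the identity rotation with `valid = FALSE`.
#' Near-collinear triples (cross-product norm below `1e-8`) get a
#' deterministic fallback: `n` is the unit vector orthogonal to `b` obtained
#' by projecting out the coordinate axis least aligned with `b`; these frames
#' are also flagged `valid = FALSE`.
#'
#' @param p_coords N x 3 matrix of P-atom coordinates (Angstrom), N >= 3.
#' @param segment Optional integer vector of contiguous-segment ids; frames
#'   never span a segment break.
#' @return List with `rotation` (N x 3 x 3 array; `[i, , k]` is the k-th
#'   column of residue i's rotation) and `valid` (logical N).
#' @export
local_frames <- function(p_coords, segment = NULL) {
  p_coords <- as.matrix(p_coords)
  n <- nrow(p_coords)
  if (n < 3L) stop("too short for frames (need at least 3 residues)")
  segment <- segment %||% rep(1L, n)
  rotation <- array(0, c(n, 3L, 3L))
  for (i in seq_len(n)) rotation[i, , ] <- diag(3L)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next
    if (segment[i] != segment[i - 1L] || segment[i] != segment[i + 1L]) next
    u_in <- p_coords[i, ] - p_coords[i - 1L, ]
    u_out <- p_coords[i + 1L, ] - p_coords[i, ]
    if (vec_norm(u_in) < 1e-12 || vec_norm(u_out) < 1e-12) next
    u_i <- u_in / vec_norm(u_in)
    u_next <- u_out / vec_norm(u_out)
    cr <- cross3(u_i, u_next)
    diff <- u_i - u_next
    if (vec_norm(cr) < 1e-8) {
      # collinear fallback: b along the chain direction if the bisector
      # degenerates; n by projecting out the least-aligned coordinate axis
      b <- if (vec_norm(diff) >= 1e-8) diff / vec_norm(diff) else u_i
      axis <- diag(3L)[, which.min(abs(b))]
      nvec <- axis - sum(axis * b) * b
      nvec <- nvec / vec_norm(nvec)
      rotation[i, , ] <- cbind(b, nvec, cross3(b, nvec))
      next  # valid stays FALSE
    }
    b <- diff / vec_norm(diff)
    nvec <- cr / vec_norm(cr)
    rotation[i, , ] <- cbind(b, nvec, cross3(b, nvec))
    valid[i] <- TRUE
  }
  list(rotation = rotation, valid = valid)
}

# Signed dihedral angle for one atom quadruple, in (-pi, pi].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vec_norm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# IUPAC nucleic-acid backbone torsion definitions. Offsets are relative
# residue indices for each of the four atoms.
DIHEDRAL_DEFS <- list(
  alpha = list(atoms = c("O3'", "P", "O5'", "C5'"), res = c(-1L, 0L, 0L, 0L)),
  beta  = list(atoms = c("P", "O5'", "C5'", "C4'"), res = c(0L, 0L, 0L, 0L)),
  gamma = list(atoms = c("O5'", "C5'", "C4'", "C3'"), res = c(0L, 0L, 0L, 0L)),
  delta = list(atoms = c("C5'", "C4'", "C3'", "O3'"), res = c(0L, 0L, 0L, 0L)),
  epsilon = list(atoms = c("C4'", "C3'", "O3'", "P"), res = c(0L, 0L, 0L, 1L)),
  zeta = list(atoms = c("C3'", "O3'", "P", "O5'"), res = c(0L, 0L, 1L, 1L)))

#' Backbone dihedral angles
#'
#' Computes the six backbone torsions per residue under the IUPAC
#' nucleic-acid convention: alpha O3'(i-1)-P-O5'-C5', beta P-O5'-C5'-C4',
#' gamma O5'-C5'-C4'-C3', delta C5'-C4'-C3'-O3', epsilon C4'-C3'-O3'-P(i+1),
#' zeta C3'-O3'-P(i+1)-O5'(i+1). Angles whose quadruple would cross a chain
#' terminus or segment break are masked (alpha at the first residue of a
#' segment; epsilon and zeta at the last).
#'
#' @param structure An `rna_backbone`.
#' @return List with `angles` (N x 6 matrix, radians in (-pi, pi], NA where
#'   masked) and `mask` (N x 6 logical, TRUE where defined).
#' @export
backbone_dihedrals <- function(structure) {
  stopifnot(inherits(structure, "rna_backbone"))
  n <- length(structure)
  coords <- structure$coords
  segment <- structure$segment
  angles <- matrix(NA_real_, n, 6L,
                   dimnames = list(NULL, names(DIHEDRAL_DEFS)))
  mask <- matrix(FALSE, n, 6L, dimnames = dimnames(angles))
  for (i in seq_len(n)) {
    for (a in seq_along(DIHEDRAL_DEFS)) {
      def <- DIHEDRAL_DEFS[[a]]
      idx <- i + def$res
      if (any(idx < 1L) || any(idx > n)) next
      if (length(unique(segment[unique(idx)])) > 1L) next
      pts <- lapply(seq_len(4L), function(k) coords[idx[k], def$atoms[k], ])
      angles[i, a] <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
      mask[i, a] <- TRUE
    }
  }
  list(angles = angles, mask = mask)
}

#' Gaussian radial-basis encoding of distances
#'
#' Component k is `exp(-((d - c_k) / width)^2)`. The default grid (16
#' centers linearly spaced on 0-20 Angstrom, width equal to the center
#' spacing) follows standard inverse-folding practice and is configurable.
#'
#' @param d Nonnegative distance(s), Angstrom.
#' @param centers RBF center vector.
#' @param width Kernel width (> 0); defaults to the center spacing.
#' @return Matrix `length(d) x length(centers)` of values in (0, 1].
#' @export
rbf_encode <- function(d, centers = seq(0, 20, length.out = 16L),
                       width = NULL) {
  if (any(d < 0)) stop("distances must be nonnegative")
  width <- width %||% (if (length(centers) > 1L) diff(centers[1:2]) else 1)
  if (width <= 0) stop("width must be positive")
  exp(-outer(d, centers, function(x, c) ((x - c) / width)^2))
}

#' k-nearest-neighbour graph over P atoms
#'
#' Each node's K nearest other nodes by Euclidean distance, ascending, ties
#' broken by lower index. When fewer than K other nodes exist, all of them
#' are listed and the remaining slots are masked padding (the padding index
#' repeats the nearest neighbour so indices stay valid and non-self).
#'
#' @param p_coords N x 3 matrix (N >= 2).
#' @param K Number of neighbours (>= 1, default 30).
#' @return List with `index` (N x K integer, 1-based) and `mask`
#'   (N x K logical, TRUE for real neighbours).
#' @export
knn_graph <- function(p_coords, K = 30L) {
  p_coords <- as.matrix(p_coords)
  n <- nrow(p_coords)
  if (n < 2L) stop("graph needs >=2 nodes")
  stopifnot(K >= 1L)
  dmat <- as.matrix(stats::dist(p_coords))
  index <- matrix(1L, n, K)
  mask <- matrix(FALSE, n, K)
  k_real <- min(K, n - 1L)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(dmat[i, others], others)]
    nb <- ord[seq_len(k_real)]
    index[i, ] <- c(nb, rep(nb[1L], K - k_real))
    mask[i, seq_len(k_real)] <- TRUE
  }
  list(index = index, mask = mask)
}

# Rotation matrix -> unit quaternion (w, x, y, z), numerically stable branch
# selection; sign fixed so w >= 0 (if w == 0, first nonzero of x,y,z > 0).
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / vec_norm(q)
  if (q[1] < 0 || (q[1] == 0 && {
    nz <- which(q[2:4] != 0)
    length(nz) > 0 && q[1 + nz[1]] < 0
  })) q <- -q
  q
}

#' Relative orientation quaternion between two local frames
#'
#' Unit quaternion (scalar-first, w >= 0) of the rotation `Q_i^T Q_j`.
#'
#' @param frame_i,frame_j 3 x 3 rotation matrices.
#' @return Numeric length-4 unit quaternion (w, x, y, z).
#' @export
quaternion_orientation <- function(frame_i, frame_j) {
  rotmat_to_quat(t(frame_i) %*% frame_j)
}

#' Graph featurization configuration
#'
#' @param K Number of neighbours (default 30).
#' @param rbf_count Number of RBF centers (default 16).
#' @param rbf_min,rbf_max RBF center range in Angstrom (default 0-20).
#' @return A list of class `graph_config`.
#' @export
graph_config <- function(K = 30L, rbf_count = 16L, rbf_min = 0, rbf_max = 20) {
  stopifnot(K >= 1L, rbf_count >= 2L, rbf_max > rbf_min)
  structure(list(K = as.integer(K), rbf_count = as.integer(rbf_count),
                 rbf_min = rbf_min, rbf_max = rbf_max),
            class = "graph_config")
}

rbf_centers <- function(config) {
  seq(config$rbf_min, config$rbf_max, length.out = config$rbf_count)
}

# Machine-readable feature dictionary: name -> [from, to] column ranges.
feature_dictionary <- function(config) {
  nr <- config$rbf_count
  node <- list(); at <- 1L
  add <- function(dict, name, width) {
    dict[[name]] <- c(at, at + width - 1L)
    at <<- at + width
    dict
  }
  for (nm in names(DIHEDRAL_DEFS)) node <- add(node, paste0("dihedral_", nm), 2L)
  for (atom in BACKBONE_ATOMS[-1]) node <- add(node, paste0("dist_", atom), nr)
  for (atom in BACKBONE_ATOMS[-1]) node <- add(node, paste0("dir_", atom), 3L)
  f_n <- at - 1L
  edge <- list(); at <- 1L
  edge <- add(edge, "orientation_quaternion", 4L)
  for (atom in BACKBONE_ATOMS[-1]) edge <- add(edge, paste0("dist_", atom), nr)
  for (atom in BACKBONE_ATOMS[-1]) edge <- add(edge, paste0("dir_", atom), 3L)
  f_m <- at - 1L
  list(node = node, edge = edge, f_n = f_n, f_m = f_m)
}

feature_dictionary_hash <- function(config) {
  dict <- feature_dictionary(config)
  fnv1a_hash(paste(
    c(vapply(names(dict$node), function(n) paste(n, dict$node[[n]][1],
                                                 dict$node[[n]][2]), ""),
      vapply(names(dict$edge), function(n) paste(n, dict$edge[[n]][1],
                                                 dict$edge[[n]][2]), ""),
      config$K, config$rbf_count, config$rbf_min, config$rbf_max),
    collapse = ";"))
}

#' Build the attributed structure graph
#'
#' Node features per residue: sin/cos of the six backbone dihedrals (12),
#' RBF encodings of the distance from each non-P backbone atom to P (5 x
#' rbf_count), and the unit direction of each non-P atom relative to P in
#' the residue's local frame (15). Edge features per (i, j): the quaternion
#' of `Q_i^T Q_j` (4), RBF encodings of the distances from j's non-P atoms
#' to P_i (5 x rbf_count), and the local-frame unit directions of those
#' atoms from P_i (15). With the default 16 RBF centers this gives
#' `f_n = 107` node and `f_m = 99` edge features.
#'
#' All features are functions of distances and frame-relative coordinates,
#' hence invariant to global rotation and translation. Features that need a
#' valid local frame are masked where the frame is degenerate (termini,
#' collinear geometry): direction vectors become zero and orientation
#' quaternions the identity, which keeps the invariance exact. Zero-length
#' direction vectors (norm < 1e-8) also encode as zero.
#'
#' @param structure An `rna_backbone` with N >= 3.
#' @param config A [graph_config()].
#' @return An object of class `rna_graph`: list with `node` (N x f_n),
#'   `edge` (N x K x f_m), `index`, `mask` (N x K), `node_mask` (length N,
#'   all TRUE here; padding introduced by [pad_graph()]), `frames`,
#'   `config`, `feature_dict` and `n`.
#' @export
build_graph <- function(structure, config = graph_config()) {
  stopifnot(inherits(structure, "rna_backbone"))
  n <- length(structure)
  if (n < 3L) stop("too short for frames (need at least 3 residues)")
  coords <- structure$coords
  p <- coords[, "P", , drop = TRUE]
  frames <- local_frames(p, structure$segment)
  dih <- backbone_dihedrals(structure)
  knn <- knn_graph(p, config$K)
  centers <- rbf_centers(config)
  nr <- config$rbf_count
  dict <- feature_dictionary(config)

  sc <- matrix(0, n, 12L)
  for (a in seq_len(6L)) {
    ok <- dih$mask[, a]
    sc[ok, 2L * a - 1L] <- sin(dih$angles[ok, a])
    sc[ok, 2L * a] <- cos(dih$angles[ok, a])
  }

  other <- BACKBONE_ATOMS[-1]
  node <- matrix(0, n, dict$f_n)
  node[, 1:12] <- sc
  for (k in seq_along(other)) {
    v <- coords[, other[k], , drop = TRUE] - p          # N x 3
    dist <- sqrt(rowSums(v * v))
    node[, 12L + (k - 1L) * nr + seq_len(nr)] <- rbf_encode(dist, centers)
    dir_block <- matrix(0, n, 3L)
    usable <- frames$valid & dist >= 1e-8
    for (i in which(usable)) {
      dir_block[i, ] <- crossprod(frames$rotation[i, , ], v[i, ]) / dist[i]
    }
    node[, 12L + 5L * nr + (k - 1L) * 3L + seq_len(3L)] <- dir_block
  }

  # Edge features, vectorized over the flat node-major edge list.
  K <- config$K
  ne <- n * K
  i_idx <- rep(seq_len(n), each = K)
  j_idx <- as.vector(t(knn$index))
  mflat <- as.vector(t(knn$mask))
  eflat <- matrix(0, ne, dict$f_m)
  eflat[mflat, 1L] <- 1  # identity quaternion default for masked frames
  both_valid <- mflat & frames$valid[i_idx] & frames$valid[j_idx]
  for (e in which(both_valid)) {
    eflat[e, 1:4] <- quaternion_orientation(
      frames$rotation[i_idx[e], , ], frames$rotation[j_idx[e], , ])
  }
  rot_i <- frames$rotation[i_idx, , , drop = FALSE]   # ne x 3 x 3
  dir_ok_i <- mflat & frames$valid[i_idx]
  for (k in seq_along(other)) {
    v <- coords[j_idx, other[k], , drop = TRUE] - p[i_idx, , drop = FALSE]
    dist <- sqrt(rowSums(v * v))
    rb <- rbf_encode(dist, centers)
    rb[!mflat, ] <- 0
    eflat[, 4L + (k - 1L) * nr + seq_len(nr)] <- rb
    ok <- dir_ok_i & dist >= 1e-8
    dir_block <- matrix(0, ne, 3L)
    for (a in 1:3) {
      dir_block[ok, a] <- rowSums(matrix(rot_i[ok, , a], ncol = 3L) *
                                    v[ok, , drop = FALSE]) / dist[ok]
    }
    eflat[, 4L + 5L * nr + (k - 1L) * 3L + seq_len(3L)] <- dir_block
  }
  edge <- aperm(array(t(eflat), c(dict$f_m, K, n)), c(3L, 2L, 1L))

  structure(list(node = node, edge = edge, index = knn$index, mask = knn$mask,
                 node_mask = rep(TRUE, n), frames = frames, config = config,
                 feature_dict = dict, n = n),
            class = "rna_graph")
}

#' Pad a structure graph to a target length
#'
#' Appends padded positions (zero node features, fully masked neighbour
#' slots) so graphs of one length bucket can be batched together. Padded
#' positions are excluded from message passing and losses via `node_mask`.
#'
#' @param graph An `rna_graph`.
#' @param target_n Target node count (>= graph$n).
#' @return A padded `rna_graph`.
#' @export
pad_graph <- function(graph, target_n) {
  stopifnot(inherits(graph, "rna_graph"), target_n >= graph$n)
  if (target_n == graph$n) return(graph)
  extra <- target_n - graph$n
  K <- graph$config$K
  f_m <- graph$feature_dict$f_m
  out <- graph
  out$node <- rbind(graph$node, matrix(0, extra, ncol(graph$node)))
  edge <- array(0, c(target_n, K, f_m))
  edge[seq_len(graph$n), , ] <- graph$edge
  out$edge <- edge
  out$index <- rbind(graph$index, matrix(1L, extra, K))
  out$mask <- rbind(graph$mask, matrix(FALSE, extra, K))
  out$node_mask <- c(graph$node_mask, rep(FALSE, extra))
  out$n <- target_n
  out
}
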
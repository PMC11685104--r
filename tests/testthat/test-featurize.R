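test_that("local frames match the hand-evaluated bisector construction", {
  fr <- local_frames(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(fr$valid, c(FALSE, TRUE, FALSE))
  Q <- fr$rotation[2, , ]
  expect_equal(Q[, 1], c(sqrt(0.5), -sqrt(0.5), 0), tolerance = 1e-7)
  expect_equal(Q[, 2], c(0, 0, 1), tolerance = 1e-7)
  expect_equal(Q[, 3], c(-sqrt(0.5), -sqrt(0.5), 0), tolerance = 1e-7)
  # termini carry the identity rotation
  expect_equal(fr$rotation[1, , ], diag(3))
})

test_that("valid frames are orthonormal with determinant +1", {
  for (seed in 1:10) {
    st <- random_backbone(25, seed)
    fr <- local_frames(st$coords[, "P", ], st$segment)
    for (i in which(fr$valid)) {
      Q <- fr$rotation[i, , ]
      expect_lt(max(abs(crossprod(Q) - diag(3))), 1e-6)
      expect_equal(det(Q), 1, tolerance = 1e-6)
    }
  }
})

test_that("collinear P atoms trigger a finite orthonormal fallback frame", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  fr <- local_frames(p)
  expect_equal(fr$valid, rep(FALSE, 4))
  for (i in 2:3) {
    Q <- fr$rotation[i, , ]
    expect_true(all(is.finite(Q)))
    expect_lt(max(abs(crossprod(Q) - diag(3))), 1e-6)
    expect_equal(det(Q), 1, tolerance = 1e-6)
  }
  expect_error(local_frames(p[1:2, ]), "too short")
})

test_that("frames never span segment breaks", {
  st <- random_backbone(10, seed = 3)
  st$segment <- c(rep(1L, 5), rep(2L, 5))
  fr <- local_frames(st$coords[, "P", ], st$segment)
  expect_false(fr$valid[5])  # last of segment 1
  expect_false(fr$valid[6])  # first of segment 2
  expect_true(all(fr$valid[c(2:4, 7:9)]))
})

test_that("backbone dihedrals agree with the projection oracle and bio3d", {
  for (seed in 1:8) {
    st <- random_backbone(12, seed, sigma = 0.5)
    dih <- backbone_dihedrals(st)
    defs <- rnadesign:::DIHEDRAL_DEFS
    for (i in 1:12) {
      for (a in seq_along(defs)) {
        def <- defs[[a]]
        idx <- i + def$res
        if (any(idx < 1L | idx > 12L)) {
          expect_false(dih$mask[i, a])
          next
        }
        pts <- lapply(1:4, function(k) st$coords[idx[k], def$atoms[k], ])
        expect_equal(unname(dih$angles[i, a]),
                     oracle_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
                     tolerance = 1e-9)
        # bio3d::torsion.xyz returns the opposite-signed convention
        expect_equal(dih$angles[i, a] * 180 / pi,
                     -bio3d::torsion.xyz(unlist(pts)),
                     tolerance = 1e-6, ignore_attr = TRUE)
      }
    }
  }
})

test_that("planar quadruples give 0 and staggered quadruples +/- pi/2", {
  # cis (eclipsed) arrangement: all four atoms coplanar, ends on same side
  expect_equal(rnadesign:::dihedral_angle(c(1, 1, 0), c(0, 1, 0),
                                          c(0, 0, 0), c(1, 0, 0)), 0)
  # trans arrangement: pi
  expect_equal(abs(rnadesign:::dihedral_angle(c(-1, 1, 0), c(0, 1, 0),
                                              c(0, 0, 0), c(1, 0, 0))), pi)
  # +/- 90 degrees, sign checked against the oracle
  a <- rnadesign:::dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, 0, 1))
  expect_equal(a, oracle_dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, 0, 1)))
  expect_equal(abs(a), pi / 2)
})

test_that("terminal and chain-break dihedrals are masked", {
  st <- random_backbone(8, seed = 2)
  dih <- backbone_dihedrals(st)
  expect_false(dih$mask[1, "alpha"])
  expect_false(dih$mask[8, "epsilon"])
  expect_false(dih$mask[8, "zeta"])
  expect_true(all(dih$mask[2:7, ]))
  st$segment <- c(rep(1L, 4), rep(2L, 4))
  dih2 <- backbone_dihedrals(st)
  expect_false(dih2$mask[4, "epsilon"])
  expect_false(dih2$mask[4, "zeta"])
  expect_false(dih2$mask[5, "alpha"])
})

test_that("rbf_encode has unit peaks at centers and Gaussian decay", {
  centers <- seq(0, 20, length.out = 16)
  width <- centers[2] - centers[1]
  enc <- rbf_encode(centers[5], centers, width)
  expect_equal(enc[1, 5], 1)
  expect_equal(rbf_encode(centers[5] + width, centers, width)[1, 5],
               exp(-1))
  expect_true(all(rbf_encode(100, centers, width) < 1e-6))
  expect_true(all(rbf_encode(runif(50, 0, 30), centers, width) > 0))
  expect_true(all(rbf_encode(runif(50, 0, 30), centers, width) <= 1))
  expect_error(rbf_encode(-1, centers, width), "nonnegative")
  expect_error(rbf_encode(1, centers, width = 0), "positive")
})

test_that("knn_graph matches the brute-force oracle with tie and clamp policies", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:40, 1)
    K <- sample(1:12, 1)
    p <- matrix(rnorm(n * 3, sd = 5), n, 3)
    g <- knn_graph(p, K)
    ora <- oracle_knn(p, K)
    k_real <- min(K, n - 1)
    expect_identical(g$index[, seq_len(k_real), drop = FALSE], ora)
    expect_true(all(g$mask[, seq_len(k_real)]))
    if (K > k_real) expect_false(any(g$mask[, (k_real + 1):K]))
    expect_true(all(g$index != row(g$index)))  # no self-edges
  }
  # exact ties on a lattice: lower index listed first
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  g <- knn_graph(p, 3)
  expect_equal(g$index[1, ], c(2L, 3L, 4L))
  # K exceeding N-1 clamps with masked padding
  g2 <- knn_graph(p[1:3, ], 30)
  expect_equal(sum(g2$mask[1, ]), 2L)
  expect_error(knn_graph(p[1, , drop = FALSE], 3), ">=2 nodes")
})

test_that("quaternion orientation matches axis-angle oracles", {
  I3 <- diag(3)
  expect_equal(quaternion_orientation(I3, I3), c(1, 0, 0, 0))
  # 180-degree rotation about the frame's third axis
  Qj <- I3 %*% axis_angle_matrix(c(0, 0, 1), pi)
  expect_equal(quaternion_orientation(I3, Qj), c(0, 0, 0, 1),
               tolerance = 1e-9)
  set.seed(5)
  for (rep in 1:25) {
    axis <- rnorm(3)
    theta <- runif(1, -pi, pi)
    R <- axis_angle_matrix(axis, theta)
    q <- quaternion_orientation(I3, R)
    expect_equal(vecnorm <- sqrt(sum(q^2)), 1, tolerance = 1e-6)
    expect_gte(q[1], 0)
    q_ora <- axis_angle_quaternion(axis, theta)
    expect_equal(q, q_ora, tolerance = 1e-9)
    # composed with a random base frame: relative rotation is recovered
    base <- random_rigid_transform()$R
    expect_equal(quaternion_orientation(base, base %*% R), q_ora,
                 tolerance = 1e-9)
  }
})

test_that("build_graph produces the documented feature dimensions", {
  st <- random_backbone(40, seed = 13)
  g <- build_graph(st)  # defaults: K = 30, 16 RBF centers
  expect_equal(dim(g$node), c(40L, 107L))
  expect_equal(dim(g$edge), c(40L, 30L, 99L))
  expect_equal(g$feature_dict$f_n, 107L)
  expect_equal(g$feature_dict$f_m, 99L)
  expect_true(all(is.finite(g$node)))
  expect_true(all(is.finite(g$edge)))
  expect_error(build_graph(random_backbone(3, 1)[c("chain_id")]), "rna_backbone")
  st2 <- synth_helix(3)
  st2$coords <- st2$coords[1:2, , , drop = FALSE]
  st2$residue_number <- 1:2; st2$residue_name <- c("A", "A")
  st2$insert <- c("", ""); st2$segment <- c(1L, 1L)
  expect_error(build_graph(st2), "too short")
})

test_that("graph features are SE(3)-invariant on random structures", {
  set.seed(99)
  for (rep in 1:10) {
    st <- random_backbone(sample(10:40, 1), seed = rep)
    g <- build_graph(st, graph_config(K = 8))
    tr <- random_rigid_transform()
    g2 <- build_graph(apply_rigid(st, tr), graph_config(K = 8))
    expect_lt(max(abs(g$node - g2$node)), 1e-5)
    expect_lt(max(abs(g$edge - g2$edge)), 1e-5)
  }
})

test_that("invalid-frame positions zero their direction features", {
  st <- random_backbone(10, seed = 4)
  g <- build_graph(st, graph_config(K = 4))
  dict <- g$feature_dict
  dir_cols <- unlist(lapply(grep("^dir_", names(dict$node)), function(i) {
    seq(dict$node[[i]][1], dict$node[[i]][2])
  }))
  expect_true(all(g$node[1, dir_cols] == 0))   # terminus: invalid frame
  expect_true(all(g$node[10, dir_cols] == 0))
  expect_false(all(g$node[5, dir_cols] == 0))  # interior: populated
})

test_that("pad_graph appends fully masked zero positions", {
  st <- random_backbone(8, seed = 6)
  g <- build_graph(st, graph_config(K = 4))
  gp <- pad_graph(g, 12)
  expect_equal(gp$n, 12L)
  expect_equal(gp$node_mask, c(rep(TRUE, 8), rep(FALSE, 4)))
  expect_true(all(gp$node[9:12, ] == 0))
  expect_false(any(gp$mask[9:12, ]))
  expect_identical(gp$node[1:8, ], g$node)
})
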
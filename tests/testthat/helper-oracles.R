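# Independent oracles, coded by different routes than the implementation.

# Dihedral by projection onto the plane perpendicular to the central bond
# (the implementation uses the plane-normal atan2 route instead).
oracle_dihedral <- function(p1, p2, p3, p4) {
  u2 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  w1 <- (p1 - p2) - sum((p1 - p2) * u2) * u2
  w4 <- (p4 - p3) - sum((p4 - p3) * u2) * u2
  cr <- c(w4[2] * w1[3] - w4[3] * w1[2],
          w4[3] * w1[1] - w4[1] * w1[3],
          w4[1] * w1[2] - w4[2] * w1[1])
  atan2(sum(cr * u2), sum(w1 * w4))
}

# Brute-force k-NN: full O(N^2) pairwise distances, full sort with the
# (distance, index) tie rule.
oracle_knn <- function(p, K) {
  n <- nrow(p)
  k_real <- min(K, n - 1L)
  idx <- matrix(0L, n, k_real)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(p) - p[i, ])^2))
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    idx[i, ] <- ord[seq_len(k_real)]
  }
  idx
}

# Direct triple-loop cross-entropy summations.
oracle_sequence_loss <- function(per_iteration, idx) {
  total <- 0
  for (P in per_iteration) {
    for (i in seq_along(idx)) {
      if (is.na(idx[i])) next
      total <- total - log(max(P[i, idx[i]], 1e-9))
    }
  }
  total
}

oracle_secondary_loss <- function(pred, idx) {
  total <- 0
  for (i in seq_along(idx)) {
    if (is.na(idx[i])) next
    total <- total - log(max(pred[i, idx[i]], 1e-9))
  }
  total
}

# Confusion-matrix macro-F1 via table(), pooled.
oracle_macro_f1 <- function(designed_chars, native_chars) {
  classes <- c("A", "U", "C", "G")
  tab <- table(factor(native_chars, classes), factor(designed_chars, classes))
  f1 <- numeric(0)
  for (cl in classes) {
    support <- sum(tab[cl, ]) + sum(tab[, cl])
    if (support == 0) next
    tp <- tab[cl, cl]
    f1 <- c(f1, if (tp == 0) 0 else {
      prec <- tp / sum(tab[, cl])
      rec <- tp / sum(tab[cl, ])
      2 * prec * rec / (prec + rec)
    })
  }
  100 * mean(f1)
}

oracle_recovery <- function(designed_chars, native_chars) {
  100 * sum(designed_chars == native_chars) / length(designed_chars)
}

# Axis-angle rotation matrix (Rodrigues), for quaternion oracle tests.
axis_angle_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  Kx <- matrix(c(0, axis[3], -axis[2],
                 -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * Kx + (1 - cos(theta)) * Kx %*% Kx
}

axis_angle_quaternion <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  q <- c(cos(theta / 2), sin(theta / 2) * axis)
  if (q[1] < 0) q <- -q
  q
}

# One-pass bracket-counter validity oracle for dot-bracket strings.
oracle_balanced <- function(symbols) {
  depth <- 0L
  for (ch in strsplit(symbols, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return(FALSE)
  }
  depth == 0L
}

random_rigid_transform <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 20))
}

apply_rigid <- function(structure, transform) {
  out <- structure
  n <- length(structure)
  for (a in seq_len(6)) {
    out$coords[, a, ] <- structure$coords[, a, ] %*% t(transform$R) +
      rep(transform$t, each = n)
  }
  out
}
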
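# Independent brute-force oracles and small fixture builders.
# These re-derive the geometric definitions with plain loops, sharing no
# code with the package implementation.

# all-pairs hydrogen-bond oracle: loops over every registered (D, H) and
# acceptor, recomputing distance and deviation-from-linearity directly
oracle_hbonds <- function(frame, registry, criteria,
                          donor_idx = NULL, acceptor_idx = NULL) {
  topo <- frame$topology
  xyz <- frame$xyz
  hits <- list()
  for (di in seq_len(nrow(registry$donors))) {
    row <- registry$donors[di, ]
    h_at <- which(topo$residue_name == row$residue_name &
                    topo$atom_name == row$hydrogen)
    for (H in h_at) {
      D <- which(topo$residue_name == row$residue_name &
                   topo$atom_name == row$donor &
                   topo$residue_id == topo$residue_id[H] &
                   topo$chain_id == topo$chain_id[H])
      if (length(D) != 1L) next
      if (!is.null(donor_idx) && !(D %in% donor_idx)) next
      for (ai in seq_len(nrow(registry$acceptors))) {
        arow <- registry$acceptors[ai, ]
        A_at <- which(topo$residue_name == arow$residue_name &
                        topo$atom_name == arow$atom)
        for (A in A_at) {
          if (A == D || A == H) next
          if (!is.null(acceptor_idx) && !(A %in% acceptor_idx)) next
          d <- sqrt(sum((xyz[A, ] - xyz[H, ])^2))
          if (d > criteria$d_max) next
          u <- xyz[H, ] - xyz[D, ]
          v <- xyz[A, ] - xyz[H, ]
          cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
          ang <- acos(min(1, max(-1, cosang))) * 180 / pi
          if (ang > criteria$angle_max) next
          hits[[length(hits) + 1L]] <- c(H = H, A = A)
        }
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2,
                                   dimnames = list(NULL, c("H", "A"))))
  m <- do.call(rbind, hits)
  m <- unique(m)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# all-pairs repulsive-contact oracle at the group-pair level
oracle_contacts <- function(frame, groups, cutoff) {
  idx <- lapply(groups, function(g) resolve_selection(g, frame))
  idx <- idx[lengths(idx) > 0]
  n <- length(idx)
  count <- 0L
  if (n < 2L) return(0L)
  for (a in 2:n) {
    for (b in 1:(a - 1)) {
      touching <- FALSE
      for (i in idx[[a]]) {
        for (j in idx[[b]]) {
          if (sqrt(sum((frame$xyz[i, ] - frame$xyz[j, ])^2)) <= cutoff)
            touching <- TRUE
        }
      }
      if (touching) count <- count + 1L
    }
  }
  count
}

# random frame of n atoms in a small box, all of them serine-hydroxyl
# donors and water-oxygen acceptors so that many near-cutoff pairs occur
random_polar_frame <- function(n = 50, box = 8, seed = 1) {
  set.seed(seed)
  n_don <- floor(n / 3)
  topo <- rbind(
    atom_topology(rep(c("OG", "HG"), n_don), "SER",
                  rep(seq_len(n_don), each = 2)),
    atom_topology(rep("O", n - 2 * n_don), "HOH",
                  1000L + seq_len(n - 2 * n_don))
  )
  xyz <- matrix(runif(nrow(topo) * 3, 0, box), ncol = 3)
  # keep each hydrogen ~1 A from its donor so angles are meaningful
  for (k in seq_len(n_don)) {
    d <- 2 * k - 1
    xyz[d + 1, ] <- xyz[d, ] + stats::rnorm(3, 0, 0.6)
  }
  md_frame(topo, xyz)
}

# rigid-body motion helper: random proper rotation + translation
random_rigid_motion <- function(seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- rnorm(3, 0, 10)
  list(R = R, t = t)
}

apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% motion$R, 2, -motion$t)
}

transform_ensemble <- function(ens, motion) {
  md_ensemble(ens$topology,
              lapply(ens$runs, function(run)
                lapply(run, apply_rigid, motion = motion)),
              equilibration_fraction = ens$equilibration_fraction,
              label = ens$label)
}

expect_events_equal_oracle <- function(frame, registry, criteria, ...) {
  got <- detect_hbonds(frame, registry, criteria, ...)
  want <- oracle_hbonds(frame, registry, criteria)
  got_pairs <- unique(cbind(H = got$hydrogen, A = got$acceptor))
  expect_equal(nrow(got_pairs), nrow(want))
  if (nrow(want))
    expect_true(all(paste(got_pairs[, 1], got_pairs[, 2]) %in%
                      paste(want[, 1], want[, 2])))
}
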
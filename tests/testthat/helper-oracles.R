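# Independent oracles and shared fixtures for the test suite.

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force rotation-search RMSD oracle: coarse random-quaternion scan
# followed by Nelder-Mead refinement over an axis-angle parameterisation.
# Independent of the Kabsch code path.
oracle_superpose_rmsd <- function(A, B, n_grid = 2000) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  rot_from_par <- function(p) {
    # p = rotation vector (axis * angle)
    theta <- sqrt(sum(p^2))
    if (theta < 1e-12) return(diag(3))
    k <- p / theta
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  }
  rmsd_of <- function(R) sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  best_val <- Inf
  best_par <- c(0, 0, 0)
  for (i in seq_len(n_grid)) {
    # uniform random rotation via normalized quaternion
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; v <- q[2:4]
    theta <- 2 * acos(pmin(1, abs(w)))
    axis <- if (sqrt(sum(v^2)) < 1e-12) c(1, 0, 0) else v / sqrt(sum(v^2))
    p <- axis * theta * sign(w + (w == 0))
    val <- rmsd_of(rot_from_par(p))
    if (val < best_val) {
      best_val <- val
      best_par <- p
    }
  }
  opt <- optim(best_par, function(p) rmsd_of(rot_from_par(p)),
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  min(best_val, opt$value)
}

# naive sliding-window motif oracle: every start, both spacer lengths,
# leftmost-first, shorter spacer preferred, non-overlapping
oracle_scan_motif <- function(seq, spacers = c(17L, 18L)) {
  chars <- strsplit(seq, "")[[1]]
  hits <- list()
  i <- 1L
  while (i <= length(chars)) {
    found <- FALSE
    for (sp in sort(spacers)) {
      len <- 6L + sp + 1L
      if (i + len - 1L > length(chars)) next
      w <- chars[i:(i + len - 1L)]
      if (w[1] == "G" && w[3] == "G" && w[6] == "G" &&
          w[len] %in% c("E", "D")) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = i, end = i + len - 1L, spacer_length = sp,
          acidic_residue = w[len], stringsAsFactors = FALSE)
        i <- i + len
        found <- TRUE
        break
      }
    }
    if (!found) i <- i + 1L
  }
  if (length(hits) == 0L) {
    data.frame(start = integer(), end = integer(), spacer_length = integer(),
               acidic_residue = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, hits)
  }
}

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# the ten published non-square KtrA ring diagonal pairs (L1/L2, Angstrom)
published_nonsquare_pairs <- function() {
  tibble::tibble(
    name = c("WT-ADP", "R16K-ADP", "R16A-ADP-r1", "R16A-ADP-r2",
             "A80P-ATP", "A80P-ADP", "E125Q-ATP-r1", "E125Q-ATP-r2",
             "E125Q-ADP-r1", "E125Q-ADP-r2"),
    L1 = c(40.7, 52.0, 34, 37, 52, 52, 34, 42, 34, 42),
    L2 = c(30.7, 21.9, 30, 28, 23, 22, 30, 27, 30, 27)
  )
}

# rigid transform of an atom tibble
transform_atoms <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R) +
    matrix(t, nrow(atoms), 3, byrow = TRUE)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}
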
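#' Cross-ring diagonal metrics (L1/L2)
#'
#' Computes the four cross-ring diagonal distances between marker C-alpha
#' atoms of opposite subunits (ring positions i and i+4), partitions them
#' into the two two-fold-related pairs ({1,3} and {2,4} in ring order), and
#' reports L1 as the mean of the pair with the larger mean and L2 as the
#' other. When all four diagonals agree within 0.2 Å (a four-fold ring),
#' L1 = L2 = the overall mean. The default marker, residue 38, is the
#' asparagine whose C-alpha separation across the KtrA ring face
#' distinguishes the square (L1 = L2) from the non-square (L1 > L2) state.
#'
#' @param ring An `rck_ring` from [build_ring()].
#' @param marker_residue Author residue number of the marker (default 38).
#' @return One-row tibble: `L1`, `L2`, `asymmetry` (= L1 - L2) in Å, and a
#'   `diagonals` list-column holding the four raw diagonals in ring order.
#' @export
compute_l1_l2 <- function(ring, marker_residue = 38) {
  m <- marker_coords(ring, marker_residue, "CA")
  d <- sqrt(rowSums((m[1:4, , drop = FALSE] - m[5:8, , drop = FALSE])^2))
  d <- unname(d)
  if (max(d) - min(d) <= 0.2) {
    L1 <- L2 <- mean(d)
  } else {
    pair_means <- c(mean(d[c(1, 3)]), mean(d[c(2, 4)]))
    L1 <- max(pair_means)
    L2 <- min(pair_means)
  }
  tibble(L1 = L1, L2 = L2, asymmetry = L1 - L2, diagonals = list(d))
}

#' Intra-dimer marker distances
#'
#' RCK subunits pair into four compact dimers around the ring; consecutive
#' subunits in angular order form a dimer, anchored so that the consecutive
#' pair with the smallest inter-centroid distance starts a dimer (ties break
#' toward ring position 1). The default marker, residue 36, is the conserved
#' aspartate of the nucleotide-binding site whose C-alpha separation reports
#' closure of the intra-dimer interface.
#'
#' @inheritParams compute_l1_l2
#' @param marker_residue Author residue number of the marker (default 36).
#' @return Numeric vector of 4 distances (Å), one per dimer in ring order.
#' @export
intra_dimer_distances <- function(ring, marker_residue = 36) {
  pairs <- dimer_pairs(ring)
  m <- marker_coords(ring, marker_residue, "CA")
  vapply(pairs, function(p) vec_norm(m[p[1], ] - m[p[2], ]), numeric(1))
}

# dimer pairing: consecutive subunits, anchored at the closest consecutive pair
dimer_pairs <- function(ring) {
  cents <- ring$subunit_centroids
  gaps <- vapply(1:8, function(i) {
    j <- if (i == 8L) 1L else i + 1L
    vec_norm(cents[i, ] - cents[j, ])
  }, numeric(1))
  anchor <- which.min(round(gaps, 6))        # ties -> lowest ring position
  start <- if (anchor %% 2L == 1L) 1L else 2L
  lapply(0:3, function(k) {
    i <- ((start - 1L + 2L * k) %% 8L) + 1L
    j <- (i %% 8L) + 1L
    c(i, j)
  })
}

#' Classify ring conformations as square or non-square
#'
#' A ring is called square when the difference between its two cross-ring
#' diagonal means does not exceed `threshold` (default 2.0 Å — the printed
#' square rings all have asymmetry 0 and the non-square ones at least 4 Å,
#' so 2.0 splits them with margin). The call is symmetric in L1 and L2.
#'
#' @param metrics Data frame with columns `L1` and `L2` (e.g. from
#'   [compute_l1_l2()], one row per ring).
#' @param threshold Å; must be positive.
#' @return `metrics` with added columns `label` (`"square"`/`"non-square"`)
#'   and `threshold`.
#' @export
classify_conformation <- function(metrics, threshold = 2.0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive distance in Angstrom",
          class = "rck_usage_error")
  }
  if (!all(c("L1", "L2") %in% names(metrics))) {
    abort("`metrics` must have columns L1 and L2", class = "rck_usage_error")
  }
  metrics %>%
    mutate(
      label = ifelse(pmax(.data$L1, .data$L2) - pmin(.data$L1, .data$L2) <=
                       threshold, "square", "non-square"),
      threshold = threshold
    )
}

#' Cluster ring conformations in (L1, L2) space
#'
#' Agglomerative clustering on Euclidean distance in the (L1, L2) plane,
#' cut at `cutoff`. Complete linkage with the default 3.8 Å cut groups the
#' published non-square KtrA rings into their four conformational groups.
#' Items are processed in lexicographic name order so labelling is
#' deterministic; group numbers follow first appearance in the input.
#'
#' @param items Data frame with columns `name`, `L1`, `L2`.
#' @param linkage Agglomeration method (only `"complete"` is offered).
#' @param cutoff Å; tree cut height.
#' @return `items` with an integer `group` column; attributes `linkage` and
#'   `cutoff` record the settings.
#' @export
cluster_conformations <- function(items, linkage = "complete", cutoff = 3.8) {
  linkage <- match.arg(linkage, "complete")
  if (!is.data.frame(items) || nrow(items) == 0L) {
    abort("`items` must be a data frame with at least one row",
          class = "rck_usage_error")
  }
  if (!all(c("name", "L1", "L2") %in% names(items))) {
    abort("`items` must have columns name, L1, L2", class = "rck_usage_error")
  }
  ord <- radix_order(items$name)
  sorted <- items[ord, ]
  lab <- if (nrow(sorted) == 1L) {
    1L
  } else {
    hc <- hclust(dist(as.matrix(sorted[, c("L1", "L2")])), method = linkage)
    cutree(hc, h = cutoff)
  }
  sorted$group <- lab
  out <- sorted[order(ord), ]              # restore input order
  out$group <- as.integer(factor(out$group, levels = unique(out$group)))
  out <- as_tibble(out)
  attr(out, "linkage") <- linkage
  attr(out, "cutoff") <- cutoff
  out
}

# Kabsch: optimal proper rotation R with A %*% R ~ B (A, B centred)
kabsch_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square deviation after optimal superposition
#'
#' Least-squares rigid superposition (Kabsch algorithm with the proper
#' rotation enforced) followed by the RMSD of paired points.
#'
#' @param coords_a,coords_b N x 3 matrices of paired positions (N >= 3,
#'   non-collinear).
#' @return RMSD in Å.
#' @export
superpose_rmsd <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L) {
    abort("coordinate sets must be N x 3 matrices of equal size",
          class = "rck_usage_error")
  }
  if (nrow(A) < 3L) {
    abort("at least 3 paired points are required", class = "rck_usage_error")
  }
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  if (svd(A)$d[2] < 1e-8 || svd(B)$d[2] < 1e-8) {
    abort("degenerate (collinear) geometry: superposition is ill-defined",
          class = "rck_numerical_error")
  }
  R <- kabsch_rotation(A, B)
  sqrt(mean(rowSums((A %*% R - B)^2)))
}

#' Whole-ring C-alpha RMSD between two rings
#'
#' Matches C-alpha atoms by (ring position, author residue number), drops
#' residues unmodelled in either ring pairwise, and reports the Kabsch RMSD
#' over the common set.
#'
#' @param ring_a,ring_b `rck_ring` objects.
#' @return One-row tibble: `rmsd` (Å) and `n_atoms` used.
#' @export
ring_ca_rmsd <- function(ring_a, ring_b) {
  stopifnot(inherits(ring_a, "rck_ring"), inherits(ring_b, "rck_ring"))
  ca_of <- function(ring, i) {
    ring$atoms %>%
      filter(.data$chain == ring$subunits[i], .data$elety == "CA",
             .data$type == "ATOM") %>%
      distinct(.data$resno, .keep_all = TRUE)
  }
  A <- list(); B <- list()
  for (i in 1:8) {
    ca_a <- ca_of(ring_a, i); ca_b <- ca_of(ring_b, i)
    common <- intersect(ca_a$resno, ca_b$resno)
    ca_a <- ca_a %>% filter(.data$resno %in% common) %>% arrange(.data$resno)
    ca_b <- ca_b %>% filter(.data$resno %in% common) %>% arrange(.data$resno)
    A[[i]] <- as.matrix(ca_a[, c("x", "y", "z")])
    B[[i]] <- as.matrix(ca_b[, c("x", "y", "z")])
  }
  A <- do.call(rbind, A); B <- do.call(rbind, B)
  tibble(rmsd = superpose_rmsd(A, B), n_atoms = nrow(A))
}

#' Intra-dimer hinge angle (documented convention)
#'
#' The hinge between the two subunits of an RCK dimer has no closed-form
#' definition in the field; this function reports a *convention-dependent*
#' angle: the angle at the dimer-interface centroid (midpoint of the two
#' intra-dimer marker C-alpha atoms, residue `marker_residue`) subtended by
#' the two subunits' C-alpha centroids. Values are in \[0, 180\] degrees and
#' should only be compared between rings measured with this same convention.
#'
#' @param ring An `rck_ring`.
#' @param dimer Integer pair: ring positions of the two subunits (default
#'   the first dimer).
#' @param marker_residue Marker residue defining the interface (default 36).
#' @return Angle in degrees.
#' @export
hinge_angle <- function(ring, dimer = c(1L, 2L), marker_residue = 36) {
  stopifnot(inherits(ring, "rck_ring"), length(dimer) == 2L)
  m <- marker_coords(ring, marker_residue, "CA")
  vertex <- (m[dimer[1], ] + m[dimer[2], ]) / 2
  cent <- function(i) {
    ca <- ring$atoms %>%
      filter(.data$chain == ring$subunits[i], .data$elety == "CA",
             .data$type == "ATOM")
    if (nrow(ca) == 0L) {
      abort(sprintf("no C-alpha atoms in subunit %s", ring$subunits[i]),
            class = "rck_marker_error")
    }
    c(mean(ca$x), mean(ca$y), mean(ca$z))
  }
  v1 <- cent(dimer[1]) - vertex
  v2 <- cent(dimer[2]) - vertex
  cosang <- sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' One-row conformational report for a ring
#'
#' Convenience wrapper combining [compute_l1_l2()],
#' [intra_dimer_distances()] and [classify_conformation()].
#'
#' @inheritParams compute_l1_l2
#' @param dimer_residue Intra-dimer marker residue (default 36).
#' @param threshold Square-call threshold in Å (default 2.0).
#' @param id Optional ring identifier for the `name` column.
#' @return One-row tibble with `name`, `L1`, `L2`, `asymmetry`, `label`,
#'   `threshold`, and list-columns `diagonals` and `intra_dimer`.
#' @export
ring_metrics <- function(ring, marker_residue = 38, dimer_residue = 36,
                         threshold = 2.0, id = "ring") {
  m <- compute_l1_l2(ring, marker_residue) %>%
    classify_conformation(threshold = threshold)
  m$intra_dimer <- list(intra_dimer_distances(ring, dimer_residue))
  m$name <- id
  m %>% select("name", "L1", "L2", "asymmetry", "label", "threshold",
               "diagonals", "intra_dimer")
}
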
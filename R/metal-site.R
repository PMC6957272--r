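#' Reference coordination profiles for candidate ions
#'
#' Literature-standard expectations used by [score_identity()]: ideal
#' metal–oxygen donor distances, preferred coordination numbers and preferred
#' coordination polyhedra. Mg2+ is a strict octahedral CN-6 ion at ~2.07 Å;
#' Ca2+ accepts 6–8 donors at ~2.39 Å, often pentagonal-bipyramidal at CN 7.
#' Edit the returned tibble (or supply your own) to change the standards —
#' they are data, not code.
#'
#' @return Tibble with columns `element`, `ideal_distance` (Å),
#'   `preferred_cn` (list of integer vectors) and `preferred_geometry`
#'   (list of character vectors).
#' @export
ion_profiles <- function() {
  tibble(
    element = c("MG", "CA"),
    ideal_distance = c(2.07, 2.39),
    preferred_cn = list(6L, c(6L, 7L, 8L)),
    preferred_geometry = list("octahedral",
                              c("octahedral", "pentagonal-bipyramidal"))
  )
}

# ideal unit-vertex sets for the supported coordination polyhedra
polyhedron_vertices <- function(name) {
  switch(name,
    "tetrahedral" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                          c(-1, -1, 1)) / sqrt(3),
    "square-planar" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)),
    "trigonal-bipyramidal" = rbind(
      t(vapply(0:2, function(k) c(cos(2 * pi * k / 3),
                                  sin(2 * pi * k / 3), 0), numeric(3))),
      c(0, 0, 1), c(0, 0, -1)),
    "octahedral" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                         c(0, 0, 1), c(0, 0, -1)),
    "pentagonal-bipyramidal" = rbind(
      t(vapply(0:4, function(k) c(cos(2 * pi * k / 5),
                                  sin(2 * pi * k / 5), 0), numeric(3))),
      c(0, 0, 1), c(0, 0, -1)),
    abort(paste0("unknown polyhedron: ", name), class = "rck_usage_error")
  )
}

supported_polyhedra <- function() {
  c("tetrahedral", "square-planar", "trigonal-bipyramidal", "octahedral",
    "pentagonal-bipyramidal")
}

#' Resolve a "chain:resno:atom" selector against an atom table
#'
#' @param atoms Atom tibble.
#' @param selector String `"chain:resno:atom_name"` (e.g. `"A:125:OE1"`).
#' @return The matching atom rows (possibly zero rows).
#' @export
resolve_selector <- function(atoms, selector) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    abort(paste0("selector must look like 'chain:resno:atom', got '",
                 selector, "'"), class = "rck_usage_error")
  }
  atoms %>%
    filter(.data$chain == parts[1], .data$resno == as.integer(parts[2]),
           .data$elety == parts[3])
}

#' Find the coordination shell around a metal centre
#'
#' Collects all atoms of the donor elements within `cutoff` of the centre,
#' excluding atoms belonging to the centre's own residue record and anything
#' closer than 0.8 Å (a clash guard). An empty shell is a valid result with
#' coordination number 0, not an error.
#'
#' @param atoms Atom tibble.
#' @param center Either a numeric xyz position, a `"chain:resno:atom"`
#'   selector, or an element symbol (e.g. `"MG"`) naming a unique HETATM.
#' @param cutoff Detection radius in Å (default 3.0).
#' @param donor_elements Elements accepted as donors (default O and N).
#' @return Object of class `rck_shell`: list with `center` (xyz),
#'   `center_b` (B-factor or NA), `donors` (tibble sorted by distance,
#'   with columns `chain`, `resno`, `resid`, `elety`, `elesy`, `dist`, `b`)
#'   and `cn`.
#' @export
find_shell <- function(atoms, center, cutoff = 3.0,
                       donor_elements = c("O", "N")) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    abort("`cutoff` must be positive", class = "rck_usage_error")
  }
  center_row <- NULL
  if (is.numeric(center) && length(center) == 3L) {
    pos <- as.numeric(center)
    center_b <- NA_real_
  } else if (is.character(center) && length(center) == 1L) {
    center_row <- if (grepl(":", center, fixed = TRUE)) {
      resolve_selector(atoms, center)
    } else {
      atoms %>% filter(.data$type == "HETATM",
                       toupper(.data$elesy) == toupper(center))
    }
    if (nrow(center_row) == 0L) {
      abort(paste0("centre selector '", center, "' matches no atom"),
            class = "rck_usage_error")
    }
    if (nrow(center_row) > 1L) {
      abort(paste0("centre selector '", center, "' is ambiguous (",
                   nrow(center_row), " atoms); use 'chain:resno:atom'"),
            class = "rck_usage_error")
    }
    pos <- as.numeric(center_row[1L, c("x", "y", "z")])
    center_b <- center_row$b[1L]
  } else {
    abort("`center` must be an xyz vector, a selector, or an element symbol",
          class = "rck_usage_error")
  }
  cand <- atoms %>%
    filter(toupper(.data$elesy) %in% toupper(donor_elements)) %>%
    mutate(dist = sqrt((.data$x - pos[1])^2 + (.data$y - pos[2])^2 +
                         (.data$z - pos[3])^2)) %>%
    filter(.data$dist > 0.8, .data$dist <= cutoff)
  if (!is.null(center_row)) {
    cand <- cand %>%
      filter(!(.data$chain == center_row$chain[1L] &
                 .data$resno == center_row$resno[1L] &
                 .data$resid == center_row$resid[1L]))
  }
  cand <- cand %>% arrange(.data$dist, .data$eleno)
  structure(
    list(center = pos, center_b = center_b,
         donors = cand %>% select("chain", "resno", "resid", "elety",
                                  "elesy", "x", "y", "z", "dist", "b"),
         cn = nrow(cand), cutoff = cutoff),
    class = "rck_shell"
  )
}

#' @export
print.rck_shell <- function(x, ...) {
  cat("<rck_shell> CN =", x$cn, " cutoff =", x$cutoff, "A\n")
  if (x$cn > 0) print(x$donors %>% select("chain", "resno", "resid",
                                          "elety", "dist", "b"))
  invisible(x)
}

# deterministic match of observed unit vectors to an ideal vertex set:
# two-vector seeds over all ordered ideal pairs, greedy assignment, then
# alternating Kabsch refinement; returns angular RMSD (degrees)
match_polyhedron <- function(U, V) {
  n <- nrow(U)
  # pick the observed pair that is most orthogonal for stable seeding
  dots <- abs(U[1, ] %*% t(U))
  m <- which.min(dots)
  u_seed <- rbind(U[1, ], U[m, ], unit_vec(cross3(U[1, ], U[m, ])))
  angular_rmsd <- function(R, assign) {
    cosang <- pmin(1, pmax(-1, rowSums(U * (V[assign, , drop = FALSE] %*% t(R)))))
    sqrt(mean(acos(cosang)^2)) * 180 / pi
  }
  greedy_assign <- function(R) {
    cost <- -U %*% t(V %*% t(R))          # negative cosine similarity
    assign <- integer(n)
    free_r <- seq_len(n); free_c <- seq_len(n)
    for (step in seq_len(n)) {
      sub <- cost[free_r, free_c, drop = FALSE]
      k <- which.min(sub)
      i <- (k - 1L) %% length(free_r) + 1L
      j <- (k - 1L) %/% length(free_r) + 1L
      assign[free_r[i]] <- free_c[j]
      free_r <- free_r[-i]; free_c <- free_c[-j]
    }
    assign
  }
  best <- Inf
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k == j) next
      cr <- cross3(V[j, ], V[k, ])
      if (vec_norm(cr) < 1e-6) next       # collinear seed pair
      v_seed <- rbind(V[j, ], V[k, ], unit_vec(cr))
      R <- kabsch_rotation(v_seed, u_seed) # maps ideal -> observed frame
      R <- t(R)                            # apply as V %*% t(R)
      for (iter in 1:3) {
        assign <- greedy_assign(R)
        R <- t(kabsch_rotation(V[assign, , drop = FALSE], U))
      }
      r <- angular_rmsd(R, assign)
      if (r < best) best <- r
    }
  }
  best
}

#' Assess the coordination geometry of a shell
#'
#' Matches the unit vectors centre-to-donor against each supported ideal
#' polyhedron with the same vertex count, using an optimal rotation and
#' vertex assignment; the residual angular RMSD decides the best label. A
#' residual above `irregular_cutoff` (default 20°) or a coordination number
#' below 3 yields `"irregular"`.
#'
#' @param shell An `rck_shell`.
#' @param irregular_cutoff Degrees; residual above which the shell is called
#'   irregular.
#' @return One-row tibble: `best_polyhedron`, `angular_rmsd` (degrees, NA
#'   when undefined) and `cn`. The per-candidate residuals are attached as
#'   attribute `"candidates"`.
#' @export
assess_geometry <- function(shell, irregular_cutoff = 20) {
  stopifnot(inherits(shell, "rck_shell"))
  if (shell$cn < 3L) {
    return(tibble(best_polyhedron = "irregular", angular_rmsd = NA_real_,
                  cn = shell$cn))
  }
  cands <- supported_polyhedra()
  cands <- cands[vapply(cands, function(p) nrow(polyhedron_vertices(p)),
                        1L) == shell$cn]
  if (length(cands) == 0L) {
    return(tibble(best_polyhedron = "irregular", angular_rmsd = NA_real_,
                  cn = shell$cn))
  }
  U <- as.matrix(shell$donors[, c("x", "y", "z")])
  U <- sweep(U, 2, shell$center)
  U <- U / sqrt(rowSums(U^2))
  res <- vapply(cands, function(p) match_polyhedron(U, polyhedron_vertices(p)),
                numeric(1))
  best <- cands[which.min(res)]
  out <- tibble(
    best_polyhedron = if (min(res) > irregular_cutoff) "irregular" else best,
    angular_rmsd = min(res),
    cn = shell$cn
  )
  attr(out, "candidates") <- tibble(polyhedron = cands, angular_rmsd = unname(res))
  out
}

#' Score candidate ion identities for a coordination shell
#'
#' Ranks candidate ions by a declared, configurable penalty: the deviation
#' of the mean donor distance from the ion's ideal distance (per Å), the
#' distance of the coordination number from the ion's preferred set (per
#' unit) and a flat penalty when the observed polyhedron is not among the
#' ion's preferred geometries. Lower totals rank first. When B-factors are
#' present, the centre-to-donor B-factor ratio is reported and a
#' `lighter_ion_suspected` flag raised above `b_ratio_flag` — a metal
#' modelled too heavy for its density refines with an inflated B relative
#' to its shell.
#'
#' @param shell An `rck_shell` with `cn >= 1`.
#' @param profiles Ion profile tibble (default [ion_profiles()]).
#' @param weights Named numeric: `distance` (per Å), `cn` (per unit),
#'   `geometry` (flat).
#' @param b_ratio_flag Ratio above which the lighter-ion flag is set
#'   (default 1.2).
#' @return Tibble, one row per candidate ion sorted by `total` ascending,
#'   with columns `element`, `distance_term`, `cn_term`, `geometry_term`,
#'   `total`, `rank`. Attributes: `b_ratio`, `lighter_ion_suspected`,
#'   `geometry` (the [assess_geometry()] row) and `weights`.
#' @export
score_identity <- function(shell, profiles = ion_profiles(),
                           weights = c(distance = 1, cn = 0.5, geometry = 0.5),
                           b_ratio_flag = 1.2) {
  stopifnot(inherits(shell, "rck_shell"))
  if (shell$cn < 1L) {
    abort("cannot score an empty shell (CN 0)", class = "rck_usage_error")
  }
  need <- c("element", "ideal_distance", "preferred_cn", "preferred_geometry")
  if (!all(need %in% names(profiles))) {
    abort(paste0("ion profiles must have columns: ",
                 paste(need, collapse = ", ")), class = "rck_config_error")
  }
  if (!all(c("distance", "cn", "geometry") %in% names(weights))) {
    abort("`weights` needs named entries distance, cn, geometry",
          class = "rck_config_error")
  }
  geo <- assess_geometry(shell)
  mean_dist <- mean(shell$donors$dist)
  scores <- purrr::pmap_dfr(profiles, function(element, ideal_distance,
                                               preferred_cn,
                                               preferred_geometry, ...) {
    dist_term <- abs(mean_dist - ideal_distance) * weights[["distance"]]
    cn_term <- if (shell$cn %in% preferred_cn) 0 else
      min(abs(shell$cn - preferred_cn)) * weights[["cn"]]
    geom_term <- if (geo$best_polyhedron %in% preferred_geometry) 0 else
      weights[["geometry"]]
    tibble(element = element, distance_term = dist_term, cn_term = cn_term,
           geometry_term = geom_term,
           total = dist_term + cn_term + geom_term)
  })
  scores <- scores %>%
    arrange(.data$total, .data$element) %>%
    mutate(rank = row_number())
  b_ratio <- if (is.finite(shell$center_b) && all(is.finite(shell$donors$b))) {
    shell$center_b / mean(shell$donors$b)
  } else {
    NA_real_
  }
  attr(scores, "b_ratio") <- b_ratio
  attr(scores, "lighter_ion_suspected") <-
    is.finite(b_ratio) && b_ratio > b_ratio_flag
  attr(scores, "geometry") <- geo
  attr(scores, "weights") <- weights
  scores
}

#' Locate a candidate interface cation site from donor selectors
#'
#' A screening aid for the intra-dimer interface site that sits between the
#' gamma-phosphates of the two bound nucleotides and the carboxylates of the
#' two interface glutamates: the candidate centre is the centroid of the
#' resolvable donor oxygens, and the distances from that centre to each donor
#' are reported. Unresolvable selectors (e.g. a mutated-away glutamate) are
#' recorded in `missing`, never silently dropped.
#'
#' @param atoms Atom tibble.
#' @param selectors Character vector of `"chain:resno:atom"` donor selectors.
#' @return Object of class `rck_site`: list with `center` (xyz), `donors`
#'   (tibble of `selector`, `dist`), and `missing` (character).
#' @export
locate_interface_site <- function(atoms, selectors) {
  if (length(selectors) == 0L) {
    abort("at least one donor selector is required", class = "rck_usage_error")
  }
  rows <- lapply(selectors, function(s) resolve_selector(atoms, s))
  found <- vapply(rows, nrow, 1L) > 0L
  if (!any(found)) {
    abort("none of the donor selectors resolve to an atom",
          class = "rck_usage_error")
  }
  xyz <- do.call(rbind, lapply(rows[found], function(r)
    as.numeric(r[1L, c("x", "y", "z")])))
  center <- colMeans(xyz)
  donors <- tibble(
    selector = selectors[found],
    dist = sqrt(rowSums(sweep(xyz, 2, center)^2))
  )
  structure(list(center = center, donors = donors,
                 missing = selectors[!found]),
            class = "rck_site")
}

#' @export
print.rck_site <- function(x, ...) {
  cat("<rck_site> centre:", paste(sprintf("%.2f", x$center), collapse = " "), "\n")
  print(x$donors)
  if (length(x$missing) > 0L) {
    cat("missing donors:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}
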
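#' Generate a synthetic octameric ring with prescribed diagonals
#'
#' Builds an 8-subunit ring of small rigid C-alpha stubs (residues 34–38
#' per subunit — the minimum needed by the ring metrics) whose marker
#' residue-38 atoms realise the requested cross-ring diagonals exactly at
#' zero noise: subunits sit at 45-degree steps about the z axis, with the
#' two-fold-related diagonal pairs at radius L1/2 and L2/2. Optional
#' per-dimer residue-36 separations are honoured by placing those markers
#' symmetrically about each dimer midpoint. Gaussian positional noise of
#' `noise_sigma` Å is applied per atom when requested.
#'
#' @param L1,L2 Target diagonal means in Å (`L1 >= L2 > 0`).
#' @param dimer_d36 Optional numeric(4): intra-dimer residue-36 C-alpha
#'   distances for dimers (1,2), (3,4), (5,6), (7,8) in ring order.
#' @param noise_sigma Positional noise SD in Å (default 0).
#' @param seed Integer seed; the generator is deterministic given its
#'   arguments.
#' @return Atom tibble (chains A–H) consumable by [build_ring()] and
#'   writable with [write_structure_pdb()].
#' @export
simulate_ring <- function(L1 = 30, L2 = 30, dimer_d36 = NULL,
                          noise_sigma = 0, seed = 1L) {
  if (!is.numeric(L1) || !is.numeric(L2) || L2 <= 0 || L1 < L2) {
    abort("need L1 >= L2 > 0 (swap the arguments?)", class = "rck_usage_error")
  }
  if (!is.null(dimer_d36) && length(dimer_d36) != 4L) {
    abort("`dimer_d36` must have 4 entries (one per dimer)",
          class = "rck_usage_error")
  }
  radii <- rep(c(L1, L2) / 2, 4)              # diagonal pairs {1,3} and {2,4}
  theta <- (0:7) * pi / 4
  marker38 <- cbind(radii * cos(theta), radii * sin(theta), 0)
  chains <- LETTERS[1:8]
  # residue-36 markers: default a fixed local offset; per-dimer spacing when given
  marker36 <- marker38 + cbind(-2 * cos(theta), -2 * sin(theta), 3)
  if (!is.null(dimer_d36)) {
    for (k in 0:3) {
      i <- 2L * k + 1L; j <- i + 1L
      midpoint <- (marker38[i, ] + marker38[j, ]) / 2 + c(0, 0, 3)
      u <- unit_vec(marker38[j, ] - marker38[i, ])
      marker36[i, ] <- midpoint - u * dimer_d36[k + 1L] / 2
      marker36[j, ] <- midpoint + u * dimer_d36[k + 1L] / 2
    }
  }
  rows <- list()
  for (s in 1:8) {
    # rigid 5-residue stub; residues 34, 35, 37 complete the scaffold
    stub <- rbind(
      marker36[s, ] + c(0, 0, 2.5),           # 34
      marker36[s, ] + c(0, 0, 1.2),           # 35
      marker36[s, ],                          # 36
      (marker36[s, ] + marker38[s, ]) / 2,    # 37
      marker38[s, ]                           # 38
    )
    rows[[s]] <- tibble(
      type = "ATOM", elety = "CA", alt = "",
      resid = c("ALA", "ALA", "ASP", "ALA", "ASN"),
      chain = chains[s], resno = 34:38, insert = "",
      x = stub[, 1], y = stub[, 2], z = stub[, 3],
      o = 1, b = 30, elesy = "C"
    )
  }
  atoms <- bind_rows(rows)
  if (noise_sigma > 0) {
    atoms <- withr::with_seed(seed, {
      atoms %>% mutate(
        x = .data$x + rnorm(n(), 0, noise_sigma),
        y = .data$y + rnorm(n(), 0, noise_sigma),
        z = .data$z + rnorm(n(), 0, noise_sigma)
      )
    })
  }
  atoms$eleno <- seq_len(nrow(atoms))
  attr(atoms, "structure_id") <- sprintf("synthetic_ring_L1_%g_L2_%g", L1, L2)
  atoms
}

#' Generate a synthetic metal site with a prescribed coordination shell
#'
#' Places a metal atom at the origin and donor oxygens (as single-atom
#' water-like residues) at the vertices of an ideal coordination polyhedron
#' scaled to `distance`, optionally jittered in distance (Å) and direction
#' (degrees). B-factors of the centre and donors are set as requested, so
#' centre-to-shell B-factor ratios can be emulated.
#'
#' @param ion Element symbol for the centre (e.g. `"MG"`, `"CA"`).
#' @param cn Coordination number; must match the polyhedron vertex count.
#' @param distance Centre–donor distance in Å.
#' @param geometry Polyhedron label (see [assess_geometry()]).
#' @param jitter_dist SD of Gaussian distance jitter (Å).
#' @param jitter_ang SD of Gaussian angular jitter (degrees).
#' @param b_center,b_donors B-factors (Å²).
#' @param seed Integer seed.
#' @return Atom tibble (metal chain M, donors chain W).
#' @export
simulate_metal_site <- function(ion = "MG", cn = 6L, distance = 2.07,
                                geometry = "octahedral", jitter_dist = 0,
                                jitter_ang = 0, b_center = 30, b_donors = 30,
                                seed = 1L) {
  V <- polyhedron_vertices(geometry)
  if (nrow(V) != cn) {
    abort(sprintf("geometry '%s' has %d vertices but cn = %d was requested",
                  geometry, nrow(V), cn), class = "rck_usage_error")
  }
  pos <- withr::with_seed(seed, {
    t(vapply(seq_len(cn), function(i) {
      v <- V[i, ]
      if (jitter_ang > 0) {
        ang <- rnorm(1, 0, jitter_ang) * pi / 180
        perp <- cross3(v, rnorm(3))
        if (vec_norm(perp) < 1e-9) perp <- cross3(v, c(1, 0, 0))
        perp <- unit_vec(perp)
        v <- v * cos(ang) + cross3(perp, v) * sin(ang)
        v <- unit_vec(v)
      }
      d <- distance + if (jitter_dist > 0) rnorm(1, 0, jitter_dist) else 0
      v * max(d, 0.9)
    }, numeric(3)))
  })
  metal <- tibble(
    type = "HETATM", elety = toupper(ion), alt = "", resid = toupper(ion),
    chain = "M", resno = 1L, insert = "",
    x = 0, y = 0, z = 0, o = 1, b = b_center, elesy = toupper(ion)
  )
  donors <- tibble(
    type = "HETATM", elety = "O", alt = "", resid = "HOH",
    chain = "W", resno = 100L + seq_len(cn), insert = "",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    o = 1, b = b_donors, elesy = "O"
  )
  atoms <- bind_rows(metal, donors)
  atoms$eleno <- seq_len(nrow(atoms))
  attr(atoms, "structure_id") <- sprintf("synthetic_%s_site", tolower(ion))
  atoms
}

#' Generate a synthetic protein alignment with prescribed column composition
#'
#' Draws each row's residue per column from categorical distributions given
#' in `column_spec` (unspecified columns are uniform over the 20 amino
#' acids). In exact-counts mode the per-column residue counts are fixed to
#' the largest-remainder apportionment of `freq * n_rows`, so printed-count
#' compositions (e.g. 13 glutamates of 15 rows) are reproduced
#' deterministically. Optionally embeds the nucleotide-binding motif
#' (GxGxxG + 17-residue spacer + E) at a declared start in every row.
#'
#' @param n_rows,length Alignment dimensions.
#' @param column_spec Named list: column index -> named residue-frequency
#'   vector summing to 1.
#' @param exact_counts Use deterministic largest-remainder counts per
#'   specified column instead of random draws.
#' @param embed_nbs_motif Embed the motif in every row?
#' @param motif_start 1-based column where the motif starts.
#' @param seed Integer seed.
#' @return Alignment tibble (`id`, `sequence`).
#' @export
simulate_alignment <- function(n_rows = 15L, length = 60L,
                               column_spec = list(), exact_counts = FALSE,
                               embed_nbs_motif = FALSE, motif_start = 1L,
                               seed = 1L) {
  aa20 <- setdiff(AA_ALPHABET, "X")
  for (spec in column_spec) {
    if (abs(sum(spec) - 1) > 1e-6) {
      abort("column_spec frequencies must sum to 1", class = "rck_usage_error")
    }
  }
  mat <- withr::with_seed(seed, {
    m <- matrix(sample(aa20, n_rows * length, replace = TRUE),
                nrow = n_rows, ncol = length)
    for (col_name in names(column_spec)) {
      cidx <- as.integer(col_name)
      if (is.na(cidx) || cidx < 1L || cidx > length) {
        abort(paste0("column_spec index out of range: ", col_name),
              class = "rck_usage_error")
      }
      spec <- column_spec[[col_name]]
      if (exact_counts) {
        raw <- spec * n_rows
        cnt <- floor(raw)
        rem <- n_rows - sum(cnt)
        if (rem > 0) {
          extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
          cnt[extra] <- cnt[extra] + 1
        }
        m[, cidx] <- sample(rep(names(spec), times = cnt))
      } else {
        m[, cidx] <- sample(names(spec), n_rows, replace = TRUE, prob = spec)
      }
    }
    if (embed_nbs_motif) {
      motif_len <- 6L + 17L + 1L
      if (motif_start < 1L || motif_start + motif_len - 1L > length) {
        abort("motif does not fit at `motif_start`", class = "rck_usage_error")
      }
      fixed <- c(1L, 3L, 6L, motif_len)             # G . G . . G [spacer] E
      m[, motif_start + fixed[1:3] - 1L] <- "G"
      m[, motif_start + motif_len - 1L] <- "E"
    }
    m
  })
  tibble(
    id = sprintf("seq%02d", seq_len(n_rows)),
    sequence = apply(mat, 1, paste, collapse = "")
  )
}

#' Generate a synthetic ACMA flux-assay trace
#'
#' Emulates the assay timeline: flat baseline at normalized fluorescence 1
#' until CCCP addition at `cccp_time`, then a one- or two-phase exponential
#' quench toward `floor` over the decay window, optionally followed by a
#' valinomycin tail decaying quickly to 0. The normalized signal is mapped
#' to raw arbitrary units by the affine transform `a * NF + b`, and additive
#' Gaussian noise of SD `noise_sigma` (NF units) is applied.
#'
#' @param k_fast Fast (or single) rate constant, s^-1.
#' @param k_slow Optional slow rate constant for a two-phase quench.
#' @param amp_fast Fraction of the decaying amplitude in the fast phase.
#' @param floor Normalized steady-state level the quench decays to.
#' @param noise_sigma Additive Gaussian noise SD in NF units.
#' @param cccp_time Baseline duration in s (default 100).
#' @param decay_duration Post-CCCP observation window in s (default 400).
#' @param valinomycin Append a 100-s valinomycin tail to NF 0?
#' @param dt Sampling interval in s (default 2).
#' @param raw_scale Length-2 `c(a, b)` affine map from NF to raw AU.
#' @param seed Integer seed.
#' @return Flux-trace tibble (see [as_flux_trace()]) with the generating
#'   parameters attached as attribute `"truth"`.
#' @export
simulate_flux_trace <- function(k_fast = 0.096, k_slow = NULL, amp_fast = 1,
                                floor = 0.2, noise_sigma = 0,
                                cccp_time = 100, decay_duration = 400,
                                valinomycin = FALSE, dt = 2,
                                raw_scale = c(1000, 200), seed = 1L) {
  if (k_fast <= 0 || (!is.null(k_slow) && k_slow <= 0)) {
    abort("rate constants must be positive", class = "rck_usage_error")
  }
  if (amp_fast < 0 || amp_fast > 1) {
    abort("`amp_fast` must lie in [0, 1]", class = "rck_usage_error")
  }
  if (dt <= 0 || decay_duration < 10 * dt) {
    abort("invalid schedule: need decay_duration >= 10 * dt",
          class = "rck_usage_error")
  }
  val_time <- if (valinomycin) cccp_time + decay_duration else NULL
  t_end <- cccp_time + decay_duration + if (valinomycin) 100 else 0
  time <- seq(0, t_end, by = dt)
  amp <- 1 - floor
  nf <- ifelse(
    time <= cccp_time, 1,
    floor + amp * (amp_fast * exp(-k_fast * (time - cccp_time)) +
                     (1 - amp_fast) *
                     exp(-(if (is.null(k_slow)) k_fast else k_slow) *
                           (time - cccp_time)))
  )
  if (valinomycin) {
    tail_idx <- time > val_time
    nf_at_val <- nf[which(time <= val_time)[sum(time <= val_time)]]
    nf[tail_idx] <- nf_at_val * exp(-0.5 * (time[tail_idx] - val_time))
  }
  nf_noisy <- if (noise_sigma > 0) {
    withr::with_seed(seed, nf + rnorm(length(nf), 0, noise_sigma))
  } else {
    nf
  }
  trace <- tibble(time = time,
                  fluorescence = raw_scale[1] * nf_noisy + raw_scale[2])
  trace <- as_flux_trace(trace, cccp_time = cccp_time,
                         valinomycin_time = val_time)
  attr(trace, "truth") <- list(k_fast = k_fast, k_slow = k_slow,
                               amp_fast = amp_fast, floor = floor,
                               noise_sigma = noise_sigma,
                               raw_scale = raw_scale)
  trace
}

#' Generate a synthetic Hill titration table
#'
#' Rates follow the Hill equation at each concentration of the grid, with
#' multiplicative Gaussian noise per replicate — emulating flux-rate
#' titrations read out as mean ± SD over separate titration series.
#'
#' @param k_half Half-activation concentration (in `unit`).
#' @param n_hill Hill coefficient.
#' @param start,end Rates (s^-1) at zero and saturating concentration.
#' @param conc Concentration grid (same `unit`); defaults to a 0–2000
#'   grid mirroring a micromolar divalent-cation titration.
#' @param unit Concentration unit tag carried with the data (e.g. `"uM"`,
#'   `"mM"`).
#' @param noise_sigma Multiplicative rate noise SD (default 0.05 = 5%).
#' @param n_replicates Number of replicate series (default 3).
#' @param seed Integer seed.
#' @return Tibble with columns `replicate`, `conc`, `unit`, `rate`; true
#'   parameters attached as attribute `"truth"`.
#' @export
simulate_titration <- function(k_half = 155, n_hill = 1.8, start = 0.01,
                               end = 0.10,
                               conc = c(0, 25, 50, 100, 200, 400, 800,
                                        1500, 2000),
                               unit = "uM", noise_sigma = 0.05,
                               n_replicates = 3L, seed = 1L) {
  if (length(conc) == 0L || any(conc < 0)) {
    abort("`conc` must be a nonempty nonnegative grid", class = "rck_usage_error")
  }
  true_rate <- start + (end - start) * conc^n_hill / (k_half^n_hill + conc^n_hill)
  out <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble(replicate = r, conc = conc, unit = unit,
             rate = true_rate * (1 + if (noise_sigma > 0)
               rnorm(length(conc), 0, noise_sigma) else 0))
    })
  })
  attr(out, "truth") <- list(k_half = k_half, n_hill = n_hill,
                             start = start, end = end,
                             noise_sigma = noise_sigma)
  out
}
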
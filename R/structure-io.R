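#' Read a macromolecular coordinate file into an atom table
#'
#' Parses a PDB or mmCIF file (via bio3d) and returns one row per atom, with
#' author residue numbering retained. Alternate-location conformers are
#' collapsed to the highest-occupancy record (ties resolved in favour of
#' altloc "A"). Any biological-assembly operators found in the file
#' (`REMARK 350` BIOMT records or the `_pdbx_struct_oper_list` category) are
#' attached as the `"operators"` attribute for use by [apply_assembly()].
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (guess from the extension), `"pdb"` or `"cif"`.
#' @return A tibble with columns `type` (ATOM/HETATM), `eleno`, `elety`
#'   (atom name), `alt`, `resid` (3-letter residue code), `chain`, `resno`
#'   (author numbering), `insert`, `x`, `y`, `z` (Å), `o` (occupancy),
#'   `b` (isotropic B-factor, Å²) and `elesy` (element symbol).
#' @seealso [apply_assembly()], [build_ring()], [write_structure_pdb()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!is.character(path) || length(path) != 1L) {
    abort("`path` must be a single file path", class = "rck_usage_error")
  }
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "rck_usage_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.insert = FALSE, rm.alt = FALSE,
                      verbose = FALSE)
    } else {
      bio3d::read.cif(path, multi = FALSE, rm.insert = FALSE, rm.alt = FALSE,
                      verbose = FALSE)
    },
    error = function(e) {
      abort(paste0("failed to parse ", format, " file '", path, "': ",
                   conditionMessage(e)),
            class = "rck_parse_error")
    }
  )
  atoms <- as_tibble(parsed$atom)
  if (nrow(atoms) == 0L) {
    abort(paste0("no atom records found in '", path, "'"),
          class = "rck_parse_error")
  }
  atoms <- tidy_atom_table(atoms)
  attr(atoms, "structure_id") <- sub("\\.[^.]*(\\.gz)?$", "", basename(path))
  attr(atoms, "operators") <- read_assembly_operators(path, format)
  atoms
}

# normalise a bio3d atom data frame: column types, altloc collapse
tidy_atom_table <- function(atoms) {
  keep <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "b", "elesy")
  for (col in setdiff(keep, names(atoms))) atoms[[col]] <- NA
  atoms <- atoms[, keep]
  atoms <- atoms %>%
    mutate(
      across(all_of(c("x", "y", "z", "o", "b")), as.numeric),
      resno = as.integer(.data$resno),
      eleno = as.integer(.data$eleno),
      chain = ifelse(is.na(.data$chain), "", as.character(.data$chain)),
      insert = ifelse(is.na(.data$insert), "", as.character(.data$insert)),
      alt = ifelse(is.na(.data$alt), "", as.character(.data$alt))
    )
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    abort(paste0("non-finite coordinates at atom record(s): ",
                 paste(head(atoms$eleno[bad], 5L), collapse = ", ")),
          class = "rck_parse_error")
  }
  if (anyNA(atoms$elesy) || any(atoms$elesy == "")) {
    guess <- suppressWarnings(bio3d::atom2ele(atoms$elety))
    fix <- is.na(atoms$elesy) | atoms$elesy == ""
    atoms$elesy[fix] <- guess[fix]
  }
  atoms$o[!is.finite(atoms$o)] <- 1
  # altloc: keep the highest-occupancy conformer; tie -> 'A' (then smallest)
  atoms %>%
    mutate(.alt_rank = ifelse(.data$alt %in% c("", "A"), 0L, 1L)) %>%
    arrange(.data$chain, .data$resno, .data$insert, .data$elety,
            dplyr::desc(.data$o), .data$.alt_rank, .data$alt) %>%
    distinct(.data$chain, .data$resno, .data$insert, .data$resid,
             .data$elety, .keep_all = TRUE) %>%
    arrange(.data$eleno) %>%
    select(-".alt_rank")
}

#' Extract biological-assembly operators from a coordinate file
#'
#' Reads rigid-body operators from `REMARK 350` BIOMT records (PDB format) or
#' the `_pdbx_struct_oper_list` loop (mmCIF). Returns a list of operators,
#' each a `list(R = <3x3 rotation>, t = <length-3 translation>)`; the list is
#' empty when the file declares none.
#'
#' @inheritParams read_structure
#' @return List of `list(R, t)` operators (possibly empty).
#' @export
read_assembly_operators <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  if (format == "pdb") parse_biomt(lines) else parse_cif_oper(lines)
}

parse_biomt <- function(lines) {
  rows <- grep("^REMARK 350\\s+BIOMT[123]", lines, value = TRUE)
  if (length(rows) == 0L) return(list())
  fields <- lapply(strsplit(trimws(sub("^REMARK 350", "", rows)), "\\s+"), identity)
  ok <- vapply(fields, length, 1L) >= 6L
  fields <- fields[ok]
  if (length(fields) == 0L) return(list())
  tab <- data.frame(
    row = as.integer(sub("BIOMT", "", vapply(fields, `[[`, "", 1L))),
    op  = vapply(fields, `[[`, "", 2L),
    m1  = as.numeric(vapply(fields, `[[`, "", 3L)),
    m2  = as.numeric(vapply(fields, `[[`, "", 4L)),
    m3  = as.numeric(vapply(fields, `[[`, "", 5L)),
    t   = as.numeric(vapply(fields, `[[`, "", 6L))
  )
  ops <- list()
  for (id in unique(tab$op)) {
    sub <- tab[tab$op == id, ]
    if (nrow(sub) != 3L) next
    sub <- sub[order(sub$row), ]
    ops[[length(ops) + 1L]] <- list(
      R = rbind(c(sub$m1[1], sub$m2[1], sub$m3[1]),
                c(sub$m1[2], sub$m2[2], sub$m3[2]),
                c(sub$m1[3], sub$m2[3], sub$m3[3])),
      t = sub$t
    )
  }
  ops
}

parse_cif_oper <- function(lines) {
  tag_idx <- grep("^_pdbx_struct_oper_list\\.", lines)
  if (length(tag_idx) == 0L) return(list())
  tags <- sub("^_pdbx_struct_oper_list\\.", "", trimws(lines[tag_idx]))
  tags <- vapply(strsplit(tags, "\\s+"), `[[`, "", 1L)
  start <- max(tag_idx) + 1L
  vals <- character()
  i <- start
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_")) break
    vals <- c(vals, scan(text = ln, what = character(), quiet = TRUE))
    i <- i + 1L
  }
  if (length(tag_idx) == 1L) {
    # non-loop single operator: tag value pairs on the tag lines themselves
    kv <- lapply(lines[tag_idx], function(ln) scan(text = ln, what = character(), quiet = TRUE))
    vals <- vapply(kv, function(x) if (length(x) >= 2L) x[2L] else NA_character_, "")
  }
  if (length(vals) %% length(tags) != 0L) return(list())
  mat <- matrix(vals, ncol = length(tags), byrow = TRUE)
  colnames(mat) <- tags
  need <- c(outer(1:3, 1:3, function(i, j) sprintf("matrix[%d][%d]", i, j)),
            sprintf("vector[%d]", 1:3))
  if (!all(need %in% tags)) return(list())
  lapply(seq_len(nrow(mat)), function(r) {
    R <- matrix(as.numeric(mat[r, sprintf("matrix[%d][%d]",
                                          rep(1:3, each = 3), rep(1:3, 3))]),
                nrow = 3, byrow = TRUE)
    list(R = R, t = as.numeric(mat[r, sprintf("vector[%d]", 1:3)]))
  })
}

#' Expand a structure by rigid-body assembly operators
#'
#' Applies each operator to every chain of the input, producing one copy of
#' each chain per operator with fresh unique chain identifiers. Passing the
#' identity operator alone returns an equivalent model. Operators must be
#' proper rigid transforms (orthonormal rotation, determinant +1).
#'
#' @param atoms Atom tibble from [read_structure()] or a generator.
#' @param operators List of `list(R, t)` operators; defaults to the
#'   operators recorded on `atoms` by [read_structure()].
#' @return Atom tibble with `length(operators) * n_chains` chains.
#' @export
apply_assembly <- function(atoms, operators = NULL) {
  operators <- operators %||% attr(atoms, "operators")
  if (is.null(operators) || length(operators) == 0L) {
    abort("no assembly operators supplied or recorded on the structure",
          class = "rck_usage_error")
  }
  for (i in seq_along(operators)) {
    op <- operators[[i]]
    if (!is.list(op) || is.null(op$R) || is.null(op$t) ||
        !all(dim(op$R) == c(3L, 3L)) || length(op$t) != 3L) {
      abort(sprintf("operator %d is not a list(R = 3x3, t = length-3)", i),
            class = "rck_usage_error")
    }
    if (max(abs(crossprod(op$R) - diag(3))) > 1e-3) {
      abort(sprintf("operator %d rotation is not orthonormal within 1e-3", i),
            class = "rck_validation_error")
    }
    if (det(op$R) < 0) {
      abort(sprintf("operator %d is improper (determinant < 0)", i),
            class = "rck_validation_error")
    }
  }
  is_identity <- function(op) {
    max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t)) < 1e-9
  }
  if (length(operators) == 1L && is_identity(operators[[1L]])) {
    return(atoms)
  }
  chains <- unique(atoms$chain)
  pool <- c(LETTERS, letters, as.character(0:9))
  n_out <- length(operators) * length(chains)
  new_ids <- if (n_out <= length(pool)) pool[seq_len(n_out)] else
    paste0("C", seq_len(n_out))
  out <- vector("list", length(operators))
  k <- 0L
  for (i in seq_along(operators)) {
    op <- operators[[i]]
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    xyz <- xyz %*% t(op$R) + matrix(op$t, nrow(xyz), 3, byrow = TRUE)
    copy <- atoms
    copy$x <- xyz[, 1]; copy$y <- xyz[, 2]; copy$z <- xyz[, 3]
    map <- setNames(new_ids[k + seq_along(chains)], chains)
    copy$chain <- unname(map[copy$chain])
    k <- k + length(chains)
    out[[i]] <- copy
  }
  res <- bind_rows(out)
  res$eleno <- seq_len(nrow(res))
  attr(res, "structure_id") <- attr(atoms, "structure_id")
  attr(res, "operators") <- NULL
  res
}

#' Assemble an ordered octameric ring from an atom table
#'
#' Selects eight protein chains (explicitly, or all protein chains, or — when
#' the file holds more than one ring — by connected components of subunit
#' centroids closer than `split_cutoff`), computes the ring axis as the
#' principal axis of the eight subunit centroids, and orders the subunits
#' angularly about that axis starting at the subunit with the
#' lexicographically smallest chain identifier.
#'
#' @param atoms Atom tibble.
#' @param chains Optional character vector naming the 8 subunit chains.
#' @param split_cutoff Å; centroid-distance cutoff used to separate multiple
#'   rings sharing one asymmetric unit (default 60).
#' @return An object of class `rck_ring`: a list with elements `atoms`,
#'   `subunits` (ordered chain ids), `axis` (unit vector), `centroid` and
#'   `subunit_centroids` (8 x 3, ring order).
#' @export
build_ring <- function(atoms, chains = NULL, split_cutoff = 60) {
  protein <- atoms %>% filter(.data$type == "ATOM")
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(atoms$chain))
    if (length(missing) > 0L) {
      abort(paste0("chain(s) not present: ", paste(missing, collapse = ", ")),
            class = "rck_usage_error")
    }
    protein <- protein %>% filter(.data$chain %in% chains)
  }
  ids <- unique(protein$chain)
  cents <- chain_centroids(protein, ids)
  if (is.null(chains) && length(ids) > 8L) {
    comp <- centroid_components(cents, split_cutoff)
    sizes <- vapply(comp, length, 1L)
    if (sum(sizes == 8L) == 1L && all(sizes %in% c(0L, 8L))) {
      ids <- comp[[which(sizes == 8L)]]
    } else if (all(sizes == 8L)) {
      abort(paste0("multiple candidate rings found; pass `chains` to pick one: ",
                   paste(vapply(comp, paste, "", collapse = "+"), collapse = " | ")),
            class = "rck_ring_error")
    }
    protein <- protein %>% filter(.data$chain %in% ids)
    cents <- cents[ids, , drop = FALSE]
  }
  if (length(ids) != 8L) {
    abort(sprintf("expected 8 subunits, found %d", length(ids)),
          class = "rck_ring_error")
  }
  centroid <- colMeans(cents)
  centred <- sweep(cents, 2, centroid)
  ev <- eigen(crossprod(centred) / nrow(centred), symmetric = TRUE)
  axis <- ev$vectors[, 3L]                       # smallest variance = ring normal
  axis <- axis / vec_norm(axis)
  if (axis[which.max(abs(axis))] < 0) axis <- -axis
  ref <- ids[radix_order(ids)][1L]
  d_ref <- centred[ref, ] - sum(centred[ref, ] * axis) * axis
  e1 <- unit_vec(d_ref)
  e2 <- cross3(axis, e1)
  ang <- vapply(ids, function(id) {
    d <- centred[id, ] - sum(centred[id, ] * axis) * axis
    a <- atan2(sum(d * e2), sum(d * e1))
    if (a < -1e-9) a <- a + 2 * pi
    a
  }, numeric(1))
  ord <- ids[order(ang, ids, method = "radix")]
  keep_atoms <- atoms %>% filter(.data$chain %in% ids)
  structure(
    list(atoms = keep_atoms,
         subunits = ord,
         axis = axis,
         centroid = centroid,
         subunit_centroids = cents[ord, , drop = FALSE]),
    class = "rck_ring"
  )
}

chain_centroids <- function(protein, ids) {
  cents <- t(vapply(ids, function(id) {
    sub <- protein %>% filter(.data$chain == id)
    ca <- sub %>% filter(.data$elety == "CA")
    if (nrow(ca) > 0L) sub <- ca
    c(mean(sub$x), mean(sub$y), mean(sub$z))
  }, numeric(3)))
  rownames(cents) <- ids
  cents
}

centroid_components <- function(cents, cutoff) {
  n <- nrow(cents)
  adj <- as.matrix(dist(cents)) < cutoff
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i; members <- integer()
    while (length(queue) > 0L) {
      j <- queue[1L]; queue <- queue[-1L]
      if (seen[j]) next
      seen[j] <- TRUE
      members <- c(members, j)
      queue <- c(queue, which(adj[j, ] & !seen))
    }
    comps[[length(comps) + 1L]] <- rownames(cents)[sort(members)]
  }
  comps
}

#' @export
print.rck_ring <- function(x, ...) {
  cat("<rck_ring>", length(x$subunits), "subunits:",
      paste(x$subunits, collapse = " "), "\n")
  cat("  axis:", paste(sprintf("%.3f", x$axis), collapse = " "),
      " centroid:", paste(sprintf("%.1f", x$centroid), collapse = " "), "\n")
  invisible(x)
}

#' Marker-atom coordinates in ring order
#'
#' Returns the position of one named atom of one residue in each of the eight
#' subunits, in ring order. A missing marker in any subunit is an error that
#' names the offending subunits — unmodelled regions are never skipped
#' silently.
#'
#' @param ring An `rck_ring`.
#' @param residue_number Author residue number of the marker.
#' @param atom_name Atom name (default `"CA"`).
#' @return An 8 x 3 matrix of positions (Å), rownames = subunit chain ids.
#' @export
marker_coords <- function(ring, residue_number, atom_name = "CA") {
  stopifnot(inherits(ring, "rck_ring"))
  rows <- lapply(ring$subunits, function(id) {
    hit <- ring$atoms %>%
      filter(.data$chain == id, .data$resno == residue_number,
             .data$elety == atom_name)
    if (nrow(hit) == 0L) NULL else as.numeric(hit[1L, c("x", "y", "z")])
  })
  missing <- ring$subunits[vapply(rows, is.null, TRUE)]
  if (length(missing) > 0L) {
    abort(sprintf("marker residue %d (%s) missing in subunit(s): %s",
                  residue_number, atom_name, paste(missing, collapse = ", ")),
          class = "rck_marker_error")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- ring$subunits
  out
}

#' Write an atom table as a fixed-column PDB file
#'
#' Used to materialise synthetic fixtures; round-trips through
#' [read_structure()] to within the 1e-3 Å precision of the format.
#'
#' @param atoms Atom tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(atoms, path) {
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = atoms$type, resno = atoms$resno, resid = atoms$resid,
    eleno = atoms$eleno %||% seq_len(nrow(atoms)),
    elety = atoms$elety, chain = atoms$chain,
    o = atoms$o, b = atoms$b, elesy = atoms$elesy
  )
  invisible(path)
}

#' Download a deposited structure (helper for interactive/CLI use)
#'
#' Fetches a coordinate file from RCSB into `dest_dir`. The analysis
#' functions never download anything themselves; offline workflows should
#' point them at local files.
#'
#' @param id 4-character PDB accession.
#' @param dest_dir Directory to save into.
#' @param format `"pdb"` or `"cif"`.
#' @param assembly Optional assembly number; when given, the biological
#'   assembly file is fetched instead of the asymmetric unit.
#' @return Path to the downloaded file.
#' @export
fetch_structure <- function(id, dest_dir = ".", format = c("cif", "pdb"),
                            assembly = NULL) {
  format <- match.arg(format)
  id <- toupper(id)
  file <- if (is.null(assembly)) {
    paste0(id, ".", format)
  } else if (format == "cif") {
    paste0(id, "-assembly", assembly, ".cif")
  } else {
    paste0(id, ".pdb", assembly)
  }
  url <- paste0("https://files.rcsb.org/download/", file)
  dest <- file.path(dest_dir, file)
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest)) {
    abort(paste0("could not download ", url,
                 " (no network access, or entry unavailable)"),
          class = "rck_download_error")
  }
  dest
}
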
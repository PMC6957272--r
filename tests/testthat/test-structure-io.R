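test_that("PDB write/read round trip preserves atoms to format precision", {
  atoms <- simulate_ring(40.7, 30.7, dimer_d36 = c(8, 14, 8, 14))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(atoms, p)
  back <- read_structure(p)
  expect_equal(nrow(back), nrow(atoms))
  expect_equal(back$elety, atoms$elety)
  expect_equal(back$chain, atoms$chain)
  expect_equal(back$resno, atoms$resno)
  expect_lt(max(abs(back$x - atoms$x)), 1e-3)
  expect_lt(max(abs(back$y - atoms$y)), 1e-3)
  expect_lt(max(abs(back$z - atoms$z)), 1e-3)
})

test_that("unreadable or empty files give parse errors, bad paths usage errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(), empty)
  expect_error(read_structure(empty), class = "rck_parse_error")
  expect_error(read_structure("/no/such/file.pdb"), class = "rck_usage_error")
})

test_that("altloc conformers collapse to the highest-occupancy record", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA AALA A   2       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BALA A   2       6.000   0.000   0.000  0.50 10.00           C",
    "END"), p)
  atoms <- read_structure(p)
  expect_equal(nrow(atoms), 2L)
  expect_equal(atoms$x[atoms$resno == 1], 5)   # higher occupancy wins
  expect_equal(atoms$x[atoms$resno == 2], 1)   # tie -> altloc A
})

test_that("assembly operators multiply chains and validate rotations", {
  dimer <- simulate_ring(30, 30) %>% dplyr::filter(chain %in% c("A", "B"))
  ident <- list(list(R = diag(3), t = c(0, 0, 0)))
  expect_equal(unique(apply_assembly(dimer, ident)$chain),
               unique(dimer$chain))
  rot_z <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
           byrow = TRUE)
  }
  ops4 <- lapply(c(0, 90, 180, 270), function(d) list(R = rot_z(d), t = c(0, 0, 0)))
  expanded <- apply_assembly(dimer, ops4)
  expect_equal(length(unique(expanded$chain)), 8L)
  # n operators -> exactly n-fold chain count for any n
  ops3 <- ops4[1:3]
  expect_equal(length(unique(apply_assembly(dimer, ops3)$chain)), 6L)
  bad <- list(list(R = diag(3) * 1.1, t = c(0, 0, 0)))
  expect_error(apply_assembly(dimer, bad), class = "rck_validation_error")
  improper <- list(list(R = diag(c(1, 1, -1)), t = c(0, 0, 0)))
  expect_error(apply_assembly(dimer, improper), class = "rck_validation_error")
})

test_that("a dimer expanded by the crystallographic 4-fold forms a square ring", {
  dimer <- simulate_ring(30, 30, dimer_d36 = rep(8, 4)) %>%
    dplyr::filter(chain %in% c("A", "B"))
  rot_z <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
           byrow = TRUE)
  }
  ops <- lapply(c(0, 90, 180, 270), function(d) list(R = rot_z(d), t = c(0, 0, 0)))
  ring <- build_ring(apply_assembly(dimer, ops))
  m <- compute_l1_l2(ring)
  expect_equal(m$L1, m$L2)                     # exact equality by symmetry
  # brute-force check of all marker diagonals on the expanded coordinates
  mk <- marker_coords(ring, 38)
  d <- sqrt(rowSums((mk[1:4, ] - mk[5:8, ])^2))
  expect_lt(max(d) - min(d), 1e-9)
})

test_that("build_ring rejects non-octameric selections with a count", {
  seven <- simulate_ring(30, 30) %>% dplyr::filter(chain != "H")
  err <- expect_error(build_ring(seven), class = "rck_ring_error")
  expect_match(conditionMessage(err), "expected 8 subunits, found 7")
})

test_that("subunit ordering matches a brute-force angular sort and is
           stable under relabeling", {
  set.seed(42)
  atoms <- simulate_ring(52, 22, dimer_d36 = c(8, 9, 8, 9))
  ring <- build_ring(atoms)
  # independent oracle: atan2 sort of subunit centroids in the xy plane
  cents <- sapply(LETTERS[1:8], function(ch) {
    sub <- atoms[atoms$chain == ch, ]
    c(mean(sub$x), mean(sub$y))
  })
  ang <- atan2(cents[2, ], cents[1, ]) %% (2 * pi)
  oracle <- names(sort(ang))
  # align both cyclic orders at chain A; allow either direction
  rot_to_a <- function(v) {
    i <- which(v == "A")
    c(v[i:length(v)], v[seq_len(i - 1L)])
  }
  got <- rot_to_a(ring$subunits)
  ora <- rot_to_a(oracle)
  expect_true(identical(got, ora) || identical(got, rot_to_a(rev(oracle))))

  # relabeling chains permutes nothing but the names
  relab <- atoms
  map <- setNames(LETTERS[c(3:8, 1:2)], LETTERS[1:8])
  relab$chain <- unname(map[relab$chain])
  ring2 <- build_ring(relab)
  orig_in_new_names <- unname(map[ring$subunits])
  same_cycle <- function(a, b) {
    n <- length(a)
    any(vapply(seq_len(n), function(s) {
      identical(b, c(a[s:n], a[seq_len(s - 1L)])) ||
        identical(rev(b), c(a[s:n], a[seq_len(s - 1L)]))
    }, logical(1)))
  }
  expect_true(same_cycle(orig_in_new_names, ring2$subunits))
})

test_that("marker lookup echoes synthetic coordinates and reports gaps", {
  atoms <- simulate_ring(30, 30)
  ring <- build_ring(atoms)
  mk <- marker_coords(ring, 38)
  manual <- t(sapply(ring$subunits, function(ch) {
    r <- atoms[atoms$chain == ch & atoms$resno == 38 & atoms$elety == "CA", ]
    c(r$x, r$y, r$z)
  }))
  expect_equal(unname(mk), unname(manual))
  err <- expect_error(marker_coords(ring, 9999), class = "rck_marker_error")
  expect_match(conditionMessage(err), "9999")
  expect_match(conditionMessage(err), "A, B")   # names offenders
})

test_that("BIOMT and mmCIF operator records are parsed", {
  pdb_lines <- c(
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 350   BIOMT1   2 -1.000000  0.000000  0.000000        5.00000",
    "REMARK 350   BIOMT2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "END")
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, p)
  ops <- read_assembly_operators(p)
  expect_length(ops, 2L)
  expect_equal(ops[[1]]$R, diag(3))
  expect_equal(ops[[2]]$t, c(5, 0, 0))

  cif_lines <- c(
    "loop_",
    "_pdbx_struct_oper_list.id",
    "_pdbx_struct_oper_list.matrix[1][1]",
    "_pdbx_struct_oper_list.matrix[1][2]",
    "_pdbx_struct_oper_list.matrix[1][3]",
    "_pdbx_struct_oper_list.vector[1]",
    "_pdbx_struct_oper_list.matrix[2][1]",
    "_pdbx_struct_oper_list.matrix[2][2]",
    "_pdbx_struct_oper_list.matrix[2][3]",
    "_pdbx_struct_oper_list.vector[2]",
    "_pdbx_struct_oper_list.matrix[3][1]",
    "_pdbx_struct_oper_list.matrix[3][2]",
    "_pdbx_struct_oper_list.matrix[3][3]",
    "_pdbx_struct_oper_list.vector[3]",
    "1 1.0 0.0 0.0 0.0 0.0 1.0 0.0 0.0 0.0 0.0 1.0 0.0",
    "2 0.0 -1.0 0.0 2.5 1.0 0.0 0.0 0.0 0.0 0.0 1.0 0.0",
    "#")
  pc <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif_lines, pc)
  ops2 <- read_assembly_operators(pc, format = "cif")
  expect_length(ops2, 2L)
  expect_equal(ops2[[2]]$R[1, ], c(0, -1, 0))
  expect_equal(ops2[[2]]$t, c(2.5, 0, 0))
})
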
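Package: rckring
Title: Conformation, Metal-Site, Conservation and Flux-Kinetics Analysis of
    RCK Octameric Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural and functional analysis of octameric
    rings formed by RCK ("regulator of conductance of K+") domains, such as the
    KtrA ring that gates the bacterial KtrAB potassium channel. Reads PDB and
    mmCIF coordinate files, expands crystallographic assemblies, and computes
    ring-conformation metrics (cross-ring L1/L2 diagonal distances between
    marker C-alpha atoms, intra-dimer distances, Kabsch C-alpha RMSD), with
    square versus non-square classification and complete-linkage clustering of
    ring conformations. Characterises divalent-cation coordination shells
    (coordination number, polyhedral geometry, donor distances, B-factor
    ratios) and scores candidate ion identities such as Mg2+ versus Ca2+.
    Scans sequences for the Rossmann-fold nucleotide-binding motif, maps and
    quantifies alignment-column conservation, and classifies Kef-family
    sequences by length. Normalises ACMA fluorescence-quenching flux traces,
    fits one- and two-phase exponential decays with information-criterion
    model selection, extracts flux rate constants (k = 1/tau), and fits Hill
    titrations. Includes seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
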
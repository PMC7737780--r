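# PDB input/output, torsion extraction, and idealized reconstruction.

test_that("a complete PDB file round-trips through write_pdb/read_pdb", {
  m <- helical_template(5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- read_pdb(f)
  expect_equal(n_residues(m2), 5)
  expect_length(m2$breaks, 0)
  expect_equal(m2$aa, m$aa)
  for (nm in c("N", "CA", "C", "O"))
    expect_lt(max(abs(m2$atoms[[nm]] - m$atoms[[nm]])), 0.001)
})

test_that("a residue missing CA is dropped with a warning and a break recorded", {
  m <- helical_template(5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  lines <- readLines(f)
  ca3 <- grep("^ATOM.* CA .* A   3 ", lines)
  expect_length(ca3, 1)
  writeLines(lines[-ca3], f)
  expect_warning(m2 <- read_pdb(f), "dropping 1 residue")
  expect_equal(n_residues(m2), 4)
  expect_equal(m2$breaks, 2L)  # discontinuity between old residues 2 and 4
  expect_equal(m2$seqnum, c(1L, 2L, 4L, 5L))
})

test_that("alternate locations resolve to highest occupancy, ties to altloc A", {
  mk_line <- function(serial, name, alt, resno, xyz, occ)
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, "ALA", "A", resno, xyz[1], xyz[2], xyz[3],
            occ, 0, substr(name, 1, 1))
  lines <- c(
    mk_line(1, "N", " ", 1, c(0, 0, 0), 1),
    mk_line(2, "CA", "B", 1, c(9, 9, 9), 0.4),
    mk_line(3, "CA", "A", 1, c(1.458, 0, 0), 0.6),
    mk_line(4, "C", " ", 1, c(2.0, 1.4, 0), 1),
    mk_line(5, "N", " ", 2, c(2.5, 2.6, 0), 1),
    mk_line(6, "CA", "A", 2, c(3.9, 3.0, 0), 0.5),
    mk_line(7, "CA", "B", 2, c(8, 8, 8), 0.5),
    mk_line(8, "C", " ", 2, c(5.0, 2.2, 0.4), 1),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_pdb(f)
  expect_equal(unname(m$atoms$CA[1, ]), c(1.458, 0, 0))   # higher occupancy
  expect_equal(unname(m$atoms$CA[2, ]), c(3.9, 3.0, 0))   # tie -> altloc A
})

test_that("missing chains are reported with the available ones", {
  m <- helical_template(5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  expect_error(read_pdb(f, chain = "Q"), "available chains: A")
})

test_that("torsion extraction follows the four-atom convention and chain ends", {
  m <- helical_template(10)
  tor <- extract_torsions(m)
  expect_true(is.na(tor$phi[1]))
  expect_true(is.na(tor$psi[10]) && is.na(tor$omega[10]))
  expect_true(all(abs(abs(tor$omega[1:9])) > 150))  # trans peptide near 180
  # two-residue chain: only psi[1]/omega[1]/phi[2] remain defined
  m2 <- rebuild_backbone(data.frame(phi = c(NA, -60), psi = c(120, NA),
                                    omega = c(180, NA)), "AA")
  t2 <- extract_torsions(m2)
  expect_true(is.na(t2$phi[1]) && is.na(t2$psi[2]) && is.na(t2$omega[2]))
  expect_equal(t2$phi[2], -60, tolerance = 1e-8)
})

test_that("dihedral agrees with an independent oracle and handles planar cis", {
  # planar cis arrangement: first and fourth points on the same side
  expect_equal(dihedral_angle(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dihedral_oracle(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  set.seed(101)
  for (k in 1:100) {
    pts <- matrix(rnorm(12, sd = 2), 4, 3)
    got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    want <- dihedral_oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("rebuild/extract is the identity and rebuilds are rigid-invariant", {
  set.seed(7)
  for (k in 1:20) {
    n <- sample(4:30, 1)
    tor <- random_torsions(n)
    m <- rebuild_backbone(tor, strrep("A", n))
    t2 <- extract_torsions(m)
    dd <- fragstitch:::.wrap_angle(as.matrix(t2) - as.matrix(tor))
    expect_lt(max(abs(dd), na.rm = TRUE), 0.01)
  }
  tor <- random_torsions(15)
  m1 <- rebuild_backbone(tor, strrep("G", 15))
  frame <- sweep(fragstitch:::.default_anchor_frame() %*% t(random_rotation()),
                 2, c(3, -8, 2), "+")
  m2 <- rebuild_backbone(tor, strrep("G", 15), anchor_frame = frame)
  fit <- kabsch_superpose(do.call(rbind, m2$atoms[c("N", "CA", "C")]),
                          do.call(rbind, m1$atoms[c("N", "CA", "C")]))
  expect_lt(fit$rmsd, 1e-6)
})

test_that("consecutive CA-CA distance for trans omega matches planar geometry", {
  g <- ideal_geometry()
  # independent 2D zigzag construction from the ideal constants
  deg <- pi / 180
  th1 <- (180 - g$a_ca_c_n) * deg
  v1 <- c(g$b_ca_c, 0)
  v2 <- g$b_c_n * c(cos(th1), sin(th1))
  th2 <- th1 - (180 - g$a_c_n_ca) * deg
  v3 <- g$b_n_ca * c(cos(th2), sin(th2))
  expected <- sqrt(sum((v1 + v2 + v3)^2))
  tor <- data.frame(phi = c(NA, -120), psi = c(140, NA), omega = c(180, NA))
  m <- rebuild_backbone(tor, "AA")
  got <- sqrt(sum((m$atoms$CA[2, ] - m$atoms$CA[1, ])^2))
  expect_equal(got, expected, tolerance = 0.05)
})

test_that("rebuild rejects undefined interior torsions and empty writes error", {
  tor <- random_torsions(6)
  tor$psi[3] <- NA
  expect_error(rebuild_backbone(tor, strrep("A", 6)), "interior")
  m <- helical_template(5)
  m_bad <- m; m_bad$aa <- character(0)
  expect_error(write_pdb(structure(list(aa = character(0)),
                                   class = "backbone_model"),
                         withr::local_tempfile()), "empty")
})

test_that("TER records are written at chain breaks", {
  m <- helical_template(8)
  # displace the tail to create a genuine discontinuity
  for (nm in names(m$atoms)) m$atoms[[nm]][5:8, ] <- m$atoms[[nm]][5:8, ] + 40
  m <- backbone_model(m$source_id, m$aa, m$atoms)
  expect_equal(m$breaks, 4L)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  lines <- readLines(f)
  ters <- grep("^TER", lines)
  expect_length(ters, 2)  # one at the break, one at chain end
  expect_match(lines[ters[1]], " 4$")
})
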
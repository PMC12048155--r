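test_that("a three-residue ATOM block parses into the forced sequence", {
  txt <- three_residue_pdb(c("A", "C", "D"))
  s <- parse_structure(txt)
  expect_s3_class(s, "protein_structure")
  expect_equal(n_residues(s), 3)
  expect_equal(s$sequence, "ACD")
  expect_true(all(s$chain == "A"))
  expect_silent(validate_structure(s))
})

test_that("degenerate input and missing chains raise parse errors", {
  expect_error(parse_structure(""), "ATOM")
  expect_error(parse_structure("HEADER    ONLY A HEADER\nEND"), "ATOM")
  txt <- three_residue_pdb()
  expect_error(parse_structure(txt, chain = "B"), "chain 'B' not found")
})

test_that("alternate locations resolve to the highest occupancy", {
  txt <- three_residue_pdb(c("A", "C", "D"))
  ca_idx <- grep("^ATOM.{9}CA", txt)[1]
  base <- txt[ca_idx]
  with_alt <- function(line, alt, occ, xshift) {
    x <- as.numeric(substr(line, 31, 38)) + xshift
    paste0(substr(line, 1, 16), alt, substr(line, 18, 30),
           sprintf("%8.3f", x), substr(line, 39, 54),
           sprintf("%6.2f", occ), substr(line, 61, nchar(line)))
  }
  txt_alt <- append(txt[-ca_idx],
                    c(with_alt(base, "A", 0.60, 0),
                      with_alt(base, "B", 0.40, 5)),
                    after = ca_idx - 1)
  s <- parse_structure(txt_alt)
  s_ref <- parse_structure(txt)
  # altloc A (occupancy 0.6) wins: CA coordinate matches the unshifted one
  expect_equal(s$atoms$CA[1, ], s_ref$atoms$CA[1, ], tolerance = 1e-6)
})

test_that("PDB round-trip preserves sequence and coordinates", {
  s <- helix(15, jitter = 0.3, seed = 7)
  tmp <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, tmp)
  s2 <- parse_structure(tmp)
  expect_equal(s2$sequence, s$sequence)
  for (a in c("N", "CA", "C", "O")) {
    expect_lt(max(abs(s2$atoms[[a]] - s$atoms[[a]])), 1e-3)
  }
  # and the re-written file parses identically again
  tmp2 <- tempfile(fileext = ".pdb")
  write_structure_pdb(s2, tmp2)
  s3 <- parse_structure(tmp2)
  expect_equal(s3$sequence, s2$sequence)
  expect_lt(max(abs(s3$atoms$CA - s2$atoms$CA)), 1e-3)
  unlink(c(tmp, tmp2))
})

test_that("parsing ignores HETATM/ANISOU/header records and maps MSE", {
  txt <- three_residue_pdb(c("A", "C", "D"))
  noise <- c("HEADER    TEST",
             "ANISOU    1  N   ALA A   1     100    100FAKE",
             "HETATM 9999  O   HOH A 900      99.000  99.000  99.000  1.00  0.00           O")
  mixed <- c(noise[1], txt[1:4], noise[2:3], txt[5:length(txt)])
  s <- parse_structure(mixed)
  expect_equal(s$sequence, "ACD")
  # MSE maps to its canonical parent M
  txt_mse <- sub("ALA", "MSE", txt)
  expect_equal(substr(parse_structure(txt_mse)$sequence, 1, 1), "M")
  # an unknown residue name maps to X but keeps its node
  txt_unk <- sub("ALA", "ZZZ", txt)
  s_unk <- parse_structure(txt_unk)
  expect_equal(s_unk$sequence, "XCD")
  expect_equal(n_residues(s_unk), 3)
})

test_that("missing O and CB are reconstructed and flagged", {
  txt <- three_residue_pdb()
  no_o <- txt[!grepl("^ATOM.{9}O ", txt)]
  s <- parse_structure(no_o)
  expect_equal(n_residues(s), 3)
  expect_true(all(is.finite(s$atoms$O)))
  expect_true(all(s$cb_virtual))
  d_co <- sqrt(rowSums((s$atoms$C - s$atoms$O)^2))
  expect_true(all(abs(d_co - 1.231) < 0.01))
  expect_silent(validate_structure(s))
})

test_that("virtual C-beta has ideal tetrahedral geometry and is equivariant", {
  s <- helix(10, jitter = 0, seed = 3)
  i <- 5
  cb <- virtual_cbeta(s$atoms$N[i, ], s$atoms$CA[i, ], s$atoms$C[i, ])
  d_ca <- sqrt(sum((cb - s$atoms$CA[i, ])^2))
  expect_true(abs(d_ca - 1.53) < 0.02)
  # tetrahedral angles, computed independently from the returned point
  ang <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  expect_true(abs(ang(s$atoms$N[i, ], s$atoms$CA[i, ], cb) - 110) < 3)
  expect_true(abs(ang(s$atoms$C[i, ], s$atoms$CA[i, ], cb) - 110) < 3)

  motion <- rigid_motion(9)
  cb_t <- virtual_cbeta(as.numeric(motion$R %*% s$atoms$N[i, ] + motion$t),
                        as.numeric(motion$R %*% s$atoms$CA[i, ] + motion$t),
                        as.numeric(motion$R %*% s$atoms$C[i, ] + motion$t))
  expect_lt(max(abs(cb_t - (as.numeric(motion$R %*% cb) + motion$t))), 1e-9)

  expect_error(virtual_cbeta(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)), "collinear")
  expect_error(virtual_cbeta(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("FASTA write/read round-trips extracted sequences", {
  ss <- list(helix(8, seed = 1), helix(12, seed = 2))
  tmp <- tempfile(fileext = ".fasta")
  write_structure_fasta(ss, tmp)
  seqs <- read_fasta_sequences(tmp)
  expect_equal(unname(seqs), vapply(ss, `[[`, character(1), "sequence"))
  unlink(tmp)
})
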
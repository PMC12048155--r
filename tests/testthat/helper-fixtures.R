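# Shared helpers: tiny structures, graphs and rigid motions built in code.

helix <- function(n = 20, jitter = 0.3, seed = 1) {
  make_helix_structure(n, jitter_sd = jitter, seed = seed)
}

tiny_graph <- function(n = 10, k = 5, seed = 1, jitter = 0.3) {
  build_residue_graph(helix(n, jitter, seed), graph_config(k = k))
}

rigid_motion <- function(seed = 1) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    list(R = q, t = rnorm(3, sd = 5))
  })
}

transform_structure <- function(s, motion) {
  s$atoms <- lapply(s$atoms, function(m) {
    sweep(m %*% t(motion$R), 2, motion$t, "+")
  })
  s
}

# A hand-written three-residue PDB block (ALA, CYS, ASP on chain A) with
# physically sensible backbone coordinates taken from an ideal helix.
three_residue_pdb <- function(aa = c("A", "C", "D")) {
  s <- helix(3, jitter = 0, seed = 42)
  s$aa <- aa
  s$sequence <- paste(aa, collapse = "")
  tmp <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, tmp)
  txt <- readLines(tmp)
  unlink(tmp)
  txt
}

# Planted assay + scorer pair for evaluation tests.
planted_setup <- function(n = 25, n_mutants = 40, noise_sd = 0, seed = 1) {
  s <- helix(n, jitter = 0.3, seed = seed)
  lp <- random_logprobs(n, seed = seed + 1)
  assay <- make_synthetic_assay(s, lp, n_mutants = n_mutants,
                                noise_sd = noise_sd, seed = seed + 2)
  list(structure = s, logprobs = lp, assay = assay)
}
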
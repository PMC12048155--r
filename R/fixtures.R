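# Synthetic fixtures: idealized backbones and planted-signal assays ------

#' Fixture generation specification
#'
#' @param n_proteins Number of proteins in a synthetic corpus.
#' @param length_range Integer (min, max) residue counts.
#' @param noise_sd Coordinate jitter in Angstrom applied to backbone atoms
#'   (default 0.3: thermal-displacement scale, so helices are not perfectly
#'   self-similar).
#' @param assay_noise_sd Gaussian noise added to planted assay scores.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 3, length_range = c(30, 30),
                         noise_sd = 0.3, assay_noise_sd = 0, seed = 1) {
  if (any(length_range < 2)) stop("lengths must be >= 2")
  if (noise_sd < 0 || assay_noise_sd < 0) stop("noise levels must be nonnegative")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 noise_sd = noise_sd, assay_noise_sd = assay_noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Ideal backbone internal coordinates (Angstrom / degrees): alpha helix
# with phi = -57, psi = -47, omega = 180.
.HELIX_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  phi = -57, psi = -47, omega = 180
)

#' Generate an idealized alpha-helical backbone
#'
#' Places N, CA, C atoms by chaining ideal bond lengths, angles and
#' helical dihedrals (consecutive C-alpha separation close to 3.8
#' Angstrom), reconstructs carbonyl O atoms, builds virtual C-beta atoms,
#' optionally jitters all coordinates with Gaussian noise, and assigns a
#' random sequence over the 20 canonical residues.
#'
#' @param n Number of residues (>= 2).
#' @param jitter_sd Coordinate noise standard deviation in Angstrom.
#' @param seed Integer seed; identical seeds give identical structures.
#' @param id Structure identifier.
#' @return A `protein_structure`.
#' @export
make_helix_structure <- function(n, jitter_sd = 0, seed = 1,
                                 id = sprintf("helix_%d", seed)) {
  if (n < 2) stop("a helix needs at least 2 residues")
  g <- .HELIX_GEOM
  d2r <- pi / 180
  withr::with_seed(seed, {
    # seed atoms for the first residue
    N <- matrix(0, n, 3)
    CA <- matrix(0, n, 3)
    C <- matrix(0, n, 3)
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(g$b_n_ca, 0, 0)
    C[1, ] <- CA[1, ] + g$b_ca_c *
      c(cos(pi - g$a_n_ca_c * d2r), sin(pi - g$a_n_ca_c * d2r), 0)
    for (i in 2:n) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n * d2r, g$psi * d2r)
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca * d2r, g$omega * d2r)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c * d2r, g$phi * d2r)
    }
    O <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      O[i, ] <- reconstruct_oxygen(N[i, ], CA[i, ], C[i, ],
                                   if (i < n) N[i + 1, ] else NULL)
    }
    if (jitter_sd > 0) {
      # rigid per-residue displacement: breaks helical self-similarity while
      # leaving intra-residue geometry ideal
      shift <- matrix(stats::rnorm(3 * n, sd = jitter_sd), n, 3)
      N <- N + shift
      CA <- CA + shift
      C <- C + shift
      O <- O + shift
    }
    CB <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      CB[i, ] <- virtual_cbeta(N[i, ], CA[i, ], C[i, ])
    }
    aa <- sample(canonical_residues(), n, replace = TRUE)
    new_protein_structure(
      id = id, chain = rep("A", n), seq_index = seq_len(n), aa = aa,
      atoms = list(N = N, CA = CA, C = C, O = O, CB = CB),
      cb_virtual = rep(TRUE, n)
    )
  })
}

#' Generate a synthetic corpus of helical structures
#'
#' @param spec A [fixture_spec()].
#' @return List of `protein_structure` objects with lengths drawn uniformly
#'   from the requested length range.
#' @export
make_corpus <- function(spec = fixture_spec()) {
  rng <- seq(spec$length_range[1], spec$length_range[2])
  lens <- withr::with_seed(spec$seed, {
    rng[sample.int(length(rng), spec$n_proteins, replace = TRUE)]
  })
  lapply(seq_len(spec$n_proteins), function(i) {
    make_helix_structure(lens[i], jitter_sd = spec$noise_sd,
                         seed = spec$seed + i,
                         id = sprintf("fixture_%d_%d", spec$seed, i))
  })
}

#' Random planted per-site log-probability table
#'
#' Row-normalized log-probabilities over the 33 tokens, used as a known
#' scoring model for planted-signal assays.
#'
#' @param n Number of sites.
#' @param seed Integer seed.
#' @return `n x 33` log-probability matrix.
#' @export
random_logprobs <- function(n, seed = 1) {
  withr::with_seed(seed, {
    logits_to_logprobs(matrix(stats::rnorm(n * 33), n, 33))
  })
}

#' Synthetic assay with a planted monotone signal
#'
#' Samples distinct random single-site mutants of a structure and assigns
#' each an experimental score equal to its log-odds fitness under a planted
#' log-probability model plus Gaussian noise. With zero noise a scorer that
#' knows the planted model recovers the scores exactly (rank correlation 1).
#'
#' @param structure A `protein_structure`.
#' @param planted_logprobs `n x 33` log-probability matrix (the planted
#'   model), e.g. [random_logprobs()].
#' @param n_mutants Number of mutants (>= 10 so the assay survives
#'   curation; at most `19 * n` are available).
#' @param noise_sd Score noise standard deviation.
#' @param seed Integer seed.
#' @param ph Nominal assay pH recorded in the table.
#' @return Tibble with columns `protein_id`, `mutant`, `score`, `ph`.
#' @export
make_synthetic_assay <- function(structure, planted_logprobs, n_mutants = 50,
                                 noise_sd = 0, seed = 1, ph = 7.0) {
  n <- n_residues(structure)
  if (n_mutants < 10) stop("n_mutants must be >= 10 to survive curation")
  if (nrow(planted_logprobs) != n) {
    stop("planted_logprobs must have one row per residue")
  }
  wt <- as_site_chars(structure$sequence)
  candidates <- expand.grid(position = seq_len(n), mut = canonical_residues(),
                            stringsAsFactors = FALSE)
  candidates <- candidates[candidates$mut != wt[candidates$position], ]
  if (n_mutants > nrow(candidates)) {
    stop("requested more mutants than the ", nrow(candidates), " available")
  }
  withr::with_seed(seed, {
    pick <- candidates[sample(nrow(candidates), n_mutants), ]
    mut_str <- sprintf("%s%d%s", wt[pick$position], pick$position, pick$mut)
    planted <- vapply(mut_str, function(m) {
      score_mutant(planted_logprobs, parse_mutant(m, wt))$value
    }, numeric(1))
    tibble::tibble(
      protein_id = structure$id,
      mutant = mut_str,
      score = unname(planted) + stats::rnorm(n_mutants, sd = noise_sd),
      ph = ph
    )
  })
}
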
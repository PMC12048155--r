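# Structure I/O ----------------------------------------------------------

# Non-standard residues mapped to their canonical parent; anything else
# becomes 'X' (kept as a node, one-hot to the unknown-residue token).
.NONSTANDARD_MAP <- c(
  MSE = "M", SEC = "C", CSO = "C", CSD = "C", CME = "C",
  SEP = "S", TPO = "T", PTR = "Y", HYP = "P", MLY = "K",
  KCX = "K", PCA = "Q", LLP = "K", M3L = "K", FME = "M"
)

.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

aa_three_to_one <- function(resid) {
  out <- .AA3TO1[resid]
  ns <- is.na(out)
  out[ns] <- .NONSTANDARD_MAP[resid[ns]]
  out[is.na(out)] <- "X"
  unname(out)
}

new_protein_structure <- function(id, chain, seq_index, aa, atoms, cb_virtual,
                                  insert = NULL) {
  structure(
    list(
      id = id,
      chain = chain,
      seq_index = as.integer(seq_index),
      insert = if (is.null(insert)) rep("", length(aa)) else insert,
      sequence = paste(aa, collapse = ""),
      aa = aa,
      atoms = atoms, # named list of n x 3 matrices: N, CA, C, O, CB
      cb_virtual = cb_virtual
    ),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$id, ": ", n_residues(x), " residues, chain(s) ",
      paste(unique(x$chain), collapse = ","), "\n  sequence: ",
      substr(x$sequence, 1, 60),
      if (nchar(x$sequence) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param structure A `protein_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(structure) length(structure$aa)

#' Per-residue tibble view of a structure
#'
#' @param x A `protein_structure`.
#' @param ... Unused.
#' @return A tibble with one row per residue: chain, seq_index, aa,
#'   cb_virtual, and x/y/z columns for each backbone atom.
#' @export
as_tibble.protein_structure <- function(x, ...) {
  out <- tibble::tibble(
    chain = x$chain, seq_index = x$seq_index, aa = x$aa,
    cb_virtual = x$cb_virtual
  )
  for (atom in names(x$atoms)) {
    m <- x$atoms[[atom]]
    colnames(m) <- paste0(tolower(atom), "_", c("x", "y", "z"))
    out <- dplyr::bind_cols(out, tibble::as_tibble(m))
  }
  out
}

#' Parse a backbone structure from PDB text or file
#'
#' Reads ATOM records (model 1 only; HETATM/ANISOU/header records ignored),
#' resolves alternate locations to the highest occupancy, preserves insertion
#' codes in residue ordering, maps non-standard residues to their canonical
#' parent (else `X`), and keeps residues that have at least N, CA and C.
#' Missing carbonyl O atoms are reconstructed from ideal peptide geometry; a
#' C-beta is taken from the file when present, else built virtually from the
#' backbone, so every residue carries five atoms (N, CA, C, O, CB).
#'
#' @param pdb Either a path to a PDB file or PDB-format text (a string
#'   containing newlines, or a character vector of lines).
#' @param chain Chain identifier to extract, or `NULL` for all chains in
#'   file order.
#' @param id Identifier for the returned structure; defaults to the file
#'   basename or `"structure"`.
#' @return A `protein_structure`: ordered residues, backbone coordinates in
#'   Angstrom, and the extracted one-letter sequence.
#' @export
parse_structure <- function(pdb, chain = NULL, id = NULL) {
  lines <- pdb_text_lines(pdb)
  if (is.null(id)) {
    id <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
      sub("\\.pdb$", "", basename(pdb))
    } else "structure"
  }
  if (!any(startsWith(lines, "ATOM"))) {
    stop("no ATOM records found: cannot parse a structure")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb_obj <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                                              verbose = FALSE))
  at <- pdb_obj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found: cannot parse a structure")
  if (!is.null(chain)) {
    if (!chain %in% at$chain) {
      stop(sprintf("chain '%s' not found in structure", chain))
    }
    at <- at[at$chain == chain, , drop = FALSE]
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  res_key <- paste(at$chain, at$resno, at$insert, sep = "|")
  keys <- unique(res_key) # file order, insertion codes preserved
  want <- c("N", "CA", "C", "O", "CB")

  rows <- lapply(keys, function(k) {
    sub <- at[res_key == k, , drop = FALSE]
    coords <- matrix(NA_real_, nrow = 5, ncol = 3,
                     dimnames = list(want, c("x", "y", "z")))
    for (atom in want) {
      hit <- sub[sub$elety == atom, , drop = FALSE]
      if (nrow(hit) == 0L) next
      hit <- hit[order(-hit$o, hit$alt), , drop = FALSE] # highest occupancy
      coords[atom, ] <- as.numeric(hit[1, c("x", "y", "z")])
    }
    list(chain = sub$chain[1], resno = sub$resno[1], insert = sub$insert[1],
         resid = sub$resid[1], coords = coords)
  })

  complete <- vapply(rows, function(r) {
    all(is.finite(r$coords["N", ])) && all(is.finite(r$coords["CA", ])) &&
      all(is.finite(r$coords["C", ]))
  }, logical(1))
  if (!any(complete)) {
    stop("no residue with a complete N/CA/C backbone in the requested chain(s)")
  }
  if (any(!complete)) {
    warning(sprintf("dropping %d residue(s) lacking N/CA/C backbone atoms",
                    sum(!complete)))
  }
  rows <- rows[complete]

  n <- length(rows)
  atoms <- lapply(want, function(a) {
    t(vapply(rows, function(r) r$coords[a, ], numeric(3)))
  })
  names(atoms) <- want

  aa <- aa_three_to_one(vapply(rows, `[[`, character(1), "resid"))
  cb_virtual <- rep(FALSE, n)

  for (i in seq_len(n)) {
    if (!all(is.finite(atoms$O[i, ]))) {
      n_next <- if (i < n && rows[[i + 1]]$chain == rows[[i]]$chain) {
        atoms$N[i + 1, ]
      } else NULL
      atoms$O[i, ] <- reconstruct_oxygen(atoms$N[i, ], atoms$CA[i, ],
                                         atoms$C[i, ], n_next)
    }
    if (!all(is.finite(atoms$CB[i, ]))) {
      atoms$CB[i, ] <- virtual_cbeta(atoms$N[i, ], atoms$CA[i, ], atoms$C[i, ])
      cb_virtual[i] <- TRUE
    }
  }

  new_protein_structure(
    id = id,
    chain = vapply(rows, `[[`, character(1), "chain"),
    seq_index = vapply(rows, `[[`, numeric(1), "resno"),
    insert = vapply(rows, `[[`, character(1), "insert"),
    aa = aa,
    atoms = atoms,
    cb_virtual = cb_virtual
  )
}

pdb_text_lines <- function(pdb) {
  if (length(pdb) > 1L) return(pdb)
  if (grepl("\n", pdb)) return(strsplit(pdb, "\n", fixed = TRUE)[[1]])
  if (file.exists(pdb)) return(readLines(pdb, warn = FALSE))
  if (!nzchar(trimws(pdb))) stop("no ATOM records found: cannot parse a structure")
  pdb
}

.AA1TO3 <- stats::setNames(names(.AA3TO1), .AA3TO1)

#' Write a structure's backbone to PDB format
#'
#' Emits ATOM records for N, CA, C, O (and CB where it came from the input
#' rather than virtual construction). Round-tripping through
#' [parse_structure()] preserves sequence and coordinates.
#'
#' @param structure A `protein_structure`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(structure, file) {
  n <- n_residues(structure)
  atom_names <- character(0)
  xyz <- NULL
  resno <- integer(0)
  resid <- character(0)
  chain <- character(0)
  insert <- character(0)
  for (i in seq_len(n)) {
    atoms <- c("N", "CA", "C", "O")
    if (!structure$cb_virtual[i]) atoms <- c(atoms, "CB")
    for (a in atoms) {
      atom_names <- c(atom_names, a)
      xyz <- rbind(xyz, structure$atoms[[a]][i, ])
      resno <- c(resno, structure$seq_index[i])
      r3 <- .AA1TO3[structure$aa[i]]
      resid <- c(resid, if (is.na(r3)) "UNK" else r3)
      chain <- c(chain, structure$chain[i])
      insert <- c(insert, structure$insert[i])
    }
  }
  ins <- ifelse(nzchar(insert), insert, "")
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
    seq_along(atom_names), atom_names, resid, chain, resno, ifelse(ins == "", " ", ins),
    xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, substr(atom_names, 1, 1)
  )
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Write extracted sequences to FASTA
#'
#' @param structures A `protein_structure` or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure_fasta <- function(structures, file) {
  if (inherits(structures, "protein_structure")) structures <- list(structures)
  seqinr::write.fasta(
    sequences = lapply(structures, function(s) strsplit(s$sequence, "")[[1]]),
    names = vapply(structures, `[[`, character(1), "id"),
    file.out = file
  )
  invisible(file)
}

#' Read sequences from a FASTA file
#'
#' @param file Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(file) {
  seqs <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE)
  stats::setNames(toupper(vapply(seqs, as.character, character(1))), names(seqs))
}

#' Validate structural invariants of a parsed structure
#'
#' Checks that backbone coordinates are finite, intra-residue backbone atom
#' distances are below 3 Angstrom, and the CB-CA distance lies in
#' 1.0 to 2.2 Angstrom.
#'
#' @param structure A `protein_structure`.
#' @return `TRUE` invisibly; errors describing the first violated invariant
#'   otherwise.
#' @export
validate_structure <- function(structure) {
  a <- structure$atoms
  if (nchar(structure$sequence) != n_residues(structure)) {
    stop("sequence length does not match residue count")
  }
  for (nm in c("N", "CA", "C", "O")) {
    if (!all(is.finite(a[[nm]]))) stop("non-finite ", nm, " coordinates")
  }
  pairs <- utils::combn(c("N", "CA", "C", "O"), 2)
  for (j in seq_len(ncol(pairs))) {
    d <- sqrt(rowSums((a[[pairs[1, j]]] - a[[pairs[2, j]]])^2))
    # N-O spans ~3.5 A at helical psi; all other backbone pairs stay under 3 A
    lim <- if (setequal(pairs[, j], c("N", "O"))) 4 else 3
    if (any(d >= lim)) {
      stop(sprintf("intra-residue %s-%s distance >= %d Angstrom",
                   pairs[1, j], pairs[2, j], lim))
    }
  }
  dcb <- sqrt(rowSums((a$CB - a$CA)^2))
  if (any(dcb < 1.0 | dcb > 2.2)) stop("CB-CA distance outside [1.0, 2.2] Angstrom")
  for (ch in unique(structure$chain)) {
    idx <- structure$seq_index[structure$chain == ch]
    ins <- structure$insert[structure$chain == ch]
    if (any(diff(idx) < 0)) stop("residue order not non-decreasing within chain")
    if (any(diff(idx) == 0 & !nzchar(ins[-1]))) {
      stop("duplicate residue number without insertion code")
    }
  }
  invisible(TRUE)
}
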
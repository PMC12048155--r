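# Token vocabulary -------------------------------------------------------

# The 33-token alphabet follows the published ESM-style ordering so that
# externally computed per-residue embedding tables align row-for-row with
# token indices without remapping.
.STRUCTVEP_TOKENS <- c(
  "<cls>", "<pad>", "<eos>", "<unk>",
  "L", "A", "G", "V", "S", "E", "R", "T", "I", "D", "P", "K", "Q", "N",
  "F", "Y", "M", "H", "W", "C", "X", "B", "U", "Z", "O", ".", "-",
  "<null_1>", "<mask>"
)

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, in the conventional
#' alphabetical-by-three-letter-code order used throughout the package for
#' replacement distributions.
#'
#' @return Character vector of length 20.
#' @export
canonical_residues <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Token vocabulary for sequence encoding
#'
#' Returns the ordered 33-symbol vocabulary used for one-hot encoding and for
#' the network readout: the 20 canonical residues, ambiguity/non-standard
#' symbols (`X`, `B`, `U`, `Z`, `O`, `.`, `-`), and special tokens
#' (`<cls>`, `<pad>`, `<eos>`, `<unk>`, `<null_1>`, `<mask>`).
#'
#' @return A character vector of length 33 with class `token_vocabulary`.
#' @examples
#' vocab <- token_vocabulary()
#' length(vocab) # 33
#' @export
token_vocabulary <- function() {
  structure(.STRUCTVEP_TOKENS, class = c("token_vocabulary", "character"))
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat("<token_vocabulary> ", length(x), " tokens: ",
      paste(unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Map sequence symbols to token indices
#'
#' Splits a sequence given as a single string into characters (a character
#' vector is passed through, so multi-character tokens such as `"<mask>"` are
#' representable) and maps each symbol to its vocabulary index. Symbols not in
#' the vocabulary are absorbed into the `X` (unknown residue) token.
#'
#' @param sequence Character scalar or character vector of per-site symbols.
#' @param vocab A [token_vocabulary()].
#' @return Integer vector of 1-based token indices.
#' @export
token_indices <- function(sequence, vocab = token_vocabulary()) {
  chars <- as_site_chars(sequence)
  # residue context: only the 20 canonical letters, X, gap symbols and the
  # special multi-character tokens map to themselves; every other letter
  # (ambiguity codes included) is absorbed into the unknown-residue token X
  allowed <- c(canonical_residues(), "X", ".", "-",
               vocab[startsWith(vocab, "<")])
  chars[!chars %in% allowed] <- "X"
  match(chars, vocab)
}

#' One-hot encode a sequence over the 33-token vocabulary
#'
#' @inheritParams token_indices
#' @return An n x 33 numeric matrix; each row has exactly one 1.
#' @examples
#' m <- one_hot_encode("ACD")
#' dim(m)          # 3 33
#' rowSums(m)      # all 1
#' @export
one_hot_encode <- function(sequence, vocab = token_vocabulary()) {
  idx <- token_indices(sequence, vocab)
  n <- length(idx)
  m <- matrix(0, nrow = n, ncol = length(vocab))
  m[cbind(seq_len(n), idx)] <- 1
  m
}

# Split a scalar string into per-site characters; pass vectors through.
as_site_chars <- function(sequence) {
  if (length(sequence) == 1L && !grepl("^<", sequence)) {
    strsplit(sequence, "", fixed = TRUE)[[1]]
  } else {
    as.character(sequence)
  }
}

# Collapse per-site symbols to a display string (multi-char tokens kept).
chars_to_string <- function(chars) paste(chars, collapse = "")
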
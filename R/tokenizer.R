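# Chemically aware SMILES tokenization: atom labels and their charges stay
# single tokens ("Cl" is one chlorine token, never "C" + "l"; "[N+]" is one
# token). Greedy longest-match over an explicit inventory:
#   bracket atoms [..] | %nn ring closures | Cl | Br | organic-subset and
#   aromatic atoms | digits | bonds - = # $ : / \ | branches ( ) | dot | *
.TOKEN_PATTERNS <- c(
  "\\[[^][]*\\]",   # bracket atom: isotope/element/chirality/H/charge/class
  "%[0-9]{2}",      # two-digit ring closure
  "Cl", "Br",       # two-letter organic-subset halogens
  "[BCNOPSFI]",     # single-letter organic-subset elements
  "[bcnops]",       # aromatic atoms
  "[0-9]",          # single-digit ring closures
  "[()=#$:/\\\\.*-]"  # branches, bonds, stereo slashes, dot, wildcard
)
.TOKEN_REGEX <- paste0("^(", paste(.TOKEN_PATTERNS, collapse = "|"), ")")

#' Tokenize a SMILES string into chemically meaningful tokens
#'
#' Deterministic, prefix-greedy scan that is lossless by construction:
#' concatenating the tokens reproduces the input exactly. Characters outside
#' the SMILES alphabet fail fast with the offending position, so corpus
#' errors surface before any training.
#'
#' @param smiles a single SMILES string (\code{""} gives an empty sequence)
#' @return a [TokenSequence-class]
#' @examples
#' tokenizeSmiles("Cl(O)O")        # Cl ( O ) O  -- not C l ( O ) O
#' tokenizeSmiles("C[N+](C)(C)C")  # C [N+] ( C ) ( C ) C
#' @export
tokenizeSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  tokens <- character()
  rest <- smiles
  pos <- 1L
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr(.TOKEN_REGEX, rest, perl = TRUE))
    if (!length(m))
      stop("tokenization error at position ", pos, ": unexpected character '",
           substr(rest, 1L, 1L), "' in \"", smiles, "\"")
    tokens <- c(tokens, m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
    pos <- pos + nchar(m)
  }
  new("TokenSequence", tokens = tokens, source = smiles)
}

#' @rdname TokenSequence-class
#' @param x a TokenSequence
#' @export
tokens <- function(x) x@tokens

setMethod("show", "TokenSequence", function(object) {
  cat("TokenSequence (", length(object@tokens), " tokens): ",
      paste(object@tokens, collapse = " | "), "\n", sep = "")
})

.SPECIALS <- c(pad = "<pad>", unk = "<unk>", start = "<cls>")

#' Build a token vocabulary from a corpus
#'
#' The vocabulary is the three special tokens (padding, unknown, sequence
#' start at indices 0, 1, 2) followed by the distinct corpus tokens in
#' lexicographic order, so identical corpora always produce identical index
#' assignments.
#'
#' @param corpus a list of [TokenSequence-class] objects (or plain character
#'   token vectors)
#' @return a [TokenVocabulary-class]
#' @export
buildVocabulary <- function(corpus) {
  if (!length(corpus)) stop("empty corpus: cannot build a vocabulary")
  toks <- unlist(lapply(corpus, function(s)
    if (is(s, "TokenSequence")) s@tokens else as.character(s)), use.names = FALSE)
  new("TokenVocabulary",
      tokens = c(unname(.SPECIALS), .lexSort(unique(toks))),
      specials = .SPECIALS)
}

#' @rdname TokenVocabulary-class
#' @param x a TokenVocabulary
#' @export
vocabularySize <- function(x) length(x@tokens)

#' @rdname TokenVocabulary-class
#' @param token character vector of tokens
#' @return 0-based indices (\code{tokenIndex}); unknown tokens map to the
#'   unknown index
#' @export
tokenIndex <- function(x, token) {
  i <- match(token, x@tokens)
  i[is.na(i)] <- match(x@specials[["unk"]], x@tokens)
  i - 1L
}

setMethod("show", "TokenVocabulary", function(object) {
  cat("TokenVocabulary with", length(object@tokens), "tokens",
      "(3 specials +", length(object@tokens) - 3L, "corpus tokens)\n")
})

#' Encode a token sequence as fixed-length integer indices
#'
#' Emits the sequence-start index followed by the token indices (unknown
#' tokens map to the unknown index, never an error) and pads with the
#' padding index up to \code{maxLength}. Sequences longer than
#' \code{maxLength - 1} raise an error unless \code{truncate = TRUE}.
#'
#' @param vocab a [TokenVocabulary-class]
#' @param seq a [TokenSequence-class] (or character vector of tokens)
#' @param maxLength total encoded length (>= 2)
#' @param truncate drop tokens beyond the limit instead of failing
#' @return integer vector of 0-based indices, length \code{maxLength}
#' @export
encodeTokens <- function(vocab, seq, maxLength, truncate = FALSE) {
  stopifnot(maxLength >= 2)
  toks <- if (is(seq, "TokenSequence")) seq@tokens else as.character(seq)
  if (length(toks) > maxLength - 1L) {
    if (!truncate)
      stop("sequence of ", length(toks), " tokens exceeds maxLength - 1 = ",
           maxLength - 1L, " (use truncate = TRUE to cut)")
    toks <- toks[seq_len(maxLength - 1L)]
  }
  startIdx <- match(vocab@specials[["start"]], vocab@tokens) - 1L
  padIdx <- match(vocab@specials[["pad"]], vocab@tokens) - 1L
  out <- c(startIdx, tokenIndex(vocab, toks))
  c(out, rep(padIdx, maxLength - length(out)))
}

#' @rdname encodeTokens
#' @param indices 0-based integer indices as produced by \code{encodeTokens}
#' @return \code{decodeTokens}: the token character vector (specials removed)
#' @export
decodeTokens <- function(vocab, indices) {
  toks <- vocab@tokens[indices + 1L]
  toks[!toks %in% vocab@specials]
}

#' Persist / read a vocabulary as a two-column TSV
#'
#' @param vocab a [TokenVocabulary-class]
#' @param path TSV path (columns: token, index)
#' @return \code{path} (writer) or a [TokenVocabulary-class] (reader)
#' @export
writeVocabulary <- function(vocab, path) {
  utils::write.table(
    data.frame(token = vocab@tokens, index = seq_along(vocab@tokens) - 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"),
                          quote = "", comment.char = "")
  tb <- tb[order(tb$index), , drop = FALSE]
  new("TokenVocabulary", tokens = tb$token, specials = .SPECIALS)
}
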
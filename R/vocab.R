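#' Character vocabulary
#'
#' A bijection between characters and contiguous indices with two reserved
#' entries: \code{<PAD>} at index 1 and \code{<UNK>} at index 2 (R is
#' 1-based; serialized forms use the same order, so PAD is always the first
#' row of an embedding matrix and its vector is frozen at zero).
#'
#' @param tokens character vector starting with \code{"<PAD>", "<UNK>"}
#' @return object of class \code{char_vocab}
#' @keywords internal
new_char_vocab <- function(tokens) {
  stopifnot(identical(tokens[1:2], c("<PAD>", "<UNK>")),
            !anyDuplicated(tokens))
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "char_vocab")
}

#' @export
print.char_vocab <- function(x, ...) {
  cat("<char_vocab> size", length(x$tokens),
      "(incl. <PAD>, <UNK>)\n")
  invisible(x)
}

#' Build a character vocabulary from a corpus
#'
#' Characters with frequency >= \code{min_count} are kept, ordered by
#' frequency (descending) then by unicode codepoint — a deterministic order
#' independent of corpus traversal. \code{<PAD>} and \code{<UNK>} are always
#' present.
#'
#' @param corpus a list of sentences; each sentence either a string or a
#'   character vector of single characters
#' @param min_count minimum frequency (>= 1)
#' @return a \code{char_vocab}
#' @examples
#' v <- build_vocab(list("aab"), min_count = 1)
#' v$tokens  # "<PAD>" "<UNK>" "a" "b"
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  stopifnot(min_count >= 1L)
  chars <- unlist(lapply(corpus, split_chars), use.names = FALSE)
  if (length(chars) == 0L) {
    return(new_char_vocab(c("<PAD>", "<UNK>")))
  }
  tab <- table(chars)
  keep <- tab[tab >= min_count]
  cp <- vapply(names(keep), function(ch) utf8ToInt(ch), integer(1))
  ord <- order(-as.integer(keep), cp)
  new_char_vocab(c("<PAD>", "<UNK>", names(keep)[ord]))
}

#' Map characters to vocabulary indices
#'
#' Out-of-vocabulary characters map to \code{<UNK>} (index 2).
#'
#' @param chars character vector of single characters (or one string)
#' @param vocab a \code{char_vocab}
#' @return integer vector of indices
#' @export
vocab_lookup <- function(chars, vocab) {
  chars <- split_chars(chars)
  idx <- unname(vocab$index[chars])
  idx[is.na(idx)] <- 2L
  as.integer(idx)
}

#' Embed a character sequence
#'
#' Looks up each character's row in an embedding matrix; OOV characters take
#' the \code{<UNK>} row. Total on valid inputs: an empty sentence yields a
#' 0 x d matrix.
#'
#' @param sentence string or character vector of single characters
#' @param vocab a \code{char_vocab}
#' @param matrix numeric matrix with \code{length(vocab$tokens)} rows
#' @return an n x d numeric matrix, n = number of characters
#' @export
embed_sequence <- function(sentence, vocab, matrix) {
  if (nrow(matrix) != length(vocab$tokens)) {
    stop("embedding matrix has ", nrow(matrix), " rows but vocabulary has ",
         length(vocab$tokens), " tokens")
  }
  idx <- vocab_lookup(sentence, vocab)
  matrix[idx, , drop = FALSE]
}

# Split a sentence into single characters; pass character vectors through.
split_chars <- function(x) {
  if (length(x) == 1L && nchar(x) != 1L) {
    return(strsplit(x, "", fixed = FALSE)[[1L]])
  }
  if (length(x) > 1L || (length(x) == 1L && nchar(x) == 1L)) {
    return(as.character(x))
  }
  character()
}
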
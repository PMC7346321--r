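#' Minimal text normalizer
#'
#' The documented cleaning rules, nothing more: unicode NFC normalization,
#' control-character removal, whitespace-run collapse, and replacement of
#' configured missing-value markers by a single \code{MISSING} token.
#'
#' @param raw input string
#' @param missing_markers character vector of markers (matched as whole
#'   tokens between word boundaries) to replace
#' @param missing_token replacement token
#' @return normalized string (empty in, empty out)
#' @export
normalize_document <- function(raw,
                               missing_markers = c("NA", "N/A", "?"),
                               missing_token = "␀") {
  if (length(raw) != 1L) stop("normalize one document at a time")
  if (is.na(raw) || raw == "") return("")
  x <- enc2utf8(raw)
  x <- stringi_nfc(x)
  x <- gsub("[[:space:]]+", " ", x, perl = TRUE)  # runs (incl. \t, \n) -> " "
  x <- gsub("[[:cntrl:]]", "", x, perl = TRUE)
  for (mk in missing_markers) {
    pat <- paste0("(?<![[:alnum:]])", escape_regex(mk), "(?![[:alnum:]])")
    x <- gsub(pat, missing_token, x, perl = TRUE)
  }
  trimws(x)
}

# NFC normalization via base R iconv when available; identity fallback.
stringi_nfc <- function(x) {
  y <- tryCatch(iconv(x, from = "UTF-8", to = "UTF-8"),
                error = function(e) x)
  if (is.na(y)) x else y
}

escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

#' Pack mentions into fixed-width classifier units
#'
#' The classifier consumes one 7-cell unit per extracted mention: the first
#' up to 6 surface characters (padded with \code{<PAD>}), then one label
#' token of the form \code{"B-<code>"} carrying the risk-factor type and
#' temporal attribute. The unit width makes a region size of 7 cover
#' exactly one (mention, label) unit and 14 cover two.
#'
#' @param mentions list of [risk_factor_mention()], ordered by start offset
#' @param unit_vocab a \code{unit_vocab} from [build_unit_vocab()]
#' @param cell_width unit width (default 7: 6 characters + 1 label)
#' @return integer vector of token indices, length
#'   \code{cell_width * length(mentions)}
#' @export
mentions_to_units <- function(mentions, unit_vocab, cell_width = 7L) {
  surf_width <- cell_width - 1L
  out <- integer(0)
  for (m in mentions) {
    chars <- split_chars(m$surface)
    chars <- chars[seq_len(min(length(chars), surf_width))]
    idx <- unname(unit_vocab$index[chars])
    idx[is.na(idx)] <- 2L  # <UNK>
    cell <- c(idx, rep(1L, surf_width - length(idx)))  # <PAD>
    lbl <- unit_vocab$index[paste0("B-", m$type, m$temporal)]
    if (is.na(lbl)) lbl <- 2L  # unknown mention type -> <UNK>, never a crash
    out <- c(out, cell, unname(lbl))
  }
  as.integer(out)
}

#' Build the unit-token vocabulary
#'
#' The classifier's token inventory: \code{<PAD>}, \code{<UNK>}, every
#' character occurring in the supplied texts, and one label token
#' \code{"B-<code>"} per composite entity code.
#'
#' @param texts character vector (or list) of surface texts
#' @param scheme a [tag_scheme()]
#' @return object of class \code{unit_vocab} (same structure as a
#'   \code{char_vocab}, with label tokens appended)
#' @export
build_unit_vocab <- function(texts, scheme = tag_scheme()) {
  base <- build_vocab(as.list(texts))
  tokens <- c(base$tokens, paste0("B-", scheme$codes))
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = c("unit_vocab", "char_vocab"))
}

#' Entity-level precision, recall and F-score
#'
#' Exact-match criterion, micro-averaged over documents: a predicted
#' mention counts as correct iff its span, risk-factor type and temporal
#' attribute all equal a gold mention of the same document.
#'
#' @param gold list (one element per document) of gold mention lists
#' @param pred list of predicted mention lists, aligned with \code{gold}
#' @return list with \code{precision}, \code{recall}, \code{fscore},
#'   \code{tp}, \code{n_gold}, \code{n_pred}
#' @export
entity_prf <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred must align document by document")
  }
  key <- function(m) paste(m$type, m$temporal, m$start, m$end, sep = "|")
  tp <- 0L
  n_gold <- 0L
  n_pred <- 0L
  for (i in seq_along(gold)) {
    gk <- vapply(gold[[i]], key, character(1))
    if (anyDuplicated(gk)) stop("duplicate gold span in document ", i)
    pk <- vapply(pred[[i]], key, character(1))
    tp <- tp + sum(pk %in% gk)
    n_gold <- n_gold + length(gk)
    n_pred <- n_pred + length(pk)
  }
  p <- if (n_pred > 0L) tp / n_pred else 0
  r <- if (n_gold > 0L) tp / n_gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, fscore = f,
       tp = tp, n_gold = n_gold, n_pred = n_pred)
}

#' Binary classification metrics
#'
#' Accuracy over all documents; precision, recall and F-score on the
#' positive (CVD) class, with the macro average alongside.
#'
#' @param gold integer vector of gold labels in \{0, 1\}
#' @param pred integer vector of predicted labels, same length
#' @return list with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{fscore} (positive class) and \code{macro_fscore}
#' @export
classification_metrics <- function(gold, pred) {
  if (length(gold) != length(pred)) stop("gold and pred lengths differ")
  gold <- as.integer(gold)
  pred <- as.integer(pred)
  stopifnot(all(gold %in% 0:1), all(pred %in% 0:1))
  acc <- mean(gold == pred)
  prf <- function(pos) {
    tp <- sum(gold == pos & pred == pos)
    p <- if (sum(pred == pos) > 0L) tp / sum(pred == pos) else 0
    r <- if (sum(gold == pos) > 0L) tp / sum(gold == pos) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f)
  }
  pos <- prf(1L)
  neg <- prf(0L)
  list(accuracy = acc, precision = unname(pos["p"]),
       recall = unname(pos["r"]), fscore = unname(pos["f"]),
       macro_fscore = unname((pos["f"] + neg["f"]) / 2))
}

#' End-to-end CVD prediction for one raw document
#'
#' Composition of the full pipeline: normalize the text, extract
#' risk-factor mentions with the BiLSTM-CRF labeler, pack them into
#' 7-cell units, and classify with the pyramid CNN. A document from which
#' no mention is extracted is assigned label 0 with a \code{no_evidence}
#' flag (there is nothing for the classifier to read).
#'
#' @param raw raw document text
#' @param labeler a trained \code{emrisk_labeler}
#' @param classifier a trained \code{endcnn_model}
#' @return list with \code{label} (0/1), \code{prob} (length-2 vector:
#'   no-CVD, CVD), \code{mentions}, \code{no_evidence}
#' @export
predict_cvd <- function(raw, labeler, classifier) {
  text <- normalize_document(raw)
  mentions <- extract_mentions(labeler, text)
  if (length(mentions) == 0L) {
    return(list(label = 0L, prob = c(1, 0), mentions = list(),
                no_evidence = TRUE))
  }
  units <- mentions_to_units(mentions, classifier$unit_vocab)
  prob <- endcnn_forward(units, classifier)
  list(label = as.integer(prob[2L] > 0.5), prob = prob,
       mentions = mentions, no_evidence = FALSE)
}
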
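#' Annotated sentence
#'
#' A sentence as the labeler sees it: a sequence of unicode characters and a
#' parallel sequence of BIO tags.
#'
#' @param chars character vector of single characters
#' @param tags character vector of tag strings, same length
#' @param scheme tag scheme used for validation, or NULL to skip
#' @return object of class \code{annotated_sentence}
#' @export
annotated_sentence <- function(chars, tags, scheme = NULL) {
  chars <- as.character(chars)
  tags <- as.character(tags)
  if (length(chars) != length(tags)) {
    stop("chars and tags must have equal length (",
         length(chars), " vs ", length(tags), ")")
  }
  if (any(nchar(chars) != 1L)) {
    stop("every element of chars must be a single character")
  }
  if (!is.null(scheme)) validate_tags(tags, scheme)
  structure(list(chars = chars, tags = tags), class = "annotated_sentence")
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("<annotated_sentence> ", paste(x$chars, collapse = ""), "\n", sep = "")
  ent <- sum(startsWith(x$tags, "B-"))
  cat("  length ", length(x$chars), ", ", ent, " entity span(s)\n", sep = "")
  invisible(x)
}

#' Read a character-level annotated corpus
#'
#' CoNLL-style two-column format: one \code{char<TAB>tag} per line, UTF-8,
#' blank line between sentences. Characters are preserved exactly.
#'
#' @param path path to the corpus file
#' @param scheme tag scheme for validation; NULL accepts any
#'   syntactically well-formed tag column
#' @return list of [annotated_sentence()] in file order
#' @export
read_annotated_corpus <- function(path, scheme = tag_scheme()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  chars <- character()
  tags <- character()
  flush <- function() {
    if (length(chars) > 0L) {
      sentences[[length(sentences) + 1L]] <<-
        annotated_sentence(chars, tags, scheme)
      chars <<- character()
      tags <<- character()
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "") {
      flush()
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || nchar(parts[[1L]]) != 1L) {
      stop("malformed corpus line ", i, " in ", path, ": ",
           deparse(ln))
    }
    chars <- c(chars, parts[[1L]])
    tags <- c(tags, parts[[2L]])
  }
  flush()
  sentences
}

#' Write a character-level annotated corpus
#'
#' Inverse of [read_annotated_corpus()]. Characters that would corrupt the
#' two-column format (tab, newline, carriage return) are rejected with an
#' error rather than escaped.
#'
#' @param sentences list of [annotated_sentence()]
#' @param path output path (UTF-8, no BOM)
#' @return invisibly \code{path}
#' @export
write_annotated_corpus <- function(sentences, path) {
  out <- character()
  for (s in sentences) {
    if (any(s$chars %in% c("\t", "\n", "\r"))) {
      stop("sentence contains a tab/newline character; ",
           "not representable in the two-column format")
    }
    out <- c(out, paste0(s$chars, "\t", s$tags), "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(out) > 0L) {
    writeLines(out, con, useBytes = FALSE)
  }
  invisible(path)
}

#' Labeled document
#'
#' A free-text record with a binary CVD label (1 = CVD) and, optionally,
#' gold risk-factor mentions.
#'
#' @param text unicode string
#' @param label 0 or 1
#' @param mentions optional list of [risk_factor_mention()]
#' @return object of class \code{labeled_document}
#' @export
labeled_document <- function(text, label, mentions = NULL) {
  if (length(label) != 1L || !label %in% c(0, 1)) {
    stop("label must be a single value in {0, 1}, got ", deparse(label))
  }
  structure(list(text = text, label = as.integer(label),
                 mentions = mentions),
            class = "labeled_document")
}

#' @export
print.labeled_document <- function(x, ...) {
  cat("<labeled_document> label=", x$label, ", ", nchar(x$text),
      " chars, ", length(x$mentions), " gold mention(s)\n", sep = "")
  invisible(x)
}

#' Read labeled documents (JSON lines)
#'
#' One JSON object per line with fields \code{text} and \code{label};
#' optional field \code{mentions} (array of objects with \code{type},
#' \code{temporal}, \code{start}, \code{end}, \code{surface}).
#'
#' @param path path to a JSON-lines file
#' @return list of [labeled_document()] in file order
#' @export
read_documents <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[lines != ""]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) {
                      stop("malformed JSON on line ", i, " of ", path, ": ",
                           conditionMessage(e))
                    })
    if (is.null(rec$text) || is.null(rec$label)) {
      stop("line ", i, " of ", path, ": missing field 'text' or 'label'")
    }
    if (!rec$label %in% c(0, 1)) {
      stop("line ", i, " of ", path, ": label must be 0 or 1, got ",
           deparse(rec$label))
    }
    mentions <- NULL
    if (!is.null(rec$mentions)) {
      mentions <- lapply(rec$mentions, function(m) {
        risk_factor_mention(m$type, m$temporal, m$start, m$end, m$surface)
      })
    }
    labeled_document(rec$text, rec$label, mentions)
  })
}

#' Write labeled documents (JSON lines)
#'
#' @param docs list of [labeled_document()]
#' @param path output path
#' @return invisibly \code{path}
#' @export
write_documents <- function(docs, path) {
  out <- vapply(docs, function(d) {
    rec <- list(text = d$text, label = d$label)
    if (!is.null(d$mentions)) {
      rec$mentions <- lapply(d$mentions, function(m) {
        list(type = m$type, temporal = m$temporal,
             start = m$start, end = m$end, surface = m$surface)
      })
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(out) > 0L) writeLines(out, con)
  invisible(path)
}

#' Read embeddings in word2vec text format
#'
#' Dialect: an optional header line \code{"<count> <dim>"}, then one
#' \code{"token v1 ... vd"} per line. The dimension is inferred from the
#' first data row when the header is absent. Duplicate tokens are an error.
#'
#' @param path path to the embeddings file
#' @return list with \code{tokens} (character) and \code{matrix}
#'   (numeric, one row per token, rownames = tokens)
#' @export
read_embeddings_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0L) {
    return(list(tokens = character(),
                matrix = matrix(numeric(), nrow = 0, ncol = 0)))
  }
  first <- strsplit(lines[[1L]], " ", fixed = TRUE)[[1L]]
  start <- 1L
  dim_declared <- NA_integer_
  if (length(first) == 2L &&
      !anyNA(suppressWarnings(as.integer(first)))) {
    dim_declared <- as.integer(first[[2L]])
    start <- 2L
  }
  rows <- lines[seq.int(start, length(lines))]
  tokens <- character(length(rows))
  vecs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    parts <- strsplit(rows[[i]], " ", fixed = TRUE)[[1L]]
    parts <- parts[parts != ""]
    tokens[[i]] <- parts[[1L]]
    v <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(v)) {
      stop("non-numeric vector entry for token ", deparse(tokens[[i]]))
    }
    vecs[[i]] <- v
  }
  d <- if (!is.na(dim_declared)) dim_declared else length(vecs[[1L]])
  lens <- lengths(vecs)
  if (any(lens != d)) {
    stop("inconsistent embedding dimension: expected ", d, ", found ",
         paste(unique(lens[lens != d]), collapse = ", "))
  }
  dup <- tokens[duplicated(tokens)]
  if (length(dup) > 0L) {
    stop("duplicate token in embeddings file: ",
         paste(unique(dup), collapse = ", "))
  }
  mat <- do.call(rbind, vecs)
  rownames(mat) <- tokens
  list(tokens = tokens, matrix = mat)
}

#' Write embeddings in word2vec text format (with header)
#'
#' @param tokens character vector
#' @param matrix numeric matrix, one row per token
#' @param path output path
#' @return invisibly \code{path}
#' @export
write_embeddings_text <- function(tokens, matrix, path) {
  stopifnot(length(tokens) == nrow(matrix))
  if (any(grepl("[[:space:]]", tokens))) {
    stop("tokens containing whitespace cannot be represented ",
         "in the word2vec text format")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(length(tokens), ncol(matrix)), con)
  for (i in seq_along(tokens)) {
    writeLines(paste(tokens[[i]],
                     paste(formatC(matrix[i, ], format = "g", digits = 17),
                           collapse = " ")), con)
  }
  invisible(path)
}
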
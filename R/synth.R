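#' Synthetic EMR generator configuration
#'
#' Defines the generative model standing in for private clinical corpora:
#' filler characters interleaved with planted risk-factor mentions that
#' carry BIO tags with temporal attributes, plus a document-level CVD label
#' produced by a known planted rule. The text is an abstract alphabet, not
#' imitation clinical prose: filler characters are lowercase letters,
#' mention surfaces are fixed uppercase lexicon strings, and each surface
#' ends in a single temporal-marker character (one fixed marker per
#' temporal code, inside the tagged span) so the temporal attribute is
#' recoverable from the characters alone.
#'
#' @param n_docs number of documents
#' @param filler_alphabet_size number of distinct filler characters (<= 26)
#' @param filler_p geometric parameter for filler-run lengths (runs are
#'   1 + Geom(filler_p) characters)
#' @param lambda_mentions Poisson mean of mentions per document
#' @param lexicon named list: risk-factor code -> character vector of 2-4
#'   surface strings (marker excluded); defaults to [default_lexicon()]
#' @param temporal_probs sampling weights for C, D, A, B on temporal types
#' @param theta planted-rule threshold (distinct active types needed for a
#'   positive label)
#' @param active_set temporal codes counting as active
#' @param prevalence target fraction of CVD-positive documents
#' @param seed RNG seed; a fixed seed reproduces the corpus bit for bit
#' @return list of class \code{synth_config}
#' @export
synth_config <- function(n_docs = 659L, filler_alphabet_size = 20L,
                         filler_p = 0.3, lambda_mentions = 5,
                         lexicon = default_lexicon(),
                         temporal_probs = c(C = 0.35, D = 0.25,
                                            A = 0.2, B = 0.2),
                         theta = 3L, active_set = c("C", "D"),
                         prevalence = 0.8, seed = 13L) {
  stopifnot(filler_p > 0, filler_p < 1, lambda_mentions > 0, theta >= 1L,
            prevalence > 0, prevalence < 1,
            filler_alphabet_size >= 1L, filler_alphabet_size <= 26L)
  if (any(lengths(lexicon) == 0L)) {
    stop("empty lexicon for type(s): ",
         paste(names(lexicon)[lengths(lexicon) == 0L], collapse = ", "))
  }
  structure(list(n_docs = as.integer(n_docs),
                 filler_alphabet = letters[seq_len(filler_alphabet_size)],
                 filler_p = filler_p,
                 lambda_mentions = lambda_mentions,
                 lexicon = lexicon,
                 temporal_probs = temporal_probs,
                 theta = as.integer(theta),
                 active_set = active_set,
                 prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Temporal marker characters used by the generator
#'
#' @return named character vector: temporal code -> marker character
#' @export
temporal_markers <- function() {
  c(C = "+", D = "*", A = ">", B = "<", N = "#")
}

#' Default risk-factor surface lexicon
#'
#' Each of the 12 risk-factor types gets three fixed surface strings (2-4
#' characters, before the temporal marker) built from a dedicated pair of
#' uppercase letters, so surfaces never collide across types and a packed
#' 7-cell unit (6 characters + label) never truncates a surface.
#'
#' @param scheme a [tag_scheme()]
#' @return named list: risk-factor code -> character vector of surfaces
#' @export
default_lexicon <- function(scheme = tag_scheme()) {
  types <- names(scheme$risk_factors)
  lex <- lapply(seq_along(types), function(i) {
    a <- LETTERS[2L * i - 1L]
    b <- LETTERS[2L * i]
    c(paste0(a, b), paste0(a, b, a), paste0(b, a, b, a))
  })
  names(lex) <- types
  lex
}

#' Risk-factor dictionary of a lexicon
#'
#' All mention surfaces the generator can plant, with their temporal
#' markers appended — the synthetic analogue of a clinical risk-factor
#' dictionary, used to augment skip-gram embedding training
#' ([train_char_embeddings()]) so the characters of each risk factor
#' co-occur tightly.
#'
#' @param lexicon named list: risk-factor code -> surfaces (marker-free)
#' @param scheme a [tag_scheme()]
#' @return character vector of surface strings including markers
#' @export
risk_factor_dictionary <- function(lexicon = default_lexicon(),
                                   scheme = tag_scheme()) {
  markers <- temporal_markers()
  unlist(lapply(names(lexicon), function(ty) {
    tms <- if (ty %in% scheme$atemporal) "N" else c("C", "D", "A", "B")
    as.vector(outer(lexicon[[ty]], markers[tms], paste0))
  }), use.names = FALSE)
}

#' The planted document-label rule
#'
#' A document is CVD-positive (1) iff the number of DISTINCT risk-factor
#' types occurring with a temporal attribute in the active set reaches the
#' threshold. Repeated mentions of one type count once.
#'
#' @param mentions list of [risk_factor_mention()]
#' @param theta threshold on distinct active types
#' @param active_set temporal codes counting as active
#' @return 0 or 1
#' @export
planted_rule <- function(mentions, theta = 3L, active_set = c("C", "D")) {
  if (length(mentions) == 0L) return(0L)
  act <- vapply(mentions, function(m) m$temporal %in% active_set, logical(1))
  types <- unique(vapply(mentions[act], `[[`, character(1), "type"))
  as.integer(length(types) >= theta)
}

#' Generate one synthetic EMR document
#'
#' Draws a Poisson number of mentions, samples their types, temporal
#' attributes and lexicon surfaces, and interleaves them with geometric
#' runs of filler characters. The BIO tags exactly cover the mention spans
#' (marker included); Age/Gender mentions are always temporal N. If
#' \code{target_label} is given, documents are redrawn until the planted
#' rule yields that label (bounded rejection).
#'
#' @param config a [synth_config()]
#' @param target_label NULL, 0 or 1
#' @param scheme a [tag_scheme()]
#' @param max_tries rejection-sampling cap
#' @return list with \code{sentence} ([annotated_sentence()]),
#'   \code{mentions}, and \code{document} ([labeled_document()])
#' @export
generate_document <- function(config, target_label = NULL,
                              scheme = tag_scheme(), max_tries = 10000L) {
  markers <- temporal_markers()
  for (try in seq_len(max_tries)) {
    n_m <- stats::rpois(1L, config$lambda_mentions)
    specs <- vector("list", n_m)
    if (n_m > 0L) {
      for (i in seq_len(n_m)) {
        type <- sample(names(config$lexicon), 1L)
        temporal <- if (type %in% scheme$atemporal) "N" else
          sample(names(config$temporal_probs), 1L,
                 prob = config$temporal_probs)
        base <- sample(config$lexicon[[type]], 1L)
        specs[[i]] <- list(type = type, temporal = temporal,
                           surface = paste0(base, markers[[temporal]]))
      }
    }
    label <- planted_rule(
      lapply(specs, function(s)
        risk_factor_mention(s$type, s$temporal, 0L, 1L, s$surface)),
      config$theta, config$active_set)
    if (!is.null(target_label) && label != target_label) next

    chars <- character()
    mentions <- list()
    filler_run <- function() {
      len <- 1L + stats::rgeom(1L, config$filler_p)
      sample(config$filler_alphabet, len, replace = TRUE)
    }
    chars <- c(chars, filler_run())
    for (s in specs) {
      start <- length(chars)
      schars <- strsplit(s$surface, "")[[1L]]
      chars <- c(chars, schars)
      mentions[[length(mentions) + 1L]] <- risk_factor_mention(
        s$type, s$temporal, start, start + length(schars), s$surface)
      chars <- c(chars, filler_run())
    }
    tags <- mentions_to_tags(mentions, length(chars), scheme)
    return(list(
      sentence = annotated_sentence(chars, tags, scheme),
      mentions = mentions,
      document = labeled_document(paste(chars, collapse = ""), label,
                                  mentions)
    ))
  }
  stop("rejection sampling failed to produce a document with label ",
       target_label, " after ", max_tries, " tries; ",
       "the prevalence/theta combination is infeasible")
}

#' Generate a full synthetic corpus with train/dev/test splits
#'
#' Per-document target labels are drawn Bernoulli(prevalence) and enforced
#' by bounded rejection, so the realized prevalence concentrates on the
#' target. The split ratios default to 461/66/132 of 659 (train/dev/test),
#' applied proportionally to \code{n_docs}.
#'
#' @param config a [synth_config()]
#' @param scheme a [tag_scheme()]
#' @return list of class \code{synth_corpus} with elements \code{train},
#'   \code{dev}, \code{test} (each: \code{sentences}, \code{documents},
#'   \code{mentions}), and \code{config}
#' @export
generate_corpus <- function(config = synth_config(), scheme = tag_scheme()) {
  n <- config$n_docs
  if (n < 10L) stop("need at least 10 documents")
  set.seed(config$seed)
  targets <- stats::rbinom(n, 1L, config$prevalence)
  docs <- lapply(seq_len(n), function(i) {
    generate_document(config, target_label = targets[[i]], scheme = scheme)
  })
  n_train <- round(n * 461 / 659)
  n_dev <- round(n * 66 / 659)
  n_test <- n - n_train - n_dev
  idx <- list(train = seq_len(n_train),
              dev = n_train + seq_len(n_dev),
              test = n_train + n_dev + seq_len(n_test))
  out <- lapply(idx, function(ii) {
    list(sentences = lapply(docs[ii], `[[`, "sentence"),
         documents = lapply(docs[ii], `[[`, "document"),
         mentions = lapply(docs[ii], `[[`, "mentions"))
  })
  out$config <- config
  structure(out, class = "synth_corpus")
}

#' @export
print.synth_corpus <- function(x, ...) {
  sizes <- vapply(x[c("train", "dev", "test")],
                  function(s) length(s$documents), integer(1))
  prev <- mean(vapply(c(x$train$documents, x$dev$documents,
                        x$test$documents),
                      `[[`, integer(1), "label"))
  cat("<synth_corpus> train/dev/test =", paste(sizes, collapse = "/"),
      " prevalence =", round(prev, 3), "\n")
  invisible(x)
}
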
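#' BIO tag scheme for CVD risk factors with temporal attributes
#'
#' Builds the tag inventory used throughout the package. Entities are the
#' twelve CVD risk factors; each mention additionally carries a temporal
#' attribute saying when the factor holds relative to the record: Continue
#' (C), During (D), After (A), Before (B). Age and Gender carry no temporal
#' information and always combine with the added attribute None (N). A
#' composite entity code is the risk-factor code followed by the temporal
#' code (e.g. \code{"HyC"} = Hypertension, Continue), and the per-character
#' tag vocabulary is \code{"O"} plus \code{"B-<code>"} / \code{"I-<code>"}
#' for every composite code.
#'
#' With the default inventory there are 10 x 4 + 2 = 42 composite codes and
#' 85 tags.
#'
#' @return An object of class \code{tag_scheme}: a list with
#'   \item{risk_factors}{named character vector, code -> full name}
#'   \item{temporal}{named character vector, code -> full name}
#'   \item{codes}{all composite entity codes}
#'   \item{tags}{the full tag vocabulary, \code{"O"} first}
#'   \item{tag_index}{named integer vector mapping tag string -> index}
#' @examples
#' sch <- tag_scheme()
#' length(sch$tags)  # 85
#' @export
tag_scheme <- function() {
  risk_factors <- c(
    O2   = "Overweight/Obesity",
    Hy   = "Hypertension",
    Di   = "Diabetes",
    Dy   = "Dyslipidemia",
    CKD  = "Chronic Kidney Disease",
    At   = "Atherosis",
    OSAS = "Obstructive Sleep Apnea Syndrome",
    Sm   = "Smoking",
    A2   = "Alcohol Abuse",
    FH   = "Family History of CVD",
    Age  = "Age",
    Gen  = "Gender"
  )
  temporal <- c(C = "Continue", D = "During", A = "After", B = "Before",
                N = "None")
  # Age and Gender have no temporal attribute; they take None only.
  atemporal <- c("Age", "Gen")
  codes <- c(
    as.vector(t(outer(setdiff(names(risk_factors), atemporal),
                      c("C", "D", "A", "B"), paste0))),
    paste0(atemporal, "N")
  )
  tags <- c("O", paste0("B-", codes), paste0("I-", codes))
  structure(
    list(
      risk_factors = risk_factors,
      temporal = temporal,
      atemporal = atemporal,
      codes = codes,
      tags = tags,
      tag_index = stats::setNames(seq_along(tags), tags)
    ),
    class = "tag_scheme"
  )
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat("<tag_scheme>", length(x$risk_factors), "risk factors,",
      length(x$codes), "entity codes,", length(x$tags), "tags\n")
  invisible(x)
}

#' Split a composite entity code into risk-factor and temporal parts
#'
#' @param code composite code such as \code{"HyC"} or \code{"AgeN"}
#' @param scheme a [tag_scheme()]
#' @return list with elements \code{type} (risk-factor code) and
#'   \code{temporal} (one-letter temporal code)
#' @export
split_code <- function(code, scheme = tag_scheme()) {
  if (!code %in% scheme$codes) {
    stop("unknown entity code: ", code)
  }
  type <- substr(code, 1L, nchar(code) - 1L)
  temp <- substr(code, nchar(code), nchar(code))
  list(type = type, temporal = temp)
}

#' Validate a vector of tag strings against a scheme
#'
#' @param tags character vector of tag strings
#' @param scheme a [tag_scheme()]
#' @return invisibly TRUE; errors on the first unknown tag
#' @export
validate_tags <- function(tags, scheme = tag_scheme()) {
  bad <- setdiff(unique(tags), scheme$tags)
  if (length(bad) > 0L) {
    stop("unknown tag string(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
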
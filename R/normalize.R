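#' Assess the data characteristics that drive normalization choice
#'
#' Four screens are evaluated on the whole matrix: nonnegativity, a
#' significant proportion of zeros, discreteness (all finite entries
#' integral) and the presence of negative-infinite entries (log of zero,
#' indicating data already on the log scale).
#'
#' @param matrix An [expression_matrix()] or plain numeric matrix.
#' @param zero_threshold Zero fraction above which `high_zero_proportion`
#'   is set (default 0.05).
#' @return A list of class `m3s_characteristics` with fields `nonnegative`,
#'   `high_zero_proportion`, `discretized`, `has_negative_infinite` and
#'   `zero_fraction`.
#' @export
assess_characteristics <- function(matrix, zero_threshold = 0.05) {
  v <- as.numeric(unclass(matrix))
  if (length(v) == 0L) stop_m3s("invalid_data", "empty matrix")
  if (anyNA(v)) stop_m3s("invalid_data", "matrix contains NaN/NA entries")
  if (any(v == Inf)) stop_m3s("invalid_data", "matrix contains +Inf entries")
  fin <- v[is.finite(v)]
  zf <- mean(v == 0)
  structure(list(
    nonnegative = all(v >= 0),
    high_zero_proportion = zf > zero_threshold,
    discretized = all(fin == floor(fin)),
    has_negative_infinite = any(v == -Inf),
    zero_fraction = zf
  ), class = "m3s_characteristics")
}

#' Choose a normalization from the data characteristics
#'
#' Decision tree: integer counts with zeros get `log_cpm1p`, integer counts
#' without zeros `log_cpm`; positive reals with zeros `log1p`, without
#' zeros `log`; anything with negative or negative-infinite entries is
#' already transformed and passes through as `identity`.
#'
#' @param chars Output of [assess_characteristics()].
#' @return One of `"log"`, `"log1p"`, `"cpm"`, `"log_cpm"`, `"log_cpm1p"`,
#'   `"identity"`.
#' @export
select_normalization <- function(chars) {
  stopifnot(inherits(chars, "m3s_characteristics"))
  if (chars$has_negative_infinite || !chars$nonnegative) return("identity")
  if (chars$discretized) {
    if (chars$zero_fraction > 0) "log_cpm1p" else "log_cpm"
  } else {
    if (chars$zero_fraction > 0) "log1p" else "log"
  }
}

NORMALIZATIONS <- c("log", "log1p", "cpm", "log_cpm", "log_cpm1p", "identity")

#' Apply a normalization to an expression matrix
#'
#' CPM scales each column (sample) to a library size of 1e6; logs are
#' natural. Columns with zero library size cannot be CPM-scaled: they are
#' left all-zero and recorded in the `zero_library` attribute.
#'
#' @param matrix An [expression_matrix()] or plain numeric matrix.
#' @param choice One of the transforms listed in [select_normalization()].
#' @return The transformed matrix with attribute `transform` set.
#' @export
apply_normalization <- function(matrix, choice) {
  choice <- match.arg(choice, NORMALIZATIONS)
  m <- matrix
  cpm <- function(m) {
    cs <- colSums(m)
    zero_lib <- cs == 0
    cs[zero_lib] <- 1
    out <- sweep(m, 2L, cs / 1e6, "/")
    attr(out, "zero_library") <- which(zero_lib)
    out
  }
  out <- switch(choice,
    identity = m,
    log = {
      if (any(m <= 0)) stop_m3s("invalid_transform",
                                "log requires strictly positive entries")
      log(m)
    },
    log1p = {
      if (any(m < 0)) stop_m3s("invalid_transform",
                               "log1p requires nonnegative entries")
      log1p(m)
    },
    cpm = cpm(m),
    log_cpm = {
      cm <- cpm(m)
      if (any(cm <= 0)) stop_m3s("invalid_transform",
                                 "log_cpm requires strictly positive entries")
      structure(log(cm), zero_library = attr(cm, "zero_library"))
    },
    log_cpm1p = {
      cm <- cpm(m)
      structure(log1p(cm), zero_library = attr(cm, "zero_library"))
    }
  )
  attr(out, "transform") <- choice
  class(out) <- class(matrix)
  dimnames(out) <- dimnames(matrix)
  out
}
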
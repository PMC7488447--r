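#' Enumerate all joint association patterns for J studies
#'
#' Builds the K x J binary matrix of the K = 2^J possible joint association
#' patterns across `J` studies.  Entry `(k, j) = 1` means the SNP is
#' associated with trait `j` in pattern `k`.  Rows are in canonical order:
#' ascending number of associations, ties broken by descending binary value
#' with study 1 the most significant bit, so for J = 3 the order is
#' (000), (100), (010), (001), (110), (101), (011), (111).  Row 1 is always
#' the global null pattern and the last row the all-associated pattern.
#'
#' @param J Number of studies (1 to 15).  Beyond 15 studies the pattern space
#'   is too large to enumerate; group studies and combine group-level
#'   probabilities with [group_product()] instead.
#' @return Integer matrix with `2^J` rows and `J` columns; row names are the
#'   binary pattern labels (e.g. `"101"`).
#' @seealso [pattern_labels()], [group_product()]
#' @export
#' @examples
#' make_patterns(3)
make_patterns <- function(J) {
  if (length(J) != 1L || !is.finite(J) || J != round(J) || J < 1) {
    stop("`J` must be a single positive integer")
  }
  if (J > 15) {
    stop("J > 15 enumerates more than 32768 patterns; ",
         "split the studies into groups and use group_product()")
  }
  J <- as.integer(J)
  K <- 2L^J
  # bit j of k-1, with study 1 as the most significant bit
  Q <- matrix(0L, nrow = K, ncol = J)
  for (j in seq_len(J)) {
    Q[, j] <- as.integer(bitwAnd(seq_len(K) - 1L, bitwShiftL(1L, J - j)) > 0L)
  }
  val <- as.integer(Q %*% 2L^((J - 1L):0L))
  ord <- order(rowSums(Q), -val)
  Q <- Q[ord, , drop = FALSE]
  rownames(Q) <- pattern_labels(Q)
  Q
}

#' Binary string labels for pattern matrix rows
#'
#' @param Q A binary pattern matrix as returned by [make_patterns()].
#' @return Character vector of row labels such as `"010"`.
#' @export
pattern_labels <- function(Q) {
  apply(Q, 1L, paste0, collapse = "")
}

#' Resolve a pattern-group specification to row indices of Q
#'
#' Pattern groups collapse mutually exclusive association patterns into an
#' interpretable set (e.g. "associated with the complex trait and at least
#' one omics trait").  A group may be given as
#' * a vector of row indices into `Q`,
#' * a character vector of binary pattern strings (`c("110", "111")`), or
#' * the shorthand string `"trait+>=k_omics"` meaning patterns with
#'   `q[1] == 1` and at least `k` of the remaining studies associated.
#'
#' @param Q Binary pattern matrix.
#' @param group Group specification (see Details).
#' @return Sorted integer vector of pattern (row) indices.
#' @export
#' @examples
#' Q <- make_patterns(4)
#' parse_pattern_group(Q, "trait+>=1_omics")
parse_pattern_group <- function(Q, group) {
  K <- nrow(Q)
  if (is.numeric(group)) {
    idx <- as.integer(group)
    if (anyDuplicated(idx) || any(idx < 1L | idx > K)) {
      stop("pattern indices must be distinct values in 1..K")
    }
    return(sort(idx))
  }
  if (is.character(group) && length(group) == 1L &&
      grepl("^trait\\+>=[0-9]+_?omics$", group)) {
    k <- as.integer(sub("^trait\\+>=([0-9]+)_?omics$", "\\1", group))
    idx <- which(Q[, 1L] == 1L & rowSums(Q[, -1L, drop = FALSE]) >= k)
    if (length(idx) == 0L) stop("no pattern matches the group shorthand")
    return(sort(idx))
  }
  if (is.character(group)) {
    labs <- pattern_labels(Q)
    idx <- match(group, labs)
    if (anyNA(idx)) {
      stop("unknown pattern label(s): ", paste(group[is.na(idx)], collapse = ", "))
    }
    if (anyDuplicated(idx)) stop("pattern labels must be distinct")
    return(sort(idx))
  }
  stop("`group` must be numeric indices, binary labels, or a shorthand string")
}
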
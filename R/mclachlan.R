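# McLachlan (1972) amino-acid similarity matrix, 0-9 integer scale.
# Row/column order as published: ARNDCQEGHILKMFPSTWYV.
.MCLACHLAN_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.MCLACHLAN <- matrix(c(
  8, 2, 3, 3, 1, 3, 4, 3, 3, 2, 2, 3, 3, 1, 4, 4, 3, 1, 1, 3,
  2, 8, 3, 1, 1, 5, 3, 3, 5, 1, 2, 5, 1, 1, 3, 4, 3, 3, 2, 2,
  3, 3, 8, 5, 1, 4, 4, 3, 4, 1, 1, 4, 2, 0, 1, 5, 3, 0, 2, 1,
  3, 1, 5, 8, 1, 4, 5, 3, 4, 1, 1, 3, 2, 1, 3, 3, 3, 0, 1, 1,
  1, 1, 1, 1, 9, 0, 0, 1, 3, 1, 0, 0, 3, 0, 0, 2, 2, 2, 1, 1,
  3, 5, 4, 4, 0, 8, 5, 2, 4, 0, 3, 4, 3, 0, 3, 4, 3, 2, 1, 2,
  4, 3, 4, 5, 0, 5, 8, 3, 2, 1, 1, 4, 1, 0, 4, 4, 4, 1, 2, 2,
  3, 3, 3, 3, 1, 2, 3, 8, 2, 1, 1, 3, 1, 0, 3, 3, 2, 1, 0, 2,
  3, 5, 4, 4, 3, 4, 2, 2, 8, 2, 2, 4, 3, 4, 3, 3, 4, 3, 4, 2,
  2, 1, 1, 1, 1, 0, 1, 1, 2, 8, 5, 1, 5, 3, 1, 2, 3, 3, 3, 5,
  2, 2, 1, 1, 0, 3, 1, 1, 2, 5, 8, 2, 6, 5, 1, 2, 3, 3, 3, 5,
  3, 5, 4, 3, 0, 4, 4, 3, 4, 1, 2, 8, 1, 0, 3, 3, 3, 1, 1, 2,
  3, 1, 2, 2, 3, 3, 1, 1, 3, 5, 6, 1, 8, 5, 1, 2, 3, 1, 2, 4,
  1, 1, 0, 1, 0, 0, 0, 0, 4, 3, 5, 0, 5, 9, 1, 2, 1, 6, 6, 3,
  4, 3, 1, 3, 0, 3, 4, 3, 3, 1, 1, 3, 1, 1, 8, 3, 3, 0, 0, 2,
  4, 4, 5, 3, 2, 4, 4, 3, 3, 2, 2, 3, 2, 2, 3, 8, 5, 3, 3, 2,
  3, 3, 3, 3, 2, 3, 4, 2, 4, 3, 3, 3, 3, 1, 3, 5, 8, 2, 1, 3,
  1, 3, 0, 0, 2, 2, 1, 1, 3, 3, 3, 1, 1, 6, 0, 3, 2, 9, 6, 2,
  1, 2, 2, 1, 1, 1, 2, 0, 4, 3, 3, 1, 2, 6, 0, 3, 1, 6, 9, 3,
  3, 2, 1, 1, 1, 2, 2, 2, 2, 5, 5, 2, 4, 3, 2, 2, 3, 2, 3, 8),
  nrow = 20L, byrow = TRUE,
  dimnames = list(.MCLACHLAN_AA, .MCLACHLAN_AA))

#' McLachlan (1972) amino-acid similarity
#'
#' The 20x20 integer similarity table of McLachlan (1972), on a 0-9 scale
#' (identities 8, except C/F/W/Y at 9). This is the substitution table
#' underlying the McBASC covariation statistic.
#'
#' @return \code{mclachlanMatrix()} returns the full symmetric matrix with
#'   amino-acid dimnames; \code{mclachlanSimilarity(a, b)} the single entry
#'   for residues \code{a}, \code{b} (vectorized).
#' @examples
#' mclachlanSimilarity("L", "M")  # 6
#' @export
mclachlanMatrix <- function() .MCLACHLAN

#' @rdname mclachlanMatrix
#' @param a,b one-letter amino-acid codes.
#' @export
mclachlanSimilarity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  bad <- unique(c(a[!(a %in% AA_STANDARD)], b[!(b %in% AA_STANDARD)]))
  if (length(bad))
    stop("non-standard residue letter(s): ", paste(bad, collapse = " "))
  unname(.MCLACHLAN[cbind(a, b)])
}
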
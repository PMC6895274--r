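#' Select the top-2L evolutionary couplings
#'
#' Ranks all eligible (retained, non-NA) column pairs by covariation score and
#' keeps the \code{budget = round(multiplier * L)} strongest, where \code{L}
#' is the query protein length; with the default multiplier of 2 this is the
#' length-dependent 2L coupling threshold. Ties at the cutoff are broken
#' deterministically by (score descending, i ascending, j ascending).
#'
#' @param cov a [CovariationMatrix-class].
#' @param L query protein length (defaults to the matrix dimension).
#' @param multiplier positive length multiplier (default 2).
#' @return a [CouplingSet-class] with the selected pairs and per-residue
#'   partner lists \code{C_i}.
#' @export
selectCouplings <- function(cov, L = nrow(covScores(cov)), multiplier = 2) {
  stopifnot(is(cov, "CovariationMatrix"))
  if (!is.numeric(multiplier) || multiplier <= 0)
    stop("multiplier must be positive")
  s <- cov@scores
  ut <- which(upper.tri(s) & !is.na(s), arr.ind = TRUE)
  if (nrow(ut) == 0L) stop("no eligible column pairs")
  df <- data.frame(i = ut[, 1L], j = ut[, 2L], score = s[ut])
  df <- df[order(-df$score, df$i, df$j), , drop = FALSE]
  budget <- as.integer(round(multiplier * L))
  sel <- df[seq_len(min(budget, nrow(df))), , drop = FALSE]
  rownames(sel) <- NULL
  partners <- vector("list", L)
  for (p in seq_len(L)) partners[[p]] <- integer(0)
  for (r in seq_len(nrow(sel))) {
    i <- sel$i[r]; j <- sel$j[r]
    partners[[i]] <- c(partners[[i]], j)
    partners[[j]] <- c(partners[[j]], i)
  }
  partners <- lapply(partners, sort)
  new("CouplingSet", pairs = sel, partners = partners,
      budget = budget, L = as.integer(L), multiplier = multiplier)
}

#' @describeIn selectCouplings the selected pairs as a data.frame
#'   (i, j, score), strongest first.
#' @param cs a \code{CouplingSet}.
#' @export
couplingPairs <- function(cs) {
  stopifnot(is(cs, "CouplingSet"))
  cs@pairs
}

#' @describeIn selectCouplings the coupled-partner positions \code{C_i} of
#'   residue \code{i}.
#' @param i query position.
#' @export
couplingPartners <- function(cs, i) {
  stopifnot(is(cs, "CouplingSet"))
  cs@partners[[i]]
}

#' @describeIn selectCouplings per-residue coupling counts \code{|C_i|}
#'   (integer vector of length L).
#' @export
couplingCounts <- function(cs) {
  stopifnot(is(cs, "CouplingSet"))
  lengths(cs@partners)
}

setMethod("show", "CouplingSet", function(object) {
  cat(sprintf(
    "CouplingSet: %d pairs selected (budget %d = %g x L, L = %d)\n",
    nrow(object@pairs), object@budget, object@multiplier, object@L))
})
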
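#' Describe a planted covarying column pair
#'
#' A planted pair couples two columns through a list of compatible joint
#' states: with probability \code{w} a sequence draws one of the compatible
#' (aa_i, aa_j) states jointly; otherwise the two residues are drawn
#' independently and uniformly from the letters occurring in the states.
#' \code{w = 0} therefore yields independent columns, \code{w = 1} perfect
#' compensation.
#'
#' @param i,j distinct column indices.
#' @param states list of length-2 character vectors \code{c(aa_i, aa_j)};
#'   default the classic compensatory toy states (A,K) / (S,E).
#' @param w mixing weight in [0, 1] (default 0.9).
#' @return a \code{plantedPair} list.
#' @export
plantedPair <- function(i, j, states = list(c("A", "K"), c("S", "E")),
                        w = 0.9) {
  stopifnot(i != j, w >= 0, w <= 1, length(states) >= 1L,
            all(vapply(states, length, 1L) == 2L))
  stopifnot(all(unlist(states) %in% AA_STANDARD))
  structure(list(i = as.integer(i), j = as.integer(j),
                 states = states, w = w), class = "plantedPair")
}

#' Describe a planted covarying column group (clique)
#'
#' Generalizes [plantedPair()] to a group of k columns that co-vary jointly:
#' with probability \code{w} a sequence draws one of the compatible joint
#' states (a k-tuple of residues) for the whole group; otherwise each column
#' draws independently from its own state letters. Every within-group column
#' pair covaries, so a group of size k gives each member residue k - 1
#' planted couplings — emulating the cooperative, highly coupled sites whose
#' coupling number the method is designed to detect.
#'
#' @param cols integer vector of at least 2 distinct column indices.
#' @param states list of character vectors, each of length
#'   \code{length(cols)}; default two complementary states over a rotating
#'   alphabet.
#' @param w mixing weight in [0, 1].
#' @return a \code{plantedClique} list.
#' @export
plantedClique <- function(cols, states = NULL, w = 0.9) {
  cols <- as.integer(cols)
  stopifnot(length(cols) >= 2L, !anyDuplicated(cols), w >= 0, w <= 1)
  if (is.null(states)) {
    k <- length(cols)
    states <- list(AA_STANDARD[((seq_len(k) - 1L) %% 10L) + 1L],
                   AA_STANDARD[((seq_len(k) - 1L) %% 10L) + 11L])
  }
  stopifnot(all(vapply(states, length, 1L) == length(cols)),
            all(unlist(states) %in% AA_STANDARD))
  structure(list(cols = cols, states = states, w = w),
            class = "plantedClique")
}

# Normalize a planted pair or clique to the clique representation.
.asClique <- function(p) {
  if (inherits(p, "plantedClique")) return(p)
  if (inherits(p, "plantedPair"))
    return(plantedClique(c(p$i, p$j),
                         states = lapply(p$states, identity), w = p$w))
  stop("planted elements must be plantedPair() or plantedClique() objects")
}

#' Generate a synthetic coevolving alignment
#'
#' Builds an alignment of \code{N} sequences over \code{L} columns with three
#' column categories: planted covarying pairs (joint compatible states mixed
#' with weight \code{w}), conserved columns (a dominant residue at a stated
#' frequency), and background columns (uniform over a 4-letter per-column
#' sub-alphabet, which keeps pair-count tables dense at small N). Gaps are
#' inserted independently per cell at \code{gapRate}, never in the query row;
#' the query (row 1, id \code{"query"}) is gap-free and drawn from the
#' compatible states. Fully deterministic for a fixed seed; the global RNG
#' state is left untouched.
#'
#' @param L number of columns (= query length).
#' @param N number of sequences (>= 2).
#' @param plantedPairs list of [plantedPair()] and/or [plantedClique()]
#'   objects with disjoint columns.
#' @param conserved list of \code{list(col, aa, freq)} conserved-column
#'   descriptors; columns must be disjoint from the planted ones.
#' @param gapRate per-cell gap probability in [0, 0.5] (default 0.05).
#' @param seed integer seed.
#' @return list with elements \code{alignment} (a [QueryAlignment-class]) and
#'   \code{truth} (planted pairs, per-column category, parameters).
#' @export
generateCoupledMsa <- function(L, N, plantedPairs = list(),
                               conserved = list(), gapRate = 0.05, seed) {
  stopifnot(L >= 1L, N >= 2L, gapRate >= 0, gapRate <= 0.5)
  cliques <- lapply(plantedPairs, .asClique)
  plantedCols <- unlist(lapply(cliques, `[[`, "cols"))
  consCols <- vapply(conserved, function(x) as.integer(x$col), integer(1L))
  allSpecial <- c(plantedCols, consCols)
  if (anyDuplicated(allSpecial))
    stop("planted and conserved columns must be disjoint")
  if (length(allSpecial) && (max(allSpecial) > L || min(allSpecial) < 1L))
    stop("column index outside 1..L")

  withr::with_seed(seed, {
    m <- matrix(NA_character_, nrow = N, ncol = L)
    category <- rep("background", L)

    for (p in cliques) {
      category[p$cols] <- "planted"
      k <- length(p$cols)
      stateMat <- do.call(rbind, p$states)  # states x columns
      # per-column letter pools for the independent (non-compensated) draws
      pools <- lapply(seq_len(k), function(ci) unique(stateMat[, ci]))
      # query draws a compatible joint state
      m[1L, p$cols] <- stateMat[sample.int(nrow(stateMat), 1L), ]
      joint <- stats::runif(N - 1L) < p$w
      stateIdx <- sample.int(nrow(stateMat), N - 1L, replace = TRUE)
      for (ci in seq_len(k)) {
        indep <- sample(pools[[ci]], N - 1L, replace = TRUE)
        m[-1L, p$cols[ci]] <- ifelse(joint, stateMat[stateIdx, ci], indep)
      }
    }
    for (cc in conserved) {
      stopifnot(cc$freq > 0, cc$freq <= 1, cc$aa %in% AA_STANDARD)
      category[cc$col] <- "conserved"
      alt <- sample(setdiff(AA_STANDARD, cc$aa), 3L)
      m[1L, cc$col] <- cc$aa
      dom <- stats::runif(N - 1L) < cc$freq
      m[-1L, cc$col] <- ifelse(dom, cc$aa, sample(alt, N - 1L, replace = TRUE))
    }
    for (col in which(category == "background")) {
      sub <- sample(AA_STANDARD, 4L)
      m[, col] <- sample(sub, N, replace = TRUE)
    }

    if (gapRate > 0 && N > 1L) {
      gapMask <- matrix(stats::runif((N - 1L) * L) < gapRate, N - 1L, L)
      body <- m[-1L, , drop = FALSE]
      body[gapMask] <- GAP_CHAR
      m[-1L, ] <- body
    }
    rownames(m) <- c("query", paste0("seq", seq_len(N - 1L) + 1L))
    aln <- new("QueryAlignment", seqMat = m, queryId = "query",
               sourceColumns = seq_len(L))
    # ground-truth pair list: every within-group column pair covaries
    truePairs <- do.call(c, lapply(cliques, function(p) {
      cp <- utils::combn(sort(p$cols), 2L)
      lapply(seq_len(ncol(cp)), function(ci)
        list(i = cp[1L, ci], j = cp[2L, ci], w = p$w))
    }))
    truth <- list(
      plantedPairs = truePairs,
      groups = cliques,
      category = category,
      params = list(L = L, N = N, gapRate = gapRate, seed = seed))
    list(alignment = aln, truth = truth)
  })
}

#' Random spec for the planted-pair recovery benchmark
#'
#' Places \code{nPlanted} covarying pairs (mixing weight \code{w}) and
#' \code{nConserved} conserved columns (dominant frequency 0.95) at random
#' disjoint positions, then generates the alignment. Convenience wrapper
#' around [generateCoupledMsa()] used by the validation suite.
#'
#' @inheritParams generateCoupledMsa
#' @param nPlanted number of planted pairs (default 3).
#' @param w mixing weight (default 0.9).
#' @param nConserved number of conserved columns (default 5).
#' @return as [generateCoupledMsa()].
#' @export
randomCoupledMsa <- function(L = 50, N = 200, nPlanted = 3, w = 0.9,
                             nConserved = 5, gapRate = 0.05, seed) {
  stopifnot(2L * nPlanted + nConserved <= L)
  layout <- withr::with_seed(seed, {
    cols <- sample.int(L, 2L * nPlanted + nConserved)
    statePool <- list(
      list(c("A", "K"), c("S", "E")),
      list(c("L", "F"), c("I", "W")),
      list(c("D", "R"), c("N", "H")),
      list(c("G", "T"), c("P", "Q")),
      list(c("V", "Y"), c("M", "C")))
    pairs <- lapply(seq_len(nPlanted), function(k)
      plantedPair(cols[2L * k - 1L], cols[2L * k],
                  states = statePool[[(k - 1L) %% length(statePool) + 1L]],
                  w = w))
    cons <- lapply(seq_len(nConserved), function(k)
      list(col = cols[2L * nPlanted + k],
           aa = sample(AA_STANDARD, 1L), freq = 0.95))
    list(pairs = pairs, cons = cons)
  })
  generateCoupledMsa(L = L, N = N, plantedPairs = layout$pairs,
                     conserved = layout$cons, gapRate = gapRate,
                     seed = seed + 1L)
}

#' Generate a labeled two-score variant dataset
#'
#' Gaussian benchmark set for the evaluation machinery: labels are balanced;
#' the informative score of positives is shifted by \code{effectSize} (in SD
#' units of the noise), and a second pure-noise score is included. The
#' expected AUC of the informative score is \code{pnorm(effectSize /
#' (sqrt(2) * noiseSd))} for unit-variance noise.
#'
#' @param n number of variants (>= 10; split half positive, half negative).
#' @param effectSize mean shift of the positives' informative score.
#' @param noiseSd standard deviation of both scores' noise (> 0).
#' @param seed integer seed.
#' @return data.frame with columns \code{label} (logical), \code{informative},
#'   \code{noise}.
#' @export
generateLabeledDataset <- function(n, effectSize, noiseSd = 1, seed) {
  stopifnot(n >= 10L, noiseSd > 0)
  withr::with_seed(seed, {
    label <- rep(c(TRUE, FALSE), length.out = n)
    informative <- stats::rnorm(n, mean = ifelse(label, effectSize, 0),
                                sd = noiseSd)
    noise <- stats::rnorm(n, mean = 0, sd = noiseSd)
    data.frame(label = label, informative = informative, noise = noise)
  })
}
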
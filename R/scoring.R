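# Base-pairing score.
#
# For each candidate pair (i, j) and each atom type a, up to seven geometry
# sub-terms are evaluated (three stacking-aware distances, two angles, two
# dihedrals).  Each sub-term contributes exp(-d^2 / (2 sigma^2)) against the
# calibrated (mean, sigma) for the pair's class, and the score is the
# equal-weight mean of all evaluable contributions, so it lies in [0, 1] and
# equals 1 at perfect agreement.  Sub-terms that cannot be computed because
# of missing atoms or absent neighbors are ignored (the denominator shrinks).

.KINDS <- c("dist0", "dist_up", "dist_down", "ang_i", "ang_j", "dih_i", "dih_j")
.DIST_KINDS <- c("dist0", "dist_up", "dist_down")

#' Geometry sub-term kinds
#'
#' The seven per-atom-type sub-terms: the pair distance (`dist0`), the two
#' stacking distances to sequence neighbors (`dist_up` = i+1 to j-1,
#' `dist_down` = i-1 to j+1), the two included angles with vertex at i and
#' at j, and the two dihedrals (i-side and j-side lead).
#'
#' @return Character vector of length 7.
#' @export
cssr_term_kinds <- function() .KINDS

#' Enumerate candidate nucleotide pairs
#'
#' All unordered pairs whose bases are compatible with canonical pairing
#' (Watson-Crick A:U / C:G, or wobble G:U), where both nucleotides retain at
#' least one recognized atom, and whose intra-chain sequence separation is at
#' least `min_separation`.  Inter-chain pairs are included only on request;
#' no separation constraint applies across chains.
#'
#' @param x An `rna_structure`.
#' @param min_separation Minimum |i - j| within a chain (default 4, the
#'   minimal hairpin-loop steric constraint).
#' @param inter_chain Include pairs between different chains?
#' @return Data frame with global 1-based columns `i`, `j` (i < j) and the
#'   pair `class` (`"WC"` or `"WOBBLE"`).
#' @export
candidate_pairs <- function(x, min_separation = 4L, inter_chain = FALSE) {
  idx <- structure_index(x)
  .candidate_pairs_idx(idx, min_separation, inter_chain)
}

.candidate_pairs_idx <- function(idx, min_separation = 4L,
                                 inter_chain = FALSE) {
  n <- idx$n
  empty <- data.frame(i = integer(), j = integer(), class = character())
  if (n < 2L) return(empty)
  ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  keep <- idx$has_atom[ii] & idx$has_atom[jj]
  same <- idx$chain[ii] == idx$chain[jj]
  keep <- keep & (!same | (jj - ii) >= min_separation)
  if (!inter_chain) keep <- keep & same
  ii <- ii[keep]; jj <- jj[keep]
  cls <- pair_class(idx$base[ii], idx$base[jj])
  ok <- !is.na(cls)
  data.frame(i = ii[ok], j = jj[ok], class = cls[ok],
             stringsAsFactors = FALSE)
}

# All seven sub-term values for one atom type over a vector of pairs.
# Returns an n_pairs x 7 matrix (NA where not evaluable).
.pair_terms <- function(idx, gi, gj, atom) {
  X <- idx$xyz[[atom]]
  na_row <- function(k) {
    out <- matrix(NA_real_, length(k), 3L)
    ok <- !is.na(k)
    out[ok, ] <- X[k[ok], , drop = FALSE]
    out
  }
  Ai <- na_row(gi)
  Aj <- na_row(gj)
  Ui <- na_row(idx$inext[gi])    # i + 1
  Dj <- na_row(idx$iprev[gj])    # j - 1
  Di <- na_row(idx$iprev[gi])    # i - 1
  Uj <- na_row(idx$inext[gj])    # j + 1
  cbind(dist0     = .row_dist(Ai, Aj),
        dist_up   = .row_dist(Ui, Dj),
        dist_down = .row_dist(Di, Uj),
        ang_i     = .row_angle(Ui, Ai, Aj),
        ang_j     = .row_angle(Dj, Aj, Ai),
        dih_i     = .row_dihedral(Ui, Ai, Aj, Dj),
        dih_j     = .row_dihedral(Uj, Aj, Ai, Di))
}

#' Raw geometry sub-term for one pair
#'
#' The concrete atom assignments, with `a_k` the coordinates of `atom` on
#' nucleotide k and neighbors taken along the chain: `dist0 = |a_i - a_j|`;
#' `dist_up = |a_(i+1) - a_(j-1)|`; `dist_down = |a_(i-1) - a_(j+1)|`;
#' `ang_i = angle(a_(i+1), a_i, a_j)`; `ang_j = angle(a_(j-1), a_j, a_i)`;
#' `dih_i = dihedral(a_(i+1), a_i, a_j, a_(j-1))`;
#' `dih_j = dihedral(a_(j+1), a_j, a_i, a_(i-1))`.
#'
#' @param x An `rna_structure`.
#' @param i,j Global 1-based nucleotide indices (i on the lower side).
#' @param atom One of [cssr_atom_types()].
#' @param kind One of [cssr_term_kinds()].
#' @return The value in Angstrom (distances) or degrees (angles/dihedrals),
#'   or `NA` when a required atom or neighbor is missing.
#' @export
term_value <- function(x, i, j, atom, kind) {
  atom <- match.arg(atom, .ATOMS)
  kind <- match.arg(kind, .KINDS)
  idx <- structure_index(x)
  m <- .pair_terms(idx, as.integer(i), as.integer(j), atom)
  unname(m[1L, kind])
}

# sigma/mean lookup tables from a cssr_params object
.param_maps <- function(params) {
  tab <- params$table
  key <- paste(tab$class, tab$atom, tab$kind)
  list(key = key, mean = tab$mean, sigma = tab$sigma)
}

#' Score candidate pairs of a structure
#'
#' Computes the base-pairing potential score for every candidate pair (see
#' [candidate_pairs()]) against a calibrated geometry model.  The score is
#' the mean Gaussian agreement `exp(-d^2/(2 sigma^2))` over all evaluable
#' sub-terms, where `d` is the deviation from the calibrated mean (taken on
#' the circle for angles and dihedrals).  Pairs with no evaluable sub-term
#' are dropped.
#'
#' @param x An `rna_structure`.
#' @param params A `cssr_params` model from [cssr_calibrate()] or
#'   [cssr_default_params()].
#' @param atoms Optional subset of atom types whose sub-terms contribute
#'   (default: all ten).
#' @param min_separation,inter_chain Passed to [candidate_pairs()].
#' @param average `"flat"` averages all sub-terms with equal weight;
#'   `"nested"` averages within each atom type first, then across atom types.
#' @param min_terms Minimum number of contributing sub-terms for a pair to
#'   be reported (default 1).
#' @return Data frame with columns `i`, `j`, `class`, `score`, `n_terms`.
#' @export
cssr_score_pairs <- function(x, params, atoms = NULL, min_separation = 4L,
                             inter_chain = FALSE,
                             average = c("flat", "nested"), min_terms = 1L) {
  stopifnot(inherits(params, "cssr_params"))
  average <- match.arg(average)
  idx <- structure_index(x)
  cand <- .candidate_pairs_idx(idx, min_separation, inter_chain)
  if (nrow(cand) == 0L)
    return(data.frame(i = integer(), j = integer(), class = character(),
                      score = numeric(), n_terms = integer()))
  if (is.null(atoms)) atoms <- .ATOMS
  else atoms <- match.arg(atoms, .ATOMS, several.ok = TRUE)
  maps <- .param_maps(params)
  np <- nrow(cand)
  tot_sum <- numeric(np); tot_n <- integer(np)
  nest_sum <- numeric(np); nest_n <- integer(np)
  for (a in atoms) {
    terms <- .pair_terms(idx, cand$i, cand$j, a)
    a_sum <- numeric(np); a_n <- integer(np)
    for (k in .KINDS) {
      pos <- match(paste(cand$class, a, k), maps$key)
      v <- terms[, k]
      ok <- !is.na(v) & !is.na(pos)
      if (!any(ok)) next
      mu <- maps$mean[pos[ok]]
      sg <- maps$sigma[pos[ok]]
      d <- if (k %in% .DIST_KINDS) v[ok] - mu
           else angular_difference(v[ok], mu)
      contrib <- exp(-(d * d) / (2 * sg * sg))
      a_sum[ok] <- a_sum[ok] + contrib
      a_n[ok] <- a_n[ok] + 1L
    }
    tot_sum <- tot_sum + a_sum
    tot_n <- tot_n + a_n
    hit <- a_n > 0L
    nest_sum[hit] <- nest_sum[hit] + a_sum[hit] / a_n[hit]
    nest_n[hit] <- nest_n[hit] + 1L
  }
  score <- if (average == "flat") ifelse(tot_n > 0L, tot_sum / tot_n, NA_real_)
           else ifelse(nest_n > 0L, nest_sum / nest_n, NA_real_)
  out <- data.frame(i = cand$i, j = cand$j, class = cand$class,
                    score = score, n_terms = tot_n,
                    stringsAsFactors = FALSE)
  out[!is.na(out$score) & out$n_terms >= min_terms, , drop = FALSE]
}

#' Score a single nucleotide pair
#'
#' Convenience wrapper around the vectorized scorer for one canonical pair.
#'
#' @inheritParams cssr_score_pairs
#' @param i,j Global 1-based nucleotide indices.
#' @return One-row data frame (`i`, `j`, `class`, `score`, `n_terms`), or a
#'   zero-row frame when no sub-term is evaluable.
#' @export
cssr_score <- function(x, i, j, params, atoms = NULL,
                       average = c("flat", "nested")) {
  average <- match.arg(average)
  idx <- structure_index(x)
  gi <- min(i, j); gj <- max(i, j)
  cls <- pair_class(idx$base[gi], idx$base[gj])
  if (is.na(cls))
    stop(sprintf("bases %s:%s at (%d, %d) are not canonically compatible",
                 idx$base[gi], idx$base[gj], gi, gj), call. = FALSE)
  if (is.null(atoms)) atoms <- .ATOMS
  maps <- .param_maps(if (inherits(params, "cssr_params")) params
                      else stop("params must be a cssr_params object"))
  s <- 0; n <- 0L; ns <- 0; nn <- 0L
  for (a in atoms) {
    terms <- .pair_terms(idx, gi, gj, a)
    a_s <- 0; a_n <- 0L
    for (k in .KINDS) {
      v <- terms[1L, k]
      pos <- match(paste(cls, a, k), maps$key)
      if (is.na(v) || is.na(pos)) next
      d <- if (k %in% .DIST_KINDS) v - maps$mean[pos]
           else angular_difference(v, maps$mean[pos])
      a_s <- a_s + exp(-(d * d) / (2 * maps$sigma[pos]^2))
      a_n <- a_n + 1L
    }
    s <- s + a_s; n <- n + a_n
    if (a_n > 0L) { ns <- ns + a_s / a_n; nn <- nn + 1L }
  }
  if (n == 0L)
    return(data.frame(i = integer(), j = integer(), class = character(),
                      score = numeric(), n_terms = integer()))
  data.frame(i = gi, j = gj, class = cls,
             score = if (average == "flat") s / n else ns / nn,
             n_terms = n, stringsAsFactors = FALSE)
}
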
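# Base-pair level evaluation: TP/FP/FN/TN counts, precision, recall, F1 and
# MCC, plus unweighted per-target aggregation with SEM.
#
# A predicted pair counts as TP only when the identical unordered index pair
# occurs in the reference (exact-match criterion; no one-off slippage
# credit).  The TN universe is all L(L-1)/2 unordered nucleotide pairs,
# giving the standard MCC.  Conventions: two empty structures score
# precision = recall = F1 = MCC = 1; one empty side gives F1 = 0.

#' Compare a predicted secondary structure against a reference
#'
#' @param predicted,reference `rna_ss` objects over the same number of
#'   nucleotides.
#' @return An object of class `ss_eval`: a list with counts `tp`, `fp`,
#'   `fn`, `tn` and metrics `precision`, `recall`, `f1`, `mcc`.
#' @examples
#' ref <- rna_ss("GGGGAAAACCCC", cbind(1:4, 12:9))
#' prd <- rna_ss("GGGGAAAACCCC", cbind(1:3, 12:10))
#' ss_evaluate(prd, ref)
#' @export
ss_evaluate <- function(predicted, reference) {
  stopifnot(inherits(predicted, "rna_ss"), inherits(reference, "rna_ss"))
  L <- length(predicted)
  if (L != length(reference))
    stop(sprintf("length mismatch: predicted %d vs reference %d nt",
                 L, length(reference)), call. = FALSE)
  pk <- paste(predicted$pairs[, 1L], predicted$pairs[, 2L])
  rk <- paste(reference$pairs[, 1L], reference$pairs[, 2L])
  tp <- sum(pk %in% rk)
  fp <- length(pk) - tp
  fn <- length(rk) - tp
  tn <- L * (L - 1) / 2 - tp - fp - fn
  if (length(pk) == 0L && length(rk) == 0L) {
    precision <- recall <- f1 <- mcc <- 1
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1, mcc = mcc),
            class = "ss_eval")
}

#' @export
print.ss_eval <- function(x, ...) {
  cat(sprintf("ss_eval: TP %d  FP %d  FN %d  TN %g\n", x$tp, x$fp, x$fn,
              x$tn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  MCC %.4f\n",
              x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}

#' Aggregate per-target evaluation results
#'
#' Unweighted per-target mean and standard error of the mean (sample SD over
#' sqrt(n); 0 for a single target) of F1 and MCC.
#'
#' @param results List of `ss_eval` objects.
#' @return Named numeric vector `mean_f1`, `sem_f1`, `mean_mcc`, `sem_mcc`,
#'   `n`.
#' @export
ss_aggregate <- function(results) {
  if (length(results) == 0L) stop("no results to aggregate", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "ss_eval")))
  f1 <- vapply(results, `[[`, numeric(1), "f1")
  mcc <- vapply(results, `[[`, numeric(1), "mcc")
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  c(mean_f1 = mean(f1), sem_f1 = sem(f1),
    mean_mcc = mean(mcc), sem_mcc = sem(mcc), n = length(f1))
}

#' Partition the pairs of a structure by canonical class
#'
#' @param ss An `rna_ss` whose pairs are all canonical.
#' @return Character vector (one of `"WC"`, `"WOBBLE"`) per pair; errors on
#'   a non-canonical pair.
#' @export
classify_pairs <- function(ss) {
  stopifnot(inherits(ss, "rna_ss"))
  if (nrow(ss$pairs) == 0L) return(character())
  bases <- strsplit(paste(ss$sequence, collapse = ""), "")[[1L]]
  cls <- pair_class(bases[ss$pairs[, 1L]], bases[ss$pairs[, 2L]])
  if (anyNA(cls)) {
    k <- which(is.na(cls))[1L]
    stop(sprintf("pair (%d, %d) with bases %s:%s is not canonical",
                 ss$pairs[k, 1L], ss$pairs[k, 2L],
                 bases[ss$pairs[k, 1L]], bases[ss$pairs[k, 2L]]),
         call. = FALSE)
  }
  cls
}
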
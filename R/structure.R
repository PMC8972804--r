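# Coarse-grained RNA chain containers.
#
# An `rna_chain` keeps, per retained nucleotide, the parent base, the author
# residue number, and a sparse set of coordinates over the ten recognized
# atom types.  Coordinates live in per-atom-type n x 3 matrices with NA rows
# where an atom is absent, which keeps downstream scoring fully vectorized.

#' The ten atom types recognized by the scoring model
#'
#' The phosphate, the eight sugar-backbone heavy atoms and the glycosidic
#' nitrogen (`"N"`, standing for N9 in purines and N1 in pyrimidines).
#'
#' @return Character vector of length 10.
#' @export
cssr_atom_types <- function() {
  c("P", "C5'", "C4'", "C3'", "C2'", "C1'", "O5'", "O4'", "O3'", "N")
}

.ATOMS <- c("P", "C5'", "C4'", "C3'", "C2'", "C1'", "O5'", "O4'", "O3'", "N")

# Constructor used by the parser and the fixture generators.
# bases: character vector in {A,C,G,U} or NA (unmappable residue name)
# xyz:   named list, one n x 3 matrix per atom type present
# linked_prev: logical, TRUE when residue i-1 is sequence-adjacent (no gap)
new_rna_chain <- function(chain_id, bases, xyz, resno = NULL,
                          insert = NULL, linked_prev = NULL) {
  n <- length(bases)
  stopifnot(n >= 1L)
  full <- vector("list", length(.ATOMS))
  names(full) <- .ATOMS
  for (a in .ATOMS) {
    m <- xyz[[a]]
    if (is.null(m)) m <- matrix(NA_real_, n, 3L)
    stopifnot(nrow(m) == n, ncol(m) == 3L)
    dimnames(m) <- NULL
    full[[a]] <- m
  }
  has_atom <- Reduce(`|`, lapply(full, function(m) !is.na(m[, 1L])))
  if (!all(has_atom))
    stop("every retained nucleotide needs at least one atom", call. = FALSE)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(insert)) insert <- rep("", n)
  if (is.null(linked_prev)) linked_prev <- c(FALSE, rep(TRUE, n - 1L))
  linked_prev[1L] <- FALSE
  structure(
    list(chain_id = as.character(chain_id), bases = as.character(bases),
         xyz = full, resno = as.integer(resno), insert = as.character(insert),
         linked_prev = as.logical(linked_prev)),
    class = "rna_chain")
}

new_rna_structure <- function(chains, source = NA_character_) {
  stopifnot(length(chains) >= 1L,
            all(vapply(chains, inherits, logical(1), "rna_chain")))
  structure(list(chains = chains, source = source), class = "rna_structure")
}

#' @export
length.rna_chain <- function(x) length(x$bases)

#' Total number of nucleotides in a structure
#' @param x An `rna_structure`.
#' @return Integer count.
#' @export
n_nucleotides <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  sum(vapply(x$chains, function(ch) length(ch$bases), integer(1)))
}

#' Chain sequences of a structure
#'
#' @param x An `rna_structure`.
#' @return Named character vector, one base string per chain; unmappable
#'   residues appear as `X`.
#' @export
structure_sequences <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  out <- vapply(x$chains, function(ch) {
    b <- ch$bases
    b[is.na(b)] <- "X"
    paste(b, collapse = "")
  }, character(1))
  names(out) <- vapply(x$chains, function(ch) ch$chain_id, character(1))
  out
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("rna_structure:", length(x$chains), "chain(s),",
      n_nucleotides(x), "nucleotides\n")
  for (ch in x$chains) {
    atoms <- vapply(ch$xyz, function(m) sum(!is.na(m[, 1L])), integer(1))
    cat(sprintf("  chain %s: %d nt, atoms: %s\n", ch$chain_id,
                length(ch$bases),
                paste0(names(atoms)[atoms > 0], "(", atoms[atoms > 0], ")",
                       collapse = " ")))
  }
  invisible(x)
}

#' Restrict a structure to a subset of atom types
#'
#' Implements per-atom-type ablation (e.g. keep only the phosphate trace).
#' Nucleotides left with zero atoms are dropped with a warning, and chain
#' adjacency is broken across the resulting gap.
#'
#' @param x An `rna_structure`.
#' @param atoms Character vector of atom types to keep (subset of
#'   [cssr_atom_types()]).
#' @return An `rna_structure`.
#' @export
subset_atoms <- function(x, atoms) {
  stopifnot(inherits(x, "rna_structure"))
  atoms <- match.arg(atoms, .ATOMS, several.ok = TRUE)
  chains <- list()
  for (ch in x$chains) {
    xyz <- ch$xyz
    for (a in setdiff(.ATOMS, atoms))
      xyz[[a]] <- matrix(NA_real_, length(ch$bases), 3L)
    keep <- Reduce(`|`, lapply(xyz[atoms], function(m) !is.na(m[, 1L])))
    if (!any(keep)) {
      warning(sprintf("chain %s: all residues lost atom subset; chain dropped",
                      ch$chain_id), call. = FALSE)
      next
    }
    if (!all(keep)) {
      warning(sprintf("chain %s: dropped %d residue(s) with no retained atoms",
                      ch$chain_id, sum(!keep)), call. = FALSE)
    }
    linked <- ch$linked_prev
    # a dropped residue breaks adjacency for the following retained one
    drop_before <- cumsum(!keep)
    lk <- linked[keep]
    idx <- which(keep)
    if (length(idx) > 1L) {
      gap <- drop_before[idx[-1L]] > drop_before[idx[-length(idx)]]
      lk[-1L] <- lk[-1L] & !gap & linked[idx[-1L]]
    }
    chains[[length(chains) + 1L]] <- new_rna_chain(
      ch$chain_id, ch$bases[keep],
      lapply(xyz, function(m) m[keep, , drop = FALSE]),
      resno = ch$resno[keep], insert = ch$insert[keep], linked_prev = lk)
  }
  if (length(chains) == 0L)
    stop("no residues left after atom subsetting", call. = FALSE)
  new_rna_structure(chains, source = x$source)
}

# Flat, global-index view of a structure used by candidate enumeration,
# scoring and calibration.  Global indices are 1-based over chains in order.
#   inext/iprev: global index of the sequence-adjacent neighbor, NA at chain
#   ends and across gaps.
structure_index <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  ns <- vapply(x$chains, function(ch) length(ch$bases), integer(1))
  n <- sum(ns)
  offs <- cumsum(c(0L, ns[-length(ns)]))
  base <- character(n); chain <- integer(n)
  inext <- rep(NA_integer_, n); iprev <- rep(NA_integer_, n)
  xyz <- lapply(.ATOMS, function(a) matrix(NA_real_, n, 3L))
  names(xyz) <- .ATOMS
  for (k in seq_along(x$chains)) {
    ch <- x$chains[[k]]
    ix <- offs[k] + seq_len(ns[k])
    base[ix] <- ch$bases
    chain[ix] <- k
    if (ns[k] > 1L) {
      linked <- ch$linked_prev[-1L]           # adjacency of i to i-1
      iprev[ix[-1L][linked]] <- ix[-ns[k]][linked]
      inext[ix[-ns[k]][linked]] <- ix[-1L][linked]
    }
    for (a in .ATOMS) xyz[[a]][ix, ] <- ch$xyz[[a]]
  }
  has_atom <- Reduce(`|`, lapply(xyz, function(m) !is.na(m[, 1L])))
  list(n = n, base = base, chain = chain, inext = inext, iprev = iprev,
       xyz = xyz, has_atom = has_atom, offsets = offs, sizes = ns)
}

# Canonical pair class of two bases: "WC", "WOBBLE" or NA.
pair_class <- function(b1, b2) {
  k <- paste(pmin(b1, b2), pmax(b1, b2))
  out <- rep(NA_character_, length(k))
  out[k == "A U" | k == "C G"] <- "WC"
  out[k == "G U"] <- "WOBBLE"
  out
}
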
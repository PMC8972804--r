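# Conflict resolution and secondary-structure containers / formats.

#' Construct a secondary-structure object
#'
#' A conflict-free set of base pairs over one or more chains.  Positions are
#' global 1-based indices over the concatenated chains.
#'
#' @param sequence Character vector of per-chain base strings (or a single
#'   string, possibly containing `&` chain separators).
#' @param pairs Two-column integer matrix of paired positions (unordered;
#'   stored with i < j), or NULL/empty for no pairs.
#' @param scores Optional numeric vector of per-pair scores.
#' @param chain_ids Optional chain identifiers.
#' @return An object of class `rna_ss`.
#' @export
rna_ss <- function(sequence, pairs = NULL, scores = NULL, chain_ids = NULL) {
  if (length(sequence) == 1L && grepl("&", sequence, fixed = TRUE))
    sequence <- strsplit(sequence, "&", fixed = TRUE)[[1L]]
  sequence <- toupper(as.character(sequence))
  n <- sum(nchar(sequence))
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(), 0L, 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                   pmax(pairs[, 1L], pairs[, 2L]))
    if (any(pairs[, 1L] < 1L) || any(pairs[, 2L] > n))
      stop("pair index out of range", call. = FALSE)
    if (any(pairs[, 1L] == pairs[, 2L]))
      stop("a nucleotide cannot pair with itself", call. = FALSE)
    if (anyDuplicated(c(pairs)))
      stop("conflicting pairs: a nucleotide occurs in more than one pair",
           call. = FALSE)
    ord <- order(pairs[, 1L])
    pairs <- pairs[ord, , drop = FALSE]
    if (!is.null(scores)) scores <- scores[ord]
  }
  if (!is.null(scores)) stopifnot(length(scores) == nrow(pairs))
  if (is.null(chain_ids)) chain_ids <- as.character(seq_along(sequence))
  structure(list(sequence = sequence, pairs = pairs, scores = scores,
                 chain_ids = as.character(chain_ids)),
            class = "rna_ss")
}

#' @export
length.rna_ss <- function(x) sum(nchar(x$sequence))

#' @export
print.rna_ss <- function(x, ...) {
  cat(sprintf("rna_ss: %d nt in %d chain(s), %d base pair(s)\n",
              length(x), length(x$sequence), nrow(x$pairs)))
  cat(paste(x$sequence, collapse = "&"), "\n")
  cat(to_dotbracket(x), "\n")
  invisible(x)
}

#' Greedy conflict-resolving filter over scored pairs
#'
#' Keeps pairs scoring at least `cutoff`, lists them in descending score
#' order, and walks the list accepting a pair only when neither nucleotide
#' already belongs to an accepted pair.  No planarity constraint is applied,
#' so crossing (pseudoknotted) pairs are legal.  Score ties are broken
#' deterministically by smaller i, then smaller j.
#'
#' @param scores Data frame with columns `i`, `j`, `score` (as returned by
#'   [cssr_score_pairs()]).
#' @param x The `rna_structure` the scores were computed on (supplies the
#'   sequence), or an `rna_ss`/character sequence.
#' @param cutoff Minimum score to consider (default 0.5).
#' @return An `rna_ss` with accepted pairs and their scores.
#' @export
ss_assign <- function(scores, x, cutoff = 0.5) {
  seqs <- if (inherits(x, "rna_structure")) structure_sequences(x)
          else if (inherits(x, "rna_ss")) x$sequence
          else as.character(x)
  ids <- if (inherits(x, "rna_structure"))
    vapply(x$chains, function(ch) ch$chain_id, character(1))
  else NULL
  n <- sum(nchar(seqs))
  keep <- scores[!is.na(scores$score) & scores$score >= cutoff, , drop = FALSE]
  if (nrow(keep) == 0L)
    return(rna_ss(seqs, NULL, NULL, ids))
  ord <- order(-keep$score, keep$i, keep$j)
  keep <- keep[ord, , drop = FALSE]
  used <- logical(n)
  acc <- logical(nrow(keep))
  for (r in seq_len(nrow(keep))) {
    i <- keep$i[r]; j <- keep$j[r]
    if (!used[i] && !used[j]) {
      acc[r] <- TRUE
      used[i] <- TRUE
      used[j] <- TRUE
    }
  }
  rna_ss(seqs, as.matrix(keep[acc, c("i", "j")]), keep$score[acc], ids)
}

#' Assign secondary structure to a 3D structure
#'
#' Full pipeline: enumerate candidate pairs, score them against the geometry
#' model, and resolve conflicts greedily.
#'
#' @inheritParams cssr_score_pairs
#' @param cutoff Score cutoff for the greedy filter (default 0.5).
#' @return An `rna_ss`.
#' @seealso [predict.cssr_params()] for the model-object interface.
#' @export
cssr_assign <- function(x, params, atoms = NULL, cutoff = 0.5,
                        min_separation = 4L, inter_chain = FALSE,
                        average = c("flat", "nested"), min_terms = 1L) {
  sc <- cssr_score_pairs(x, params, atoms = atoms,
                         min_separation = min_separation,
                         inter_chain = inter_chain,
                         average = match.arg(average), min_terms = min_terms)
  ss_assign(sc, x, cutoff = cutoff)
}

.OPENERS <- c("(", "[", "{", "<", LETTERS)
.CLOSERS <- c(")", "]", "}", ">", letters)

#' Dot-bracket notation with pseudoknot bracket levels
#'
#' One character per nucleotide, chains separated by `&`.  Crossing pairs are
#' assigned greedily to the lowest bracket level at which they cross no
#' already-assigned pair: level 0 uses `()`, then `[]`, `{}`, `<>`, then
#' letter pairs `Aa`, `Bb`, ...
#'
#' @param ss An `rna_ss`.
#' @return A dot-bracket string.
#' @export
to_dotbracket <- function(ss) {
  stopifnot(inherits(ss, "rna_ss"))
  n <- length(ss)
  ch <- rep(".", n)
  p <- ss$pairs
  if (nrow(p) > 0L) {
    ord <- order(p[, 1L])
    p <- p[ord, , drop = FALSE]
    lev <- integer(nrow(p))
    for (r in seq_len(nrow(p))) {
      l <- 0L
      repeat {
        prior <- which(lev[seq_len(r - 1L)] == l)
        crossing <- FALSE
        for (q in prior) {
          a <- p[q, 1L]; b <- p[q, 2L]; i <- p[r, 1L]; j <- p[r, 2L]
          if ((a < i && i < b && b < j) || (i < a && a < j && j < b)) {
            crossing <- TRUE; break
          }
        }
        if (!crossing) break
        l <- l + 1L
        if (l >= length(.OPENERS))
          stop("pseudoknot nesting exceeds available bracket alphabet",
               call. = FALSE)
      }
      lev[r] <- l
      ch[p[r, 1L]] <- .OPENERS[l + 1L]
      ch[p[r, 2L]] <- .CLOSERS[l + 1L]
    }
  }
  lens <- nchar(ss$sequence)
  parts <- character(length(lens))
  off <- 0L
  for (k in seq_along(lens)) {
    parts[k] <- paste(ch[off + seq_len(lens[k])], collapse = "")
    off <- off + lens[k]
  }
  paste(parts, collapse = "&")
}

#' Parse a dot-bracket string
#'
#' Inverse of [to_dotbracket()]; supports `&` chain separators and the full
#' bracket-level alphabet.
#'
#' @param sequence Base string (with `&` breaks) matching the structure.
#' @param dotbracket Dot-bracket string.
#' @return An `rna_ss`.
#' @export
parse_dotbracket <- function(sequence, dotbracket) {
  db <- gsub("&", "", dotbracket, fixed = TRUE)
  chars <- strsplit(db, "")[[1L]]
  stacks <- lapply(seq_along(.OPENERS), function(i) integer())
  pairs <- list()
  for (pos in seq_along(chars)) {
    c0 <- chars[pos]
    if (c0 %in% .OPENERS) {
      l <- match(c0, .OPENERS)
      stacks[[l]] <- c(stacks[[l]], pos)
    } else if (c0 %in% .CLOSERS) {
      l <- match(c0, .CLOSERS)
      k <- length(stacks[[l]])
      if (k == 0L)
        stop(sprintf("unbalanced '%s' at position %d", c0, pos),
             call. = FALSE)
      pairs[[length(pairs) + 1L]] <- c(stacks[[l]][k], pos)
      stacks[[l]] <- stacks[[l]][-k]
    } else if (c0 != "." && c0 != "-") {
      stop(sprintf("unexpected character '%s' at position %d", c0, pos),
           call. = FALSE)
    }
  }
  if (any(vapply(stacks, length, integer(1)) > 0L))
    stop("unbalanced brackets: unclosed pair", call. = FALSE)
  rna_ss(sequence, do.call(rbind, pairs))
}

#' Read / write dot-bracket (DBN) files
#'
#' A DBN record is an optional `>name` line, a sequence line and a structure
#' line; chains are separated by `&`.
#'
#' @param path File path.
#' @param ss An `rna_ss`.
#' @param name Record name for the `>` header.
#' @return `read_dbn` returns an `rna_ss`; the writers return `path`
#'   invisibly.
#' @export
read_dbn <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  ln <- ln[!startsWith(trimws(ln), ">")]
  if (length(ln) < 2L)
    stop("malformed DBN file: need sequence and structure lines",
         call. = FALSE)
  parse_dotbracket(trimws(ln[1L]), trimws(ln[2L]))
}

#' @rdname read_dbn
#' @export
write_dbn <- function(ss, path, name = "structure") {
  stopifnot(inherits(ss, "rna_ss"))
  writeLines(c(paste0(">", name),
               paste(ss$sequence, collapse = "&"),
               to_dotbracket(ss)), path)
  invisible(path)
}

#' Read / write CT files
#'
#' Standard 6-column connectivity table, 1-based, partner 0 when unpaired.
#' Chains are written with continuous numbering; a chain break is encoded by
#' a zero in the previous/next-index columns and is recovered on read.
#'
#' @param ss An `rna_ss`.
#' @param path File path.
#' @param name Title for the header line.
#' @return `read_ct` returns an `rna_ss`; writers return `path` invisibly.
#' @export
write_ct <- function(ss, path, name = "structure") {
  stopifnot(inherits(ss, "rna_ss"))
  n <- length(ss)
  partner <- integer(n)
  if (nrow(ss$pairs) > 0L) {
    partner[ss$pairs[, 1L]] <- ss$pairs[, 2L]
    partner[ss$pairs[, 2L]] <- ss$pairs[, 1L]
  }
  bases <- strsplit(paste(ss$sequence, collapse = ""), "")[[1L]]
  lens <- nchar(ss$sequence)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  prv <- seq_len(n) - 1L
  nxt <- seq_len(n) + 1L
  prv[starts] <- 0L
  nxt[ends] <- 0L
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("%5d %s\n", n, name), file = con)
  cat(sprintf("%5d %s %7d %4d %4d %4d\n", seq_len(n), bases, prv, nxt,
              partner, seq_len(n)), sep = "", file = con)
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 1L) stop("empty CT file", call. = FALSE)
  n <- suppressWarnings(as.integer(strsplit(trimws(ln[1L]), "\\s+")[[1L]][1L]))
  if (is.na(n)) stop("malformed CT header", call. = FALSE)
  if (length(ln) < n + 1L) stop("truncated CT file", call. = FALSE)
  fields <- strsplit(trimws(ln[1L + seq_len(n)]), "\\s+")
  bases <- vapply(fields, `[`, character(1), 2L)
  prv <- as.integer(vapply(fields, `[`, character(1), 3L))
  partner <- as.integer(vapply(fields, `[`, character(1), 5L))
  breaks <- which(prv == 0L)
  starts <- if (length(breaks)) breaks else 1L
  ends <- c(starts[-1L] - 1L, n)
  seqs <- mapply(function(s, e) paste(bases[s:e], collapse = ""),
                 starts, ends)
  p <- which(partner > seq_len(n))
  rna_ss(seqs, if (length(p)) cbind(p, partner[p]) else NULL)
}

#' Read / write BPSEQ files
#'
#' Three columns: position, base, partner (0 = unpaired), 1-based.  BPSEQ
#' has no chain-break marker, so multi-chain structures read back as one
#' chain.
#'
#' @inheritParams write_ct
#' @return `read_bpseq` returns an `rna_ss`; writers return `path`
#'   invisibly.
#' @export
write_bpseq <- function(ss, path) {
  stopifnot(inherits(ss, "rna_ss"))
  n <- length(ss)
  partner <- integer(n)
  if (nrow(ss$pairs) > 0L) {
    partner[ss$pairs[, 1L]] <- ss$pairs[, 2L]
    partner[ss$pairs[, 2L]] <- ss$pairs[, 1L]
  }
  bases <- strsplit(paste(ss$sequence, collapse = ""), "")[[1L]]
  writeLines(sprintf("%d %s %d", seq_len(n), bases, partner), path)
  invisible(path)
}

#' @rdname write_bpseq
#' @export
read_bpseq <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  fields <- strsplit(trimws(ln), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) != 3L)
  if (length(bad))
    stop(sprintf("malformed BPSEQ row %d", bad[1L]), call. = FALSE)
  bases <- vapply(fields, `[`, character(1), 2L)
  partner <- as.integer(vapply(fields, `[`, character(1), 3L))
  n <- length(bases)
  p <- which(partner > seq_len(n))
  rna_ss(paste(bases, collapse = ""),
         if (length(p)) cbind(p, partner[p]) else NULL)
}

#' Write a pair list with scores
#'
#' Plain text: commented header, then one `i j score` row per pair.
#'
#' @param ss An `rna_ss` (scores optional; NA written when absent).
#' @param path File path.
#' @return `read_pairs` returns a data frame `i`, `j`, `score`;
#'   `write_pairs` returns `path` invisibly.
#' @export
write_pairs <- function(ss, path) {
  stopifnot(inherits(ss, "rna_ss"))
  sc <- if (is.null(ss$scores)) rep(NA_real_, nrow(ss$pairs)) else ss$scores
  con <- file(path, "w")
  on.exit(close(con))
  cat("# i\tj\tscore\n", file = con)
  if (nrow(ss$pairs) > 0L)
    cat(sprintf("%d\t%d\t%s\n", ss$pairs[, 1L], ss$pairs[, 2L],
                formatC(sc, digits = 17, format = "g")),
        sep = "", file = con)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(ln, "#")]
  if (length(ln) == 0L)
    return(data.frame(i = integer(), j = integer(), score = numeric()))
  fields <- strsplit(trimws(ln), "\\s+")
  data.frame(i = as.integer(vapply(fields, `[`, character(1), 1L)),
             j = as.integer(vapply(fields, `[`, character(1), 2L)),
             score = as.numeric(vapply(fields, `[`, character(1), 3L)))
}
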
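# Independent oracles used across the suite.  These deliberately share no
# code with the package internals: scalar geometry, explicit loops, and a
# literal transcription of the greedy filter.

# --- scalar geometry, written from first principles -------------------------

o_dist <- function(p, q) sqrt(sum((p - q)^2))

o_ang <- function(a, v, c) {
  u <- a - v; w <- c - v
  acos(max(-1, min(1, sum(u * w) / (o_dist(a, v) * o_dist(c, v))))) * 180 / pi
}

o_dih <- function(p1, p2, p3, p4) {
  xp <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- xp(b1, b2); n2 <- xp(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(xp(n1, b2 / sqrt(sum(b2^2))) * n2)
  a <- atan2(y, x) * 180 / pi
  if (a <= -180) a + 360 else a
}

o_angdiff <- function(x, y) {
  min(abs(x - y + 360 * (-4:4)))
}

# --- flat residue view built directly from the public chain fields ----------

o_residues <- function(x) {
  out <- list()
  for (ci in seq_along(x$chains)) {
    ch <- x$chains[[ci]]
    for (r in seq_along(ch$bases)) {
      coords <- list()
      for (a in cssr_atom_types()) {
        co <- ch$xyz[[a]][r, ]
        if (!is.na(co[1])) coords[[a]] <- co
      }
      out[[length(out) + 1L]] <- list(chain = ci, base = ch$bases[r],
                                      coords = coords,
                                      linked_prev = ch$linked_prev[r])
    }
  }
  out
}

o_neighbor <- function(res, k, dir) {
  k2 <- k + dir
  if (k2 < 1L || k2 > length(res)) return(NULL)
  if (res[[k2]]$chain != res[[k]]$chain) return(NULL)
  linked <- if (dir > 0) res[[k2]]$linked_prev else res[[k]]$linked_prev
  if (!linked) return(NULL)
  res[[k2]]
}

o_class <- function(b1, b2) {
  s <- paste(sort(c(b1, b2)), collapse = "")
  if (s %in% c("AU", "CG")) "WC" else if (s == "GU") "WOBBLE" else NA
}

# one raw sub-term value, or NULL when not evaluable
o_term <- function(res, i, j, atom, kind) {
  g <- function(node) if (is.null(node)) NULL else node$coords[[atom]]
  ai <- g(res[[i]]); aj <- g(res[[j]])
  ui <- g(o_neighbor(res, i, +1L)); di <- g(o_neighbor(res, i, -1L))
  uj <- g(o_neighbor(res, j, +1L)); dj <- g(o_neighbor(res, j, -1L))
  need <- switch(kind,
                 dist0 = list(ai, aj), dist_up = list(ui, dj),
                 dist_down = list(di, uj), ang_i = list(ui, ai, aj),
                 ang_j = list(dj, aj, ai), dih_i = list(ui, ai, aj, dj),
                 dih_j = list(uj, aj, ai, di))
  if (any(vapply(need, is.null, logical(1)))) return(NULL)
  out <- switch(kind,
                dist0 = o_dist(ai, aj),
                dist_up = o_dist(ui, dj),
                dist_down = o_dist(di, uj),
                ang_i = o_ang(ui, ai, aj),
                ang_j = o_ang(dj, aj, ai),
                dih_i = tryCatch(o_dih(ui, ai, aj, dj),
                                 error = function(e) NULL),
                dih_j = tryCatch(o_dih(uj, aj, ai, di),
                                 error = function(e) NULL))
  out
}

# explicit-loop re-implementation of the pair score
o_score <- function(x, i, j, params, atoms = cssr_atom_types(),
                    nested = FALSE) {
  res <- o_residues(x)
  ii <- min(i, j); jj <- max(i, j)
  cls <- o_class(res[[ii]]$base, res[[jj]]$base)
  tab <- coef(params)
  total <- 0; nterm <- 0L; atom_means <- c()
  for (a in atoms) {
    s_a <- 0; n_a <- 0L
    for (k in cssr_term_kinds()) {
      v <- o_term(res, ii, jj, a, k)
      if (is.null(v)) next
      row <- tab[tab$class == cls & tab$atom == a & tab$kind == k, ]
      if (nrow(row) != 1L) next
      delta <- if (k %in% c("dist0", "dist_up", "dist_down")) v - row$mean
               else o_angdiff(v, row$mean)
      s_a <- s_a + exp(-delta^2 / (2 * row$sigma^2))
      n_a <- n_a + 1L
    }
    total <- total + s_a; nterm <- nterm + n_a
    if (n_a > 0L) atom_means <- c(atom_means, s_a / n_a)
  }
  if (nterm == 0L) return(NULL)
  list(score = if (nested) mean(atom_means) else total / nterm,
       n_terms = nterm)
}

# --- literal transcription of the conflict filter ---------------------------
# "all nucleotide pairs with scores >= cutoff are listed in descending order
#  of their scores.  Pairs are then iteratively excluded from this list if
#  one or both nucleotides overlap with any pairs that rank higher on the
#  list."
o_greedy <- function(df, cutoff = 0.5) {
  lst <- df[df$score >= cutoff, , drop = FALSE]
  lst <- lst[order(-lst$score, lst$i, lst$j), , drop = FALSE]
  excluded <- rep(FALSE, nrow(lst))
  for (r in seq_len(nrow(lst))) {
    for (h in seq_len(r - 1L)) {
      if (excluded[h]) next
      if (lst$i[r] %in% c(lst$i[h], lst$j[h]) ||
          lst$j[r] %in% c(lst$i[h], lst$j[h])) {
        excluded[r] <- TRUE
        break
      }
    }
  }
  out <- lst[!excluded, c("i", "j"), drop = FALSE]
  m <- as.matrix(out[order(out$i, out$j), , drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

# brute-force candidate enumeration by the three rules
o_candidates <- function(x, min_sep = 4L, inter_chain = FALSE) {
  res <- o_residues(x)
  n <- length(res)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (length(res[[i]]$coords) == 0L || length(res[[j]]$coords) == 0L) next
    same <- res[[i]]$chain == res[[j]]$chain
    if (same && (j - i) < min_sep) next
    if (!same && !inter_chain) next
    cls <- o_class(res[[i]]$base, res[[j]]$base)
    if (is.na(cls)) next
    out[[length(out) + 1L]] <- data.frame(i = i, j = j, class = cls)
  }
  if (length(out) == 0L)
    return(data.frame(i = integer(), j = integer(), class = character()))
  do.call(rbind, out)
}

# random conflict-free secondary structure for format round-trips
o_random_ss <- function(n, n_chains = 1L, p_pair = 0.3, seed = 1L) {
  set.seed(seed)
  lens <- if (n_chains == 1L) n else {
    cuts <- sort(sample(seq_len(n - 1L), n_chains - 1L))
    diff(c(0L, cuts, n))
  }
  seqs <- vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = ""),
    character(1))
  free <- seq_len(n)
  pairs <- NULL
  while (length(free) >= 2L && runif(1) < 0.97) {
    pick <- sample(free, 2L)
    if (runif(1) < p_pair)
      pairs <- rbind(pairs, sort(pick))
    free <- setdiff(free, pick)
  }
  rna_ss(seqs, pairs)
}

# rigid rotation matrix from a seeded QR factorization
o_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# access to the internal container constructor for fixture surgery
new_rna_structure_for_test <- function(chains) {
  cssr:::new_rna_structure(chains)
}

new_rna_chain_for_test <- function(...) {
  cssr:::new_rna_chain(...)
}
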
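# Synthetic coordinate fixtures with known ground-truth secondary structure.
#
# Geometry is an idealized cylindrical-template helix: each atom type sits at
# a fixed (radius, phase, z-offset) in the frame of its nucleotide's helix
# step, with A-form-like rise and twist.  The two strands of a duplex are
# related by a per-base-pair dyad, so every interior pair is exactly
# congruent (periodicity), which makes generator-calibrated parameters score
# ideal fixtures at exactly 1.  The templates are internally consistent
# configuration constants, not literature atomic coordinates; the scoring
# pipeline only ever compares fixtures against statistics calibrated on the
# same generator.

#' Helix geometry specification
#'
#' @param rise Rise per step in Angstrom.
#' @param twist Twist per step in degrees.
#' @param templates Named list, one `c(radius, phase, dz)` per atom type
#'   (radius Angstrom, phase degrees, z-offset Angstrom).
#' @return An object of class `helix_spec`.
#' @export
helix_spec <- function(rise = 2.81, twist = 32.7, templates = NULL) {
  if (is.null(templates)) {
    templates <- list(
      "P"   = c(9.4, 75, 1.2),
      "O5'" = c(9.3, 68, 0.6),
      "C5'" = c(9.6, 62, 0.1),
      "C4'" = c(9.5, 55, -0.2),
      "C3'" = c(9.1, 47, 0.5),
      "C2'" = c(8.9, 41, -0.9),
      "C1'" = c(9.0, 35, -0.5),
      "O4'" = c(8.8, 49, -0.6),
      "O3'" = c(8.9, 54, 1.1),
      "N"   = c(7.8, 28, -0.3))
  }
  stopifnot(setequal(names(templates), .ATOMS))
  structure(list(rise = rise, twist = twist, templates = templates[.ATOMS]),
            class = "helix_spec")
}

# Atom position on strand A (sense +1) or the dyad-related partner strand
# (sense -1) for helix step u (0-based, may be negative for continuations).
.helix_atom <- function(spec, u, atom, sense = 1L, origin = c(0, 0, 0)) {
  t <- spec$templates[[atom]]
  ang <- (spec$twist * u + sense * t[2L]) * pi / 180
  origin + c(t[1L] * cos(ang), t[1L] * sin(ang),
             spec$rise * u + sense * t[3L])
}

# Full-residue coordinates (all ten atoms) at helix step u.
.helix_residue <- function(spec, u, sense = 1L, origin = c(0, 0, 0)) {
  out <- lapply(.ATOMS, function(a) .helix_atom(spec, u, a, sense, origin))
  names(out) <- .ATOMS
  out
}

# Rigid per-atom offsets used for free (loop / linker) residues.
.free_offsets <- function(spec) {
  ref <- .helix_residue(spec, 0L)
  center <- Reduce(`+`, ref) / length(ref)
  lapply(ref, function(p) p - center)
}

.residue_at <- function(offsets, center) {
  lapply(offsets, function(o) center + o)
}

# assemble a chain from a list of per-residue atom lists
.build_chain <- function(chain_id, bases, residues) {
  n <- length(bases)
  xyz <- lapply(.ATOMS, function(a)
    do.call(rbind, lapply(residues, function(r) r[[a]])))
  names(xyz) <- .ATOMS
  new_rna_chain(chain_id, bases, xyz)
}

.BASES <- c("A", "C", "G", "U")
.WC_PARTNER <- c(A = "U", U = "A", C = "G", G = "C")

# complementary partner sequence with optional wobble steps
.partner_bases <- function(bases, gu_frac = 0) {
  out <- unname(.WC_PARTNER[bases])
  if (gu_frac > 0) {
    can_wobble <- bases %in% c("G", "U")
    flip <- can_wobble & stats::runif(length(bases)) < gu_frac
    out[flip & bases == "G"] <- "U"
    out[flip & bases == "U"] <- "G"
  }
  out
}

.random_stem <- function(n) sample(.BASES, n, replace = TRUE)

.random_loop <- function(n) sample(c("A", "C"), n, replace = TRUE)

# Run code with a temporary RNG state when seed is given.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Ideal antiparallel duplex with known pairing
#'
#' Two complementary strands placed on a regular cylindrical-template helix;
#' strand B is the per-base-pair dyad image of strand A, so all interior
#' pairs are geometrically congruent.  Ground truth pairs every position
#' with its complement (inter-chain).
#'
#' @param length Number of base pairs (>= 2).
#' @param sequence Optional strand sequence(s): one string (strand A; the
#'   partner is generated) or two strings (validated for complementarity).
#' @param gu_frac Probability of a wobble G:U step when generating the
#'   partner strand.
#' @param spec A [helix_spec()].
#' @param seed Optional RNG seed for sequence generation.
#' @return List with `structure` (an `rna_structure` of chains A and B) and
#'   `truth` (an `rna_ss`).
#' @export
make_duplex <- function(length = 10L, sequence = NULL, gu_frac = 0,
                        spec = helix_spec(), seed = NULL) {
  .with_seed(seed, {
    if (is.null(sequence)) {
      a <- .random_stem(length)
      b <- .partner_bases(a, gu_frac)
    } else if (length(sequence) == 1L) {
      a <- strsplit(toupper(sequence), "")[[1L]]
      b <- .partner_bases(a, gu_frac)
    } else {
      a <- strsplit(toupper(sequence[1L]), "")[[1L]]
      b <- strsplit(toupper(sequence[2L]), "")[[1L]]
      b <- rev(b)   # partner of a[u] in pairing order
      if (length(a) != length(b) || anyNA(pair_class(a, b)))
        stop("strands are not complementary under canonical pairing",
             call. = FALSE)
    }
    L <- length(a)
    if (L < 2L) stop("duplex needs length >= 2", call. = FALSE)
    resA <- lapply(seq_len(L) - 1L, function(u) .helix_residue(spec, u, 1L))
    resB <- lapply(rev(seq_len(L)) - 1L,
                   function(u) .helix_residue(spec, u, -1L))
    chA <- .build_chain("A", a, resA)
    chB <- .build_chain("B", rev(b), resB)
    x <- new_rna_structure(list(chA, chB), source = "synthetic duplex")
    u <- seq_len(L) - 1L
    truth <- rna_ss(structure_sequences(x),
                    cbind(u + 1L, 2L * L - u),
                    chain_ids = c("A", "B"))
    list(structure = x, truth = truth)
  })
}

#' Hairpin with an ideal-helix stem
#'
#' Single chain: duplex geometry for the stem, a smooth arc for the loop.
#' The first and last loop residues sit on the helical continuation of the
#' two stem strands, so the stem-closing pair keeps exact stacking geometry.
#' Loop bases are drawn from `{A, C}` so the unpaired region carries no
#' incidental canonical complementarity.  Ground truth = stem pairs only.
#'
#' @param stem_length Stem length in base pairs (>= 2).
#' @param loop_length Loop length in nucleotides (>= 3).
#' @param sequence Optional full chain sequence (stem + loop + stem).
#' @param gu_frac Probability of wobble steps in the stem.
#' @param spec A [helix_spec()].
#' @param seed Optional RNG seed.
#' @return List with `structure` and `truth` as in [make_duplex()].
#' @export
make_hairpin <- function(stem_length = 6L, loop_length = 4L, sequence = NULL,
                         gu_frac = 0, spec = helix_spec(), seed = NULL) {
  if (loop_length < 3L)
    stop("loop_length must be >= 3 (steric minimum)", call. = FALSE)
  if (stem_length < 2L) stop("stem_length must be >= 2", call. = FALSE)
  .with_seed(seed, {
    s <- stem_length; l <- loop_length
    if (is.null(sequence)) {
      a <- .random_stem(s)
      loop <- .random_loop(l)
      b <- .partner_bases(a, gu_frac)
    } else {
      ch <- strsplit(toupper(sequence), "")[[1L]]
      if (length(ch) != 2L * s + l)
        stop("sequence length must equal 2*stem + loop", call. = FALSE)
      a <- ch[seq_len(s)]
      loop <- ch[s + seq_len(l)]
      b <- rev(ch[s + l + seq_len(s)])
      if (anyNA(pair_class(a, b)))
        stop("stem halves are not complementary", call. = FALSE)
    }
    res5 <- lapply(seq_len(s) - 1L, function(u) .helix_residue(spec, u, 1L))
    # loop: endpoints on the helical continuations, middles on a bulged arc
    offs <- .free_offsets(spec)
    p1 <- .helix_residue(spec, s, 1L)
    pl <- .helix_residue(spec, s, -1L)
    c1 <- Reduce(`+`, p1) / length(p1)
    cl <- Reduce(`+`, pl) / length(pl)
    resL <- vector("list", l)
    resL[[1L]] <- p1
    resL[[l]] <- pl
    if (l > 2L) {
      for (t in 2L:(l - 1L)) {
        w <- (t - 1) / (l - 1)
        bulge <- 4 * sin(pi * w)
        radial <- c1 + w * (cl - c1)
        outward <- radial - c(0, 0, radial[3L])
        outward <- outward / sqrt(sum(outward^2))
        center <- radial + bulge * outward + c(0, 0, 2 * sin(pi * w))
        resL[[t]] <- .residue_at(offs, center)
      }
    }
    res3 <- lapply(rev(seq_len(s)) - 1L,
                   function(u) .helix_residue(spec, u, -1L))
    bases <- c(a, loop, rev(b))
    chain <- .build_chain("A", bases, c(res5, resL, res3))
    x <- new_rna_structure(list(chain), source = "synthetic hairpin")
    u <- seq_len(s) - 1L
    truth <- rna_ss(structure_sequences(x),
                    cbind(u + 1L, 2L * s + l - u), chain_ids = "A")
    list(structure = x, truth = truth)
  })
}

#' H-type pseudoknot with crossing stems
#'
#' Two ideal-helix stem blocks rigidly placed and connected by linkers; the
#' ground-truth pairs of the two stems cross (segment order 5'-S1-L1-S2-S1'-
#' L2-S2'-3').  Linker endpoints sit on the helical continuations of the
#' adjacent stem strands; linker bases come from `{A, C}`.
#'
#' @param stem1,stem2 Stem lengths in base pairs (>= 2).
#' @param linker1,linker2 Linker lengths in nucleotides (>= 2).
#' @param gu_frac Probability of wobble steps in the stems.
#' @param spec A [helix_spec()].
#' @param seed Optional RNG seed.
#' @return List with `structure` and `truth` as in [make_duplex()].
#' @export
make_pseudoknot <- function(stem1 = 4L, stem2 = 4L, linker1 = 3L,
                            linker2 = 3L, gu_frac = 0, spec = helix_spec(),
                            seed = NULL) {
  stopifnot(stem1 >= 2L, stem2 >= 2L)
  if (linker1 < 2L || linker2 < 2L)
    stop("linkers need >= 2 nucleotides", call. = FALSE)
  .with_seed(seed, {
    s1 <- stem1; s2 <- stem2; l1 <- linker1; l2 <- linker2
    off2 <- c(22, 0, 0)                     # rigid placement of block 2
    a1 <- .random_stem(s1); b1 <- .partner_bases(a1, gu_frac)
    a2 <- .random_stem(s2); b2 <- .partner_bases(a2, gu_frac)
    lk1 <- .random_loop(l1); lk2 <- .random_loop(l2)

    offs <- .free_offsets(spec)
    interp <- function(anchor_a, anchor_b, nfree, t) {
      w <- t / (nfree + 1)
      center <- anchor_a + w * (anchor_b - anchor_a) +
        c(0, 6 * sin(pi * w), 3 * sin(pi * w))
      .residue_at(offs, center)
    }
    ctr <- function(res) Reduce(`+`, res) / length(res)

    seg1 <- lapply(seq_len(s1) - 1L, function(u) .helix_residue(spec, u, 1L))
    lk1_first <- .helix_residue(spec, s1, 1L)
    lk1_last <- .helix_residue(spec, -1L, 1L, off2)
    segL1 <- c(list(lk1_first),
               if (l1 > 2L) lapply(seq_len(l1 - 2L), function(t)
                 interp(ctr(lk1_first), ctr(lk1_last), l1 - 2L, t)),
               list(lk1_last))
    seg2 <- lapply(seq_len(s2) - 1L,
                   function(u) .helix_residue(spec, u, 1L, off2))
    seg3 <- lapply(rev(seq_len(s1)) - 1L,
                   function(u) .helix_residue(spec, u, -1L))
    lk2_first <- .helix_residue(spec, -1L, -1L)
    lk2_last <- .helix_residue(spec, s2, -1L, off2)
    segL2 <- c(list(lk2_first),
               if (l2 > 2L) lapply(seq_len(l2 - 2L), function(t)
                 interp(ctr(lk2_first), ctr(lk2_last), l2 - 2L, t)),
               list(lk2_last))
    seg4 <- lapply(rev(seq_len(s2)) - 1L,
                   function(u) .helix_residue(spec, u, -1L, off2))

    bases <- c(a1, lk1, a2, rev(b1), lk2, rev(b2))
    chain <- .build_chain("A", bases,
                          c(seg1, segL1, seg2, seg3, segL2, seg4))
    x <- new_rna_structure(list(chain), source = "synthetic pseudoknot")
    off3 <- s1 + l1 + s2
    off4 <- off3 + s1 + l2
    u1 <- seq_len(s1) - 1L
    u2 <- seq_len(s2) - 1L
    pairs <- rbind(cbind(u1 + 1L, off3 + s1 - u1),
                   cbind(s1 + l1 + u2 + 1L, off4 + s2 - u2))
    truth <- rna_ss(structure_sequences(x), pairs, chain_ids = "A")
    list(structure = x, truth = truth)
  })
}

#' Per-atom-type mobility profile
#'
#' Relative coordinate-error scale per atom type used by the simulated
#' benchmark, emulating the backbone mobility gradient seen in experimental
#' B-factors and in coarse-grained model error: the phosphate, farthest from
#' the base-pairing interface, is placed least accurately; the glycosidic
#' nitrogen, closest, most accurately.
#'
#' @return Named numeric vector over [cssr_atom_types()].
#' @export
backbone_mobility <- function() {
  c("P" = 1.15, "O5'" = 1.10, "C5'" = 1.05, "C4'" = 1.00, "C3'" = 1.00,
    "O3'" = 1.05, "C2'" = 0.95, "O4'" = 0.95, "C1'" = 0.90, "N" = 0.85)
}

#' Add Gaussian coordinate noise
#'
#' Independent isotropic Gaussian displacement per atom, reproducible under
#' a seed; `sigma = 0` is the identity.  An optional per-atom-type scale
#' multiplies `sigma` (see [backbone_mobility()]); the default scale is 1
#' for every atom type.
#'
#' @param x An `rna_structure`.
#' @param sigma Base displacement SD per coordinate, Angstrom (>= 0).
#' @param seed Optional RNG seed (global RNG state is restored).
#' @param atom_scale Optional named numeric vector of per-atom-type scales.
#' @return A perturbed `rna_structure`.
#' @export
add_noise <- function(x, sigma, seed = NULL, atom_scale = NULL) {
  stopifnot(inherits(x, "rna_structure"), sigma >= 0)
  if (sigma == 0) return(x)
  scale <- rep(1, length(.ATOMS)); names(scale) <- .ATOMS
  if (!is.null(atom_scale)) scale[names(atom_scale)] <- atom_scale
  .with_seed(seed, {
    chains <- lapply(x$chains, function(ch) {
      n <- length(ch$bases)
      xyz <- ch$xyz
      for (a in .ATOMS) {
        eps <- matrix(stats::rnorm(3L * n, 0, sigma * scale[[a]]), n, 3L)
        xyz[[a]] <- xyz[[a]] + eps
      }
      new_rna_chain(ch$chain_id, ch$bases, xyz, resno = ch$resno,
                    insert = ch$insert, linked_prev = ch$linked_prev)
    })
    new_rna_structure(chains, source = x$source)
  })
}

#' Simulated benchmark ensemble
#'
#' Seeded collection of noisy hairpin fixtures with varied stem and loop
#' lengths and occasional wobble steps, emulating a benchmark of
#' single-chain structures of moderate size.  Noise is isotropic Gaussian
#' at `sigma`, scaled per atom type by `mobility` (see
#' [backbone_mobility()]).
#'
#' @param n_targets Number of fixtures.
#' @param sigma Base coordinate noise in Angstrom.
#' @param seed RNG seed for the whole ensemble.
#' @param mobility Per-atom-type noise scale.
#' @param gu_frac Wobble-step probability in stems.
#' @param stem_range,loop_range Integer ranges sampled per target.
#' @return List of fixtures, each a list with `structure` and `truth`.
#' @export
make_benchmark <- function(n_targets = 50L, sigma = 0.5, seed = 1L,
                           mobility = backbone_mobility(), gu_frac = 0.1,
                           stem_range = 6:14, loop_range = 4:8) {
  .with_seed(seed, {
    lapply(seq_len(n_targets), function(k) {
      fx <- make_hairpin(sample(stem_range, 1L), sample(loop_range, 1L),
                         gu_frac = gu_frac)
      if (sigma > 0)
        fx$structure <- add_noise(fx$structure, sigma,
                                  atom_scale = mobility)
      fx
    })
  })
}

#' Calibration ensemble
#'
#' Seeded set of noisy duplex fixtures (uniform noise, no mobility scaling)
#' with their ground-truth pairs, used to calibrate reference geometry
#' statistics; wobble steps are included so both pair classes are populated.
#'
#' @param n_structures Number of duplexes.
#' @param sigma Coordinate noise in Angstrom (uniform across atom types).
#' @param seed RNG seed.
#' @param gu_frac Wobble-step probability.
#' @param length_range Duplex lengths sampled per structure.
#' @return List with `structures` and `references`, suitable for
#'   [cssr_calibrate()].
#' @export
make_calibration_set <- function(n_structures = 80L, sigma = 0.5, seed = 2L,
                                 gu_frac = 0.15, length_range = 12:20) {
  .with_seed(seed, {
    fixtures <- lapply(seq_len(n_structures), function(k) {
      fx <- make_duplex(sample(length_range, 1L), gu_frac = gu_frac)
      if (sigma > 0) fx$structure <- add_noise(fx$structure, sigma)
      fx
    })
    list(structures = lapply(fixtures, `[[`, "structure"),
         references = lapply(fixtures, `[[`, "truth"))
  })
}
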
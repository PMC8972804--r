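# The geometry-statistics model: calibration, serialization, and the S3
# modelling interface (print / summary / coef / plot / predict).
#
# A fitted `cssr_params` object holds one (mean, sigma, n_obs) row per
# populated (pair class x atom type x sub-term) cell, estimated from
# annotated reference base pairs.  Distances use plain moments; angles and
# dihedrals use circular statistics, so calibration behaves correctly when a
# dihedral distribution straddles +/-180 degrees.

new_cssr_params <- function(table, sigma_floor, provenance = "") {
  stopifnot(is.data.frame(table),
            all(c("class", "atom", "kind", "mean", "sigma", "n_obs") %in%
                  names(table)))
  rownames(table) <- NULL
  structure(list(table = table, sigma_floor = sigma_floor,
                 provenance = provenance),
            class = "cssr_params")
}

#' Calibrate the base-pair geometry model
#'
#' Fits the Gaussian geometry statistics from annotated canonical base pairs:
#' for every reference pair, each evaluable sub-term (see
#' [cssr_term_kinds()]) is computed for each atom type and bucketed by
#' (pair class, atom type, sub-term); each bucket with at least two
#' observations yields a mean and standard deviation (circular statistics
#' for angles/dihedrals, plain moments for distances).  Pairs are
#' canonicalized to i < j before bucketing.  Sigma is clamped from below by
#' `sigma_floor`, which keeps scores defined when calibrating on noise-free
#' ideal geometry.
#'
#' @param structures An `rna_structure` or list of them.
#' @param reference_pairs Matching reference annotation per structure: an
#'   `rna_ss`, or a two-column matrix of global 1-based paired positions
#'   (or a list of such, one per structure).
#' @param sigma_floor Minimal allowed sigma in Angstrom/degrees
#'   (default 0.01).
#' @param trim Fraction (0 to < 0.5) trimmed from each tail of every bucket
#'   before computing moments; default 0 (plain moments).
#' @param provenance Free-text description of the calibration set.
#' @return A `cssr_params` model object.
#' @examples
#' fx <- make_duplex(10, seed = 1)
#' fit <- cssr_calibrate(fx$structure, fx$truth)
#' coef(fit)[1:3, ]
#' @export
cssr_calibrate <- function(structures, reference_pairs, sigma_floor = 1e-2,
                           trim = 0, provenance = "") {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  if (!is.list(reference_pairs) || inherits(reference_pairs, "rna_ss") ||
      is.matrix(reference_pairs))
    reference_pairs <- list(reference_pairs)
  stopifnot(length(structures) == length(reference_pairs),
            trim >= 0, trim < 0.5)
  buckets <- new.env(parent = emptyenv())
  total_pairs <- 0L
  for (s in seq_along(structures)) {
    x <- structures[[s]]
    idx <- structure_index(x)
    p <- reference_pairs[[s]]
    if (inherits(p, "rna_ss")) p <- p$pairs
    p <- matrix(as.integer(p), ncol = 2L)
    if (nrow(p) == 0L) next
    gi <- pmin(p[, 1L], p[, 2L])
    gj <- pmax(p[, 1L], p[, 2L])
    cls <- pair_class(idx$base[gi], idx$base[gj])
    if (anyNA(cls)) {
      k <- which(is.na(cls))[1L]
      stop(sprintf("reference pair (%d, %d) has non-canonical bases %s:%s",
                   gi[k], gj[k], idx$base[gi[k]], idx$base[gj[k]]),
           call. = FALSE)
    }
    total_pairs <- total_pairs + length(gi)
    for (a in .ATOMS) {
      terms <- .pair_terms(idx, gi, gj, a)
      for (k in .KINDS) {
        v <- terms[, k]
        ok <- !is.na(v)
        if (!any(ok)) next
        for (cl in unique(cls[ok])) {
          key <- paste(cl, a, k)
          sel <- ok & cls == cl
          buckets[[key]] <- c(buckets[[key]], v[sel])
        }
      }
    }
  }
  if (total_pairs == 0L)
    stop("empty reference set: no pairs to calibrate on", call. = FALSE)
  keys <- ls(buckets)
  rows <- list()
  for (key in keys) {
    v <- buckets[[key]]
    if (length(v) < 2L) next
    parts <- strsplit(key, " ")[[1L]]
    kind <- parts[3L]
    if (kind %in% .DIST_KINDS) {
      if (trim > 0) {
        qs <- stats::quantile(v, c(trim, 1 - trim), names = FALSE)
        v <- v[v >= qs[1L] & v <= qs[2L]]
        if (length(v) < 2L) next
      }
      m <- mean(v)
      sd0 <- stats::sd(v)
    } else {
      if (trim > 0) {
        cm <- circular_mean_sd(v)[["mean"]]
        dev <- ((v - cm + 180) %% 360) - 180
        qs <- stats::quantile(dev, c(trim, 1 - trim), names = FALSE)
        v <- v[dev >= qs[1L] & dev <= qs[2L]]
        if (length(v) < 2L) next
      }
      cm <- circular_mean_sd(v)
      m <- cm[["mean"]]
      sd0 <- cm[["sd"]]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      class = parts[1L], atom = parts[2L], kind = kind,
      mean = m, sigma = max(sd0, sigma_floor), n_obs = length(v),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$class, match(tab$atom, .ATOMS),
                   match(tab$kind, .KINDS)), , drop = FALSE]
  new_cssr_params(tab, sigma_floor,
                  if (nzchar(provenance)) provenance
                  else sprintf("calibrated on %d structure(s), %d reference pair(s)",
                               length(structures), total_pairs))
}

#' @export
print.cssr_params <- function(x, ...) {
  cat("cssr_params geometry model\n")
  cat("  cells:", nrow(x$table), " (classes:",
      paste(unique(x$table$class), collapse = ", "), ")\n")
  cat("  sigma floor:", x$sigma_floor, "\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
summary.cssr_params <- function(object, ...) {
  tab <- object$table
  agg <- stats::aggregate(tab$sigma, by = list(class = tab$class,
                                               atom = tab$atom),
                          FUN = stats::median)
  names(agg)[3L] <- "median_sigma"
  cat("cssr_params:", nrow(tab), "calibrated cells\n")
  cat("median sigma per (class, atom):\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' @export
coef.cssr_params <- function(object, ...) object$table

#' @export
plot.cssr_params <- function(x, ...) {
  tab <- x$table
  is_dist <- tab$kind %in% .DIST_KINDS
  graphics::par(mfrow = c(1, 2))
  graphics::boxplot(sigma ~ atom, data = tab[is_dist, ],
                    main = "distance sigma (A)", las = 2, xlab = "")
  graphics::boxplot(sigma ~ atom, data = tab[!is_dist, ],
                    main = "angle/dihedral sigma (deg)", las = 2, xlab = "")
  invisible(x)
}

#' Predict secondary structure from a fitted geometry model
#'
#' @param object A `cssr_params` model.
#' @param newdata An `rna_structure` (e.g. from [read_structure()] or the
#'   fixture generators).
#' @param ... Passed to [cssr_assign()] (`atoms`, `cutoff`,
#'   `min_separation`, `inter_chain`, ...).
#' @return An `rna_ss`.
#' @export
predict.cssr_params <- function(object, newdata, ...) {
  cssr_assign(newdata, object, ...)
}

.PARAMS_HEADER <- "# cssr-params v1"

#' Save / load a geometry-parameter table
#'
#' Tab-separated text with a versioned header line; `load_params(save_params(x))`
#' reproduces `x` exactly (numbers are written with full precision).
#'
#' @param params A `cssr_params`.
#' @param path File path.
#' @return `load_params` returns a `cssr_params`; `save_params` returns
#'   `path` invisibly.
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "cssr_params"))
  con <- file(path, "w")
  on.exit(close(con))
  cat(.PARAMS_HEADER, "\n", sep = "", file = con)
  cat(sprintf("# sigma_floor\t%s\n",
              formatC(params$sigma_floor, digits = 17, format = "g")),
      file = con)
  cat(sprintf("# provenance\t%s\n", params$provenance), file = con)
  cat("class\tatom\tkind\tmean\tsigma\tn_obs\n", file = con)
  tab <- params$table
  if (nrow(tab) > 0L)
    cat(sprintf("%s\t%s\t%s\t%s\t%s\t%d\n", tab$class, tab$atom, tab$kind,
                formatC(tab$mean, digits = 17, format = "g"),
                formatC(tab$sigma, digits = 17, format = "g"),
                tab$n_obs),
        sep = "", file = con)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) == 0L || trimws(ln[1L]) != .PARAMS_HEADER)
    stop("not a cssr parameter file (missing version header)", call. = FALSE)
  sigma_floor <- 1e-2
  provenance <- ""
  body_start <- 2L
  for (r in 2L:length(ln)) {
    if (startsWith(ln[r], "# sigma_floor")) {
      sigma_floor <- as.numeric(strsplit(ln[r], "\t")[[1L]][2L])
    } else if (startsWith(ln[r], "# provenance")) {
      f <- strsplit(ln[r], "\t")[[1L]]
      provenance <- if (length(f) > 1L) f[2L] else ""
    } else if (!startsWith(ln[r], "#")) {
      body_start <- r
      break
    }
  }
  hdr <- strsplit(ln[body_start], "\t")[[1L]]
  if (!identical(hdr, c("class", "atom", "kind", "mean", "sigma", "n_obs")))
    stop(sprintf("malformed parameter file at row %d: bad column header",
                 body_start), call. = FALSE)
  rows <- ln[-seq_len(body_start)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) == 0L) {
    tab <- data.frame(class = character(), atom = character(),
                      kind = character(), mean = numeric(),
                      sigma = numeric(), n_obs = integer())
    return(new_cssr_params(tab, sigma_floor, provenance))
  }
  fields <- strsplit(rows, "\t")
  for (r in seq_along(fields)) {
    f <- fields[[r]]
    if (length(f) != 6L || !(f[1L] %in% c("WC", "WOBBLE")) ||
        !(f[2L] %in% .ATOMS) || !(f[3L] %in% .KINDS) ||
        is.na(suppressWarnings(as.numeric(f[4L]))) ||
        is.na(suppressWarnings(as.numeric(f[5L]))))
      stop(sprintf("malformed parameter file at row %d",
                   body_start + r), call. = FALSE)
  }
  tab <- data.frame(
    class = vapply(fields, `[`, character(1), 1L),
    atom = vapply(fields, `[`, character(1), 2L),
    kind = vapply(fields, `[`, character(1), 3L),
    mean = as.numeric(vapply(fields, `[`, character(1), 4L)),
    sigma = as.numeric(vapply(fields, `[`, character(1), 5L)),
    n_obs = as.integer(vapply(fields, `[`, character(1), 6L)),
    stringsAsFactors = FALSE)
  new_cssr_params(tab, sigma_floor, provenance)
}

#' Packaged geometry parameters (synthetic calibration)
#'
#' The parameter table shipped with the package, calibrated on the bundled
#' synthetic noisy-helix ensemble (see [make_calibration_set()]), so the
#' package is usable with no external data.  For real structures, calibrate
#' on annotated experimental structures with [cssr_calibrate()] and pass the
#' result (or a file via [load_params()]) instead.
#'
#' @return A `cssr_params`.
#' @export
cssr_default_params <- function() {
  path <- system.file("extdata", "cssr_params_synthetic.tsv",
                      package = "cssr", mustWork = TRUE)
  load_params(path)
}
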
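# PDB / mmCIF input and PDB output for coarse-grained RNA chains.
#
# Parsing is delegated to bio3d (read.pdb / read.cif); this layer restricts
# atoms to the ten recognized types, maps modified residues to parent bases,
# resolves alternate locations by occupancy, and establishes chain adjacency.

# Residue-name -> parent base.  Standard names plus common RNA modifications;
# anything else with a ribose signature is kept with base NA (UNKNOWN) and
# can never enter a canonical pair.
.BASE_MAP <- c(
  A = "A", C = "C", G = "G", U = "U",
  RA = "A", RC = "C", RG = "G", RU = "U",
  ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U",
  # modified residues (parent base)
  PSU = "U", H2U = "U", `5MU` = "U", `4SU` = "U", OMU = "U", UR3 = "U",
  `3AU` = "U", `5BU` = "U", DHU = "U", UMP = "U",
  `1MA` = "A", `2MA` = "A", MA6 = "A", A2M = "A", MIA = "A", T6A = "A",
  RIA = "A", AMP = "A", `6IA` = "A",
  `1MG` = "G", `2MG` = "G", M2G = "G", `7MG` = "G", G7M = "G", OMG = "G",
  YG = "G", YYG = "G", QUO = "G", GMP = "G", GDP = "G", GTP = "G",
  `5MC` = "C", OMC = "C", `4AC` = "C", S4C = "C", CMP = "C", CBV = "C")

.DNA_RES <- c("DA", "DC", "DG", "DT", "DU", "DI", "T", "THY")

.PURINES <- c("A", "G")

# normalize an atom name: primes may be written as '*' in legacy files
.norm_atom <- function(elety) {
  e <- trimws(elety)
  e <- sub('^"(.*)"$', "\\1", e)      # mmCIF-quoted names like "C5'"
  e <- sub("^'(.*)'$", "\\1", e)
  gsub("*", "'", e, fixed = TRUE)
}

.cnd <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL))
}

#' Read an RNA structure from PDB or mmCIF
#'
#' Parses a structure file into coarse-grained RNA chains restricted to the
#' ten recognized atom types (see [cssr_atom_types()]).  The file dialect is
#' auto-detected from the extension (`.cif`/`.mmcif`) and, failing that, from
#' the content.  Purine N9 and pyrimidine N1 are both mapped to atom type
#' `"N"`.  Modified residues are mapped to their parent base via a bundled
#' table; unmappable residues with a ribose signature are kept with an
#' unknown base (excluded from pairing).  Alternate locations keep the
#' highest-occupancy conformer (ties: first).  Residues retaining zero
#' recognized atoms are dropped with a warning and break chain adjacency.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param model_index 1-based model to use from multi-model files.
#' @param atom_subset Optional character vector of atom types to retain
#'   (per-atom-type ablation, e.g. `"P"` for a phosphate trace).
#' @return An `rna_structure` (list of `rna_chain`).
#' @seealso [write_structure()], [subset_atoms()]
#' @export
read_structure <- function(path, model_index = 1L, atom_subset = NULL) {
  if (!file.exists(path))
    stop(.cnd("cssr_io_error", paste0("file not found: ", path)))
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  if (!is_cif && !grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) {
    head_txt <- tryCatch(readLines(path, n = 50L, warn = FALSE),
                         error = function(e) character())
    is_cif <- any(grepl("^data_|_atom_site\\.", head_txt))
  }
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE),
    error = function(e)
      stop(.cnd("cssr_parse_error",
                paste0("cannot parse ", path, ": ", conditionMessage(e)))),
    warning = function(w) suppressWarnings(
      if (is_cif) bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                           verbose = FALSE)))
  at <- pdb$atom
  # model selection: bio3d stores models as rows of pdb$xyz
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) >= 1L) {
    if (model_index > nrow(pdb$xyz))
      stop(.cnd("cssr_io_error",
                sprintf("model_index %d > %d models in %s",
                        model_index, nrow(pdb$xyz), path)))
    co <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- co[, 1L]; at$y <- co[, 2L]; at$z <- co[, 3L]
  } else if (model_index != 1L) {
    stop(.cnd("cssr_io_error", "single-model file: model_index must be 1"))
  }
  at$resid <- toupper(trimws(at$resid))
  at$elety <- .norm_atom(at$elety)
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  at$insert[is.na(at$insert)] <- ""
  if (is.null(at$o)) at$o <- 1
  at$o[is.na(at$o)] <- 1

  rna <- !(at$resid %in% .DNA_RES) &
    (at$resid %in% names(.BASE_MAP) |
       at$elety %in% c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'"))
  # an unmapped residue qualifies only via ribose primes and must not look
  # like an amino acid (CA backbone)
  res_key <- paste(at$chain, at$resno, at$insert, at$resid)
  known <- at$resid %in% names(.BASE_MAP)
  ca_res <- unique(res_key[at$elety == "CA"])
  rna <- rna & (known | !(res_key %in% ca_res))
  keep_res <- unique(res_key[rna])
  at <- at[res_key %in% keep_res, , drop = FALSE]
  if (nrow(at) == 0L)
    stop(.cnd("cssr_no_rna_error", paste0("no RNA residues found in ", path)))

  base <- unname(.BASE_MAP[at$resid])      # NA for unknown residues
  # map glycosidic nitrogen, then restrict to the ten types
  ety <- at$elety
  ety[ety == "N9" & !is.na(base) & base %in% .PURINES] <- "N"
  ety[ety == "N1" & !is.na(base) & !(base %in% .PURINES)] <- "N"
  at$elety <- ety
  at <- at[at$elety %in% .ATOMS, , drop = FALSE]
  if (!is.null(atom_subset)) {
    atom_subset <- match.arg(atom_subset, .ATOMS, several.ok = TRUE)
    at <- at[at$elety %in% atom_subset, , drop = FALSE]
  }
  if (nrow(at) == 0L)
    stop(.cnd("cssr_no_rna_error",
              paste0("no recognized RNA atoms retained from ", path)))

  # alt-loc resolution per (residue, atom): highest occupancy, ties first
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    akey <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(match(akey, unique(akey)), -at$o,
                 seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
             drop = FALSE]
    # restore file order of residues
    at <- at[order(match(paste(at$chain, at$resno, at$insert),
                         unique(paste(at$chain, at$resno, at$insert)))), ,
             drop = FALSE]
  }

  chains <- list()
  dropped <- 0L
  for (cid in unique(at$chain)) {
    sub <- at[at$chain == cid, , drop = FALSE]
    rk <- paste(sub$resno, sub$insert)
    ures <- unique(rk)
    n <- length(ures)
    bases <- character(n); resno <- integer(n); insert <- character(n)
    xyz <- lapply(.ATOMS, function(a) matrix(NA_real_, n, 3L))
    names(xyz) <- .ATOMS
    for (i in seq_len(n)) {
      rows <- sub[rk == ures[i], , drop = FALSE]
      bases[i] <- unname(.BASE_MAP[rows$resid[1L]])
      resno[i] <- rows$resno[1L]
      insert[i] <- rows$insert[1L]
      for (r in seq_len(nrow(rows))) {
        a <- rows$elety[r]
        if (is.na(xyz[[a]][i, 1L]))
          xyz[[a]][i, ] <- c(rows$x[r], rows$y[r], rows$z[r])
      }
    }
    has <- Reduce(`|`, lapply(xyz, function(m) !is.na(m[, 1L])))
    dropped <- dropped + sum(!has)
    if (!any(has)) next
    linked <- c(FALSE, rep(TRUE, n - 1L))
    if (n > 1L) {
      drop_before <- cumsum(!has)
      idx <- which(has)
      lk <- linked[has]
      if (length(idx) > 1L)
        lk[-1L] <- drop_before[idx[-1L]] == drop_before[idx[-length(idx)]]
      linked <- lk
    } else linked <- linked[has]
    chains[[length(chains) + 1L]] <- new_rna_chain(
      cid, bases[has],
      lapply(xyz, function(m) m[has, , drop = FALSE]),
      resno = resno[has], insert = insert[has], linked_prev = linked)
  }
  if (dropped > 0L)
    warning(sprintf("%s: dropped %d residue(s) with no recognized atoms (adjacency broken at gaps)",
                    basename(path), dropped), call. = FALSE)
  if (length(chains) == 0L)
    stop(.cnd("cssr_no_rna_error", paste0("no RNA residues found in ", path)))
  new_rna_structure(chains, source = path)
}

# PDB atom-name field: names of 1-3 characters start in column 14.
.pdb_atom_name <- function(a, base) {
  nm <- a
  if (a == "N") nm <- if (!is.na(base) && base %in% .PURINES) "N9" else "N1"
  sprintf(" %-3s", nm)
}

#' Write coarse-grained chains to a PDB file
#'
#' Emits fixed-width ATOM records (8.3 coordinate fields) with TER records
#' between chains; [read_structure()] round-trips the output to format
#' precision.
#'
#' @param x An `rna_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "rna_structure"))
  if (length(x$chains) == 0L) stop("empty chain list", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in x$chains) {
    for (i in seq_along(ch$bases)) {
      base <- ch$bases[i]
      resnm <- if (is.na(base)) "UNK" else base
      for (a in .ATOMS) {
        co <- ch$xyz[[a]][i, ]
        if (is.na(co[1L])) next
        serial <- serial + 1L
        elem <- substr(sub("[0-9']+$", "", a), 1L, 1L)
        cat(sprintf("ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s\n",
                    serial %% 100000L, .pdb_atom_name(a, base), resnm,
                    substr(ch$chain_id, 1L, 1L), ch$resno[i] %% 10000L,
                    ifelse(ch$insert[i] == "", " ", ch$insert[i]),
                    co[1L], co[2L], co[3L], 1, 0, elem),
            file = con)
      }
    }
    serial <- serial + 1L
    cat(sprintf("TER   %5d      %3s %1s%4d\n", serial %% 100000L,
                ifelse(is.na(ch$bases[length(ch$bases)]), "UNK",
                       ch$bases[length(ch$bases)]),
                substr(ch$chain_id, 1L, 1L),
                ch$resno[length(ch$bases)] %% 10000L), file = con)
  }
  cat("END\n", file = con)
  invisible(path)
}
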
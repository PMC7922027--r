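# Structure input: reading C-alpha traces from PDB/mmCIF files,
# chain/residue-range selection, and a coarse secondary-structure state
# from C-alpha geometry alone. Only the trace is kept: all downstream
# geometry (superposition, core extraction, scoring) works on C-alpha
# coordinates, which also keeps low-resolution entries usable.

#' Construct a structure model
#'
#' An ordered C-alpha trace for one chain: per residue the author
#' residue number, one-letter amino acid (X for nonstandard), C-alpha
#' coordinates and a secondary-structure state in {H, E, C}. Residue
#' positions are dense; the 0-based `linear_index` used in dumps is the
#' row number minus one.
#'
#' @param id structure identifier (e.g. PDB id plus chain).
#' @param ca numeric n x 3 C-alpha coordinate matrix (Angstrom).
#' @param aa character vector of one-letter codes.
#' @param author_seq_id integer author residue numbers.
#' @param ss secondary-structure states (`H`, `E`, `C`); assigned from
#'   geometry via [assign_secondary_structure()] when `NULL`.
#' @param family_label optional family annotation.
#' @param source_meta provenance list (file, chain, range, skipped
#'   residue count).
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(id, ca, aa, author_seq_id = seq_len(nrow(ca)),
                            ss = NULL, family_label = NULL,
                            source_meta = list()) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  stopifnot(is.character(id), length(id) == 1, ncol(ca) == 3,
            length(aa) == n, length(author_seq_id) == n)
  if (!all(is.finite(ca))) stop("non-finite C-alpha coordinates")
  if (!all(aa %in% c(AA1, "X"))) stop("amino acids must be one-letter codes or X")
  dimnames(ca) <- NULL
  m <- structure(list(id = id, ca = ca, aa = as.character(aa),
                      author_seq_id = as.integer(author_seq_id),
                      ss = ss, family_label = family_label,
                      source_meta = source_meta),
                 class = "structure_model")
  if (is.null(ss)) m <- assign_secondary_structure(m)
  else stopifnot(length(ss) == n, all(ss %in% c("H", "E", "C")))
  m
}

#' @export
print.structure_model <- function(x, ...) {
  n <- nrow(x$ca)
  cat(sprintf("Structure model '%s': %d residues (%d-%d)\n",
              x$id, n, x$author_seq_id[1], x$author_seq_id[n]))
  tb <- table(factor(x$ss, c("H", "E", "C")))
  cat(sprintf("  secondary structure: %d H, %d E, %d C\n",
              tb["H"], tb["E"], tb["C"]))
  if (!is.null(x$family_label)) cat("  family:", x$family_label, "\n")
  invisible(x)
}

#' @export
length.structure_model <- function(x) nrow(x$ca)

#' Read a C-alpha trace from a PDB or mmCIF file
#'
#' Parses the file (format chosen from the extension: `.cif`/`.mmcif`
#' for mmCIF, PDB otherwise), keeps the first model and first alternate
#' location, selects one chain and an optional inclusive author-numbered
#' residue range, and returns the ordered C-alpha trace with secondary
#' structure assigned from geometry. Hetero records are dropped; protein
#' residues lacking a C-alpha atom are skipped and counted in
#' `source_meta$n_missing_ca`.
#'
#' @param path path to the structure file.
#' @param chain chain identifier; an error names the available chains if
#'   absent.
#' @param residue_range optional `c(start, end)` inclusive author-number
#'   interval.
#' @param id identifier for the model; defaults to file base name plus
#'   chain.
#' @param family_label optional family annotation.
#' @param min_length minimum residue count accepted after selection.
#' @return a [structure_model].
#' @export
read_structure <- function(path, chain = NULL, residue_range = NULL,
                           id = NULL, family_label = NULL, min_length = 30) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
         else bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- sort(unique(at$chain))
  if (is.null(chain)) {
    if (length(chains) > 1)
      stop("file has chains {", paste(chains, collapse = ", "),
           "}; pick one with `chain`")
    chain <- chains[1]
  }
  if (!chain %in% chains)
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  # first alternate location only
  alts <- unique(at$alt)
  keep_alt <- c(NA, "", sort(setdiff(alts, c(NA, "")))[1])
  at <- at[at$alt %in% keep_alt | is.na(at$alt), , drop = FALSE]
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2)
    at <- at[at$resno >= residue_range[1] & at$resno <= residue_range[2], ,
             drop = FALSE]
    if (nrow(at) == 0)
      stop("no residues left in chain ", chain, " after range [",
           residue_range[1], ", ", residue_range[2], "]")
  }
  res_key <- paste(at$resno, at$insert)
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
  n_missing <- length(setdiff(unique(res_key), paste(ca$resno, ca$insert)))
  if (n_missing > 0)
    message(n_missing, " residue(s) without a C-alpha skipped in ",
            basename(path), " chain ", chain)
  ord <- order(ca$resno, ca$insert)
  ca <- ca[ord, , drop = FALSE]
  if (nrow(ca) < min_length)
    stop("only ", nrow(ca), " residues selected; minimum is ", min_length)
  aa <- bio3d::aa321(ca$resid)
  aa[!aa %in% AA1] <- "X"
  if (is.null(id))
    id <- paste0(sub("\\.[^.]*$", "", basename(path)), "_", chain)
  structure_model(
    id = id, ca = as.matrix(ca[, c("x", "y", "z")]), aa = aa,
    author_seq_id = ca$resno, family_label = family_label,
    source_meta = list(file = path, chain = chain,
                       range = residue_range, n_missing_ca = n_missing))
}

#' Select a residue range from a model
#'
#' Restricts a model to an inclusive author-numbered interval. Ranges
#' compose: selecting `[a, b]` then `[c, d]` equals selecting
#' `[max(a, c), min(b, d)]`.
#'
#' @param model a [structure_model].
#' @param residue_range `c(start, end)` inclusive author numbers.
#' @return the restricted [structure_model] (secondary structure is
#'   re-assigned on the selection).
#' @export
select_range <- function(model, residue_range) {
  keep <- model$author_seq_id >= residue_range[1] &
    model$author_seq_id <= residue_range[2]
  if (!any(keep)) stop("empty selection")
  structure_model(model$id, model$ca[keep, , drop = FALSE], model$aa[keep],
                  model$author_seq_id[keep], family_label = model$family_label,
                  source_meta = model$source_meta)
}

# P-SEA-style thresholds on C-alpha pseudo-distances. An ideal helix
# (rise 1.5 A, 100 deg/residue, radius 2.3 A) has d(i,i+2) = 5.43 A and
# d(i,i+3) = 5.05 A; an extended strand at 3.8 A spacing has
# d(i,i+2) = 6.6-7.6 A and d(i,i+3) >= 8.5 A.
SS_DEFAULTS <- list(
  helix_d2 = c(4.8, 6.2), helix_d3 = c(4.3, 6.0),
  strand_d2 = c(6.3, 8.2), strand_d3_min = 8.5,
  chain_break = 4.5
)

#' Assign secondary structure from C-alpha geometry
#'
#' Coarse three-state assignment (`H` helix, `E` strand, `C` coil) from
#' windowed C-alpha pseudo-distances, in the style of C-alpha-trace
#' assignment methods. A helix-like step at residue i requires
#' `d(i, i+3)` and both flanking `d(., .+2)` distances in helical
#' ranges; a strand-like step requires extended `d(., .+2)` distances
#' and `d(i, i+3)` beyond the helical regime. Steps label their covered
#' residues; helix takes precedence; termini and short segments default
#' to coil. Consecutive C-alpha distances above the chain-break
#' threshold (4.5 A) split the assignment windows. The assignment
#' depends only on internal distances, hence is invariant under rigid
#' motion.
#'
#' @param model a [structure_model] (at least 5 residues).
#' @param thresholds list of threshold overrides (see
#'   `corephylo:::SS_DEFAULTS`).
#' @return the model with `ss` replaced.
#' @export
assign_secondary_structure <- function(model, thresholds = list()) {
  th <- utils::modifyList(SS_DEFAULTS, thresholds)
  x <- model$ca
  n <- nrow(x)
  if (n < 5) stop("need at least 5 residues to assign secondary structure")
  d1 <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-n, , drop = FALSE])^2))
  seg <- cumsum(c(1, as.numeric(d1 > th$chain_break)))
  ss <- rep("C", n)
  dk <- function(k) {
    c(sqrt(rowSums((x[seq_len(n - k) + k, , drop = FALSE] -
                      x[seq_len(n - k), , drop = FALSE])^2)), rep(NA, k))
  }
  d2 <- dk(2); d3 <- dk(3)
  same_seg <- function(i, k) seg[i] == seg[min(i + k, n)]
  for (i in seq_len(n - 3)) {
    if (!same_seg(i, 3)) next
    helix <- d3[i] >= th$helix_d3[1] && d3[i] <= th$helix_d3[2] &&
      d2[i] >= th$helix_d2[1] && d2[i] <= th$helix_d2[2] &&
      d2[i + 1] >= th$helix_d2[1] && d2[i + 1] <= th$helix_d2[2]
    if (helix) {
      ss[i:(i + 3)] <- "H"
    } else {
      strand <- d3[i] >= th$strand_d3_min &&
        d2[i] >= th$strand_d2[1] && d2[i] <= th$strand_d2[2] &&
        d2[i + 1] >= th$strand_d2[1] && d2[i + 1] <= th$strand_d2[2]
      if (strand) {
        j <- i:(i + 3)
        ss[j][ss[j] != "H"] <- "E"
      }
    }
  }
  model$ss <- ss
  model
}

#' Write a model as a TSV table
#'
#' Normalized dump with columns `linear_index` (0-based),
#' `author_seq_id`, `aa`, `x`, `y`, `z`, `ss`.
#'
#' @param model a [structure_model].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_structure_tsv <- function(model, path) {
  df <- data.frame(linear_index = seq_len(nrow(model$ca)) - 1L,
                   author_seq_id = model$author_seq_id, aa = model$aa,
                   x = model$ca[, 1], y = model$ca[, 2], z = model$ca[, 3],
                   ss = model$ss)
  write_tsv(df, path)
}
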
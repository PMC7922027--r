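# Positionally conserved residues around core columns: a column is
# conserved for amino acid `a` when every structure carries `a` either
# at its core residue or at an immediate sequence neighbor within the
# window. This is how catalytic residues (e.g. the universal polymerase
# aspartates) surface even when the structural equivalences themselves
# are one or two positions off between distant folds.

#' Positionally and chemically conserved sites
#'
#' Scans every core column for amino acids identical across all
#' structures within a sequence window of `±window` residues around the
#' structurally equivalent position. All qualifying amino acids per
#' column are reported (alphabetically); for each structure the offset
#' of smallest magnitude is recorded (preference 0, then -1, then +1).
#' Window neighbors are sequence neighbors in the same chain, not
#' spatial neighbors; `X` never counts as identical. With `window = 0`
#' the result is exactly the strict-identity columns.
#'
#' @param core a `core_set`.
#' @param models list of [structure_model] objects covered by the core.
#' @param window non-negative integer window half-width.
#' @return data frame with one row per (column, amino acid): `column_id`,
#'   `aa`, then per structure the matched author residue number and
#'   offset.
#' @export
conserved_positions <- function(core, models, window = 1) {
  stopifnot(window >= 0)
  ids <- colnames(core$columns)
  models <- models[match(ids, vapply(models, `[[`, character(1), "id"))]
  if (anyNA(names(models))) stop("core references structures not supplied")
  offsets <- if (window == 0) 0L else
    as.integer(c(0, as.vector(rbind(-seq_len(window), seq_len(window)))))
  rows <- list()
  for (ci in seq_len(core$size)) {
    # amino acids seen within the window in every structure
    windowed <- lapply(seq_along(ids), function(k) {
      m <- models[[k]]
      i <- core$columns[ci, k]
      j <- i + offsets
      j <- j[j >= 1 & j <= length(m$aa)]
      setNames(m$aa[j], j)
    })
    shared <- Reduce(intersect, lapply(windowed, unique))
    shared <- sort(setdiff(shared, "X"))
    for (a in shared) {
      row <- data.frame(column_id = core$column_id[ci], aa = a)
      for (k in seq_along(ids)) {
        m <- models[[k]]
        i <- core$columns[ci, k]
        hit <- offsets[vapply(offsets, function(o) {
          j <- i + o
          j >= 1 && j <= length(m$aa) && m$aa[j] == a
        }, logical(1))][1]
        row[[paste0(ids[k], "_resno")]] <- m$author_seq_id[i + hit]
        row[[paste0(ids[k], "_offset")]] <- hit
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(column_id = character(0), aa = character(0))
  } else {
    out <- do.call(rbind, rows)
  }
  out
}
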
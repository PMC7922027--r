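# Shared small helpers: amino-acid alphabets, rigid-motion algebra,
# deterministic local RNG.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

# conventional physicochemical partition; X never matches anything
AA_CLASS_SETS <- list(
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
  polar       = c("S", "T", "N", "Q", "Y", "G"),
  positive    = c("K", "R", "H"),
  negative    = c("D", "E"),
  special     = "P"
)

#' Amino-acid class codes
#'
#' Maps one-letter amino-acid codes to a coarse physicochemical class:
#' hydrophobic (AVLIMFWC), polar (STNQYG), positive (KRH), negative (DE),
#' special (P). Unknown residues (`X`) get class 0 and never match.
#'
#' @param aa character vector of one-letter codes.
#' @return integer vector of class codes (0 for unknown).
#' @export
aa_class <- function(aa) {
  out <- integer(length(aa))
  for (k in seq_along(AA_CLASS_SETS))
    out[aa %in% AA_CLASS_SETS[[k]]] <- k
  out
}

ss_code <- function(ss) {
  out <- match(ss, c("H", "E", "C"))
  if (anyNA(out)) stop("secondary-structure states must be H, E or C")
  out
}

# random unit vector / rotation helpers (caller controls the RNG state)
random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

rotation_from_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  rotation_from_axis_angle(random_unit_vector(), runif(1, 0, 2 * pi))
}

rotation_angle_deg <- function(R1, R2) {
  c1 <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(max(-1, min(1, c1))) * 180 / pi
}

apply_rigid <- function(x, R, t) {
  sweep(x %*% t(R), 2, -as.numeric(t))
}

compose_rigid <- function(R2, t2, R1, t1) {
  # first (R1, t1) then (R2, t2)
  list(R = R2 %*% R1, t = as.numeric(R2 %*% t1 + t2))
}

invert_rigid <- function(R, t) {
  list(R = t(R), t = as.numeric(-t(R) %*% t))
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
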
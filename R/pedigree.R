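# Pedigree handling and the numerator relationship matrix.

#' Construct a pedigree object
#'
#' Validates animal/sire/dam triples, adds phantom parents that appear only
#' as sire or dam as founders, and stores the records in a topological order
#' (parents before offspring).
#'
#' @param animal character vector of animal ids.
#' @param sire,dam character vectors of parent ids; `NA` marks an unknown
#'   parent.
#' @return An object of class `"pedigree"`: a list with elements `animal`,
#'   `sire`, `dam` (character vectors in topological order, `NA` for unknown
#'   parents), `sire_idx`/`dam_idx` (integer indices into `animal`, 0 for
#'   unknown) and `n_generations` (maximum ancestor depth, founders = 0).
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  dup <- animal[duplicated(animal)]
  if (length(dup))
    stop("duplicate animal id(s): ", paste(unique(dup), collapse = ", "))

  # phantom parents: seen only as sire/dam, appended as founders
  parents <- unique(c(sire, dam))
  phantom <- setdiff(parents[!is.na(parents)], animal)
  if (length(phantom)) {
    animal <- c(animal, phantom)
    sire <- c(sire, rep(NA_character_, length(phantom)))
    dam <- c(dam, rep(NA_character_, length(phantom)))
  }

  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L

  # Kahn topological sort; depth = 1 + max(parent depth)
  depth <- rep(NA_integer_, n)
  pending <- rep(TRUE, n)
  repeat {
    ready <- which(pending &
                     (si == 0L | !is.na(depth[pmax(si, 1L)])) &
                     (di == 0L | !is.na(depth[pmax(di, 1L)])))
    if (!length(ready)) break
    ds <- ifelse(si[ready] == 0L, -1L, depth[pmax(si[ready], 1L)])
    dd <- ifelse(di[ready] == 0L, -1L, depth[pmax(di[ready], 1L)])
    depth[ready] <- pmax(ds, dd) + 1L
    pending[ready] <- FALSE
  }
  if (any(pending))
    stop("pedigree cycle detected involving: ",
         paste(animal[pending], collapse = ", "))

  ord <- order(depth, seq_len(n))
  animal <- animal[ord]; sire <- sire[ord]; dam <- dam[ord]
  si <- match(sire, animal); di <- match(dam, animal)
  si[is.na(si)] <- 0L; di[is.na(di)] <- 0L

  structure(list(animal = animal, sire = sire, dam = dam,
                 sire_idx = si, dam_idx = di,
                 n_generations = max(depth)),
            class = "pedigree")
}

#' Read a pedigree from a delimited file
#'
#' Expects a 3-column header file (animal, sire, dam). Values matching
#' `unknown` are treated as unknown parents.
#'
#' @param path path to a CSV (or other delimited) file.
#' @param unknown character vector of codes marking an unknown parent.
#' @param sep field separator.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path, unknown = c("0", "NA", ""), sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 3)
    stop("pedigree file must have at least 3 columns (animal, sire, dam)")
  s <- df[[2]]; d <- df[[3]]
  s[s %in% unknown] <- NA_character_
  d[d %in% unknown] <- NA_character_
  pedigree(df[[1]], s, d)
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(x$sire_idx == 0L & x$dam_idx == 0L)
  cat("pedigree:", length(x$animal), "animals (", founders, "founders ),",
      x$n_generations, "generations deep\n")
  invisible(x)
}

#' Prune a pedigree to a set of animals and their ancestors
#'
#' Restricting the relationship matrix to phenotyped animals gives identical
#' values whether computed on the full or the pruned pedigree, so scans only
#' need the ancestor closure of the phenotyped set.
#'
#' @param ped a [pedigree()].
#' @param ids animal ids to keep (their ancestors are kept automatically).
#' @return A pruned [pedigree()].
#' @export
prune_pedigree <- function(ped, ids) {
  miss <- setdiff(ids, ped$animal)
  if (length(miss))
    stop("ids not in pedigree: ", paste(miss, collapse = ", "))
  keep <- ped$animal %in% ids
  # sweep from youngest to oldest; order guarantees parents come earlier
  for (i in rev(seq_along(ped$animal))) {
    if (keep[i]) {
      if (ped$sire_idx[i] > 0L) keep[ped$sire_idx[i]] <- TRUE
      if (ped$dam_idx[i] > 0L) keep[ped$dam_idx[i]] <- TRUE
    }
  }
  pedigree(ped$animal[keep], ped$sire[keep], ped$dam[keep])
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the additive (numerator) relationship matrix A with inbreeding:
#' `a(i,i) = 1 + 0.5 a(s,d)` and `a(i,j) = 0.5 (a(j,s) + a(j,d))` for `j`
#' ordered before `i`; unknown parents contribute 0 and are treated as
#' unrelated non-inbred founders.
#'
#' @param ped a [pedigree()].
#' @return A symmetric numeric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  n <- length(ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  si <- ped$sire_idx; di <- ped$dam_idx
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + A[j, s]
      if (d > 0L) row <- row + A[j, d]
      row <- 0.5 * row
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- if (s > 0L && d > 0L) 1 + 0.5 * A[s, d] else 1
  }
  A
}

#' Extract a sub-relationship-matrix
#'
#' Restricts and reorders the rows/columns of a relationship matrix to the
#' given animal ids.
#'
#' @param A matrix from [build_A()] (dimnames are animal ids).
#' @param ids animal ids to keep, in the desired order.
#' @return The `ids` x `ids` block of `A`.
#' @export
submatrix_A <- function(A, ids) {
  miss <- setdiff(ids, rownames(A))
  if (length(miss))
    stop("ids not present in relationship matrix: ",
         paste(miss, collapse = ", "))
  A[ids, ids, drop = FALSE]
}

#' Write a relationship matrix as TSV
#'
#' Dense export with an id header row and column, mainly for debugging.
#'
#' @param A matrix from [build_A()].
#' @param path output path.
#' @export
write_A_tsv <- function(A, path) {
  df <- data.frame(id = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
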
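#' Read and validate a pedigree file
#'
#' Reads a three-column pedigree (animal, sire, dam), validates it, and
#' returns the records topologically sorted so that every known parent
#' precedes its offspring. Unknown parents are coded as \code{"0"} or an
#' empty field.
#'
#' @param path Path to a delimited text file with columns animal, sire, dam.
#'   A header line is detected automatically (a first row whose parent
#'   columns are neither valid IDs seen elsewhere nor \code{"0"}/empty is
#'   treated as a header when it contains no digits).
#' @return An object of class \code{"pedigree"}: a data frame with columns
#'   \code{animal}, \code{sire}, \code{dam} (character; \code{"0"} =
#'   unknown), topologically sorted, with attribute \code{founder_added}
#'   listing any parent IDs that had to be promoted to founders.
#' @details Parents referenced but never listed as animals are added as
#'   founders with a warning. Duplicate animal IDs and parent cycles are
#'   errors. The sort is stable: among animals whose parents are already
#'   placed, original file order is preserved.
#' @seealso [numerator_relationship_matrix()], [inbreeding_coefficients()]
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = FALSE, sep = detect_sep(path),
                           colClasses = "character", fill = TRUE,
                           strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(raw) < 3L)
    stop("pedigree file must have three columns: animal, sire, dam")
  raw <- raw[, 1:3]
  names(raw) <- c("animal", "sire", "dam")
  # optional header: first row with no digits anywhere
  if (nrow(raw) > 0L && !any(grepl("[0-9]", unlist(raw[1L, ]))))
    raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) stop("pedigree file contains no records")
  as_pedigree(raw$animal, raw$sire, raw$dam)
}

#' Construct a pedigree object from ID vectors
#'
#' @param animal,sire,dam Character (or coercible) vectors of equal length;
#'   \code{"0"}, \code{""} or \code{NA} mark an unknown parent.
#' @return A topologically sorted \code{"pedigree"} data frame.
#' @export
as_pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- normalize_unknown(as.character(sire))
  dam <- normalize_unknown(as.character(dam))
  if (anyDuplicated(animal)) {
    dupe <- animal[duplicated(animal)][1L]
    stop("duplicate animal ID in pedigree: ", dupe)
  }
  parents <- setdiff(c(sire, dam), c(animal, "0"))
  if (length(parents)) {
    warning("parent(s) never defined as animals, added as founders: ",
            paste(parents, collapse = ", "))
    animal <- c(parents, animal)
    sire <- c(rep("0", length(parents)), sire)
    dam <- c(rep("0", length(parents)), dam)
  }
  ord <- toposort_pedigree(animal, sire, dam)
  ped <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  structure(ped, class = c("pedigree", "data.frame"),
            founder_added = parents)
}

normalize_unknown <- function(x) {
  x[is.na(x) | x == "" | x == "0"] <- "0"
  x
}

# Kahn's algorithm, stable in input order; errors with the offending cycle.
toposort_pedigree <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(sire == "0", NA_integer_, idx[sire])
  di <- ifelse(dam == "0", NA_integer_, idx[dam])
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
                     (is.na(di) | placed[ifelse(is.na(di), 1L, di)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) {
    left <- animal[!placed]
    stop("pedigree contains a parent cycle involving: ",
         paste(left, collapse = ", "))
  }
  ord
}

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A from a
#' topologically sorted pedigree: founders have \eqn{A_{jj} = 1}; with both
#' parents s, d known \eqn{A_{jj} = 1 + 0.5 A_{sd}}; off-diagonals
#' \eqn{A_{jk} = 0.5 (A_{ks} + A_{kd})} with unknown parents contributing 0.
#'
#' @param ped A \code{"pedigree"} object.
#' @return A symmetric numeric matrix with animal IDs as dimnames.
#' @export
numerator_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      k <- seq_len(j - 1L)
      as_ <- if (s > 0L) A[k, s] else 0
      ad_ <- if (d > 0L) A[k, d] else 0
      A[k, j] <- A[j, k] <- 0.5 * (as_ + ad_)
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes per-animal inbreeding coefficients F directly from the pedigree
#' without forming A, using the ancestor-tracing algorithm on the
#' \eqn{A = LDL'} decomposition. Animals with any unknown parent have
#' \eqn{F = 0} (unknown parents are unrelated, non-inbred base animals).
#'
#' @param ped A \code{"pedigree"} object.
#' @return Named numeric vector of inbreeding coefficients in animal order.
#' @references Meuwissen, T.H.E. and Luo, Z. (1992) Computing inbreeding
#'   coefficients in large populations. Genet Sel Evol 24:305-313.
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  FF <- numeric(n)
  # within-family variances d_j, depend only on parents' F (already known)
  Dv <- numeric(n)
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    Fs <- if (s > 0L) FF[s] else 0
    Fd <- if (d > 0L) FF[d] else 0
    npar <- (s > 0L) + (d > 0L)
    Dv[j] <- switch(npar + 1L, 1, 0.75 - 0.25 * (Fs + Fd),
                    0.5 - 0.25 * (Fs + Fd))
    if (s == 0L || d == 0L) { FF[j] <- 0; next }
    # A_jj = sum over ancestors k of L_jk^2 d_k, traced from j downwards
    Lc <- numeric(j)
    Lc[j] <- 1
    ajj <- 0
    for (k in j:1) {
      if (Lc[k] == 0) next
      ajj <- ajj + Lc[k]^2 * Dv[k]
      if (si[k] > 0L) Lc[si[k]] <- Lc[si[k]] + 0.5 * Lc[k]
      if (di[k] > 0L) Lc[di[k]] <- Lc[di[k]] + 0.5 * Lc[k]
    }
    FF[j] <- ajj - 1
  }
  names(FF) <- ped$animal
  FF
}

#' Extract the genotyped-animal block of a relationship matrix
#'
#' @param A Symmetric relationship matrix with ID dimnames.
#' @param genotyped_ids Ordered character vector of genotyped-animal IDs;
#'   this order defines the row/column order of the result.
#' @return The submatrix \code{A[genotyped_ids, genotyped_ids]}.
#' @export
subset_A22 <- function(A, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  if (!length(genotyped_ids)) stop("genotyped_ids must be non-empty")
  missing <- setdiff(genotyped_ids, rownames(A))
  if (length(missing))
    stop("genotyped ID(s) not present in relationship matrix: ",
         paste(missing, collapse = ", "))
  A[genotyped_ids, genotyped_ids, drop = FALSE]
}

#' Lower Cholesky factor of a relationship matrix
#'
#' Computes the lower-triangular L with \eqn{LL' = A_{22}}. If the plain
#' factorization fails, a small ridge (jitter) is added to the diagonal,
#' escalating along a fixed ladder; the jitter actually used is attached as
#' an attribute and reported via message.
#'
#' @param A22 Symmetric positive definite matrix.
#' @param jitter Ladder of ridge values to try, in order. The default starts
#'   at 0 (no jitter).
#' @return Lower-triangular matrix L with attribute \code{"jitter"}.
#' @export
cholesky_factor <- function(A22, jitter = c(0, 1e-10, 1e-8, 1e-6)) {
  stopifnot(is.matrix(A22), nrow(A22) == ncol(A22))
  if (max(abs(A22 - t(A22))) > 1e-8 * max(1, max(abs(A22))))
    stop("matrix is not symmetric")
  for (j in jitter) {
    R <- tryCatch(chol(A22 + diag(j, nrow(A22))), error = function(e) NULL)
    if (!is.null(R)) {
      if (j > 0) message("cholesky_factor: used jitter ", j)
      L <- t(R)
      dimnames(L) <- dimnames(A22)
      attr(L, "jitter") <- j
      return(L)
    }
  }
  stop("matrix is not positive definite even after maximum jitter ",
       max(jitter))
}

#' Write a relationship matrix to a dense CSV file
#'
#' @param A Matrix with ID dimnames.
#' @param path Output file path.
#' @export
write_relationship_csv <- function(A, path) {
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
  invisible(path)
}

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl(",", line)) "," else ""
}
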
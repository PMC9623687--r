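#' Read a genotype matrix file
#'
#' Reads an allele-count matrix (animals in rows, biallelic markers in
#' columns) with a leading animal-ID column. Comma or whitespace delimiters
#' are auto-detected. Missing genotypes coded \code{5} or \code{NA} are
#' imputed to the column mean rounded to the nearest integer count.
#'
#' @param path Path to the genotype file.
#' @return A \code{"genotype_matrix"}: integer matrix of allele counts in
#'   \{0,1,2\} with animal IDs as rownames and marker IDs (\code{m1...mk} if
#'   the file has no header) as colnames; attribute \code{"n_imputed"}
#'   records how many entries were imputed.
#' @export
read_genotypes <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = FALSE, sep = detect_sep(path),
                           colClasses = "character", strip.white = TRUE)
  if (ncol(raw) < 2L) stop("genotype file must have ID plus marker columns")
  # optional header row: non-numeric marker fields
  header <- NULL
  first <- unlist(raw[1L, -1L])
  if (any(is.na(suppressWarnings(as.numeric(first))))) {
    header <- unlist(raw[1L, -1L], use.names = FALSE)
    raw <- raw[-1L, , drop = FALSE]
  }
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate animal ID in genotype file: ", ids[duplicated(ids)][1L])
  M <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (!is.matrix(M)) M <- matrix(M, nrow = nrow(raw))
  M[M == 5] <- NA
  bad <- which(!is.na(M) & !(M %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid genotype value at row ", bad[1, 1], " (animal ",
         ids[bad[1, 1]], "), marker column ", bad[1, 2],
         ": entries must be 0, 1, 2 or missing")
  }
  n_imputed <- sum(is.na(M))
  if (n_imputed > 0L) {
    for (k in which(colSums(is.na(M)) > 0L)) {
      mk <- mean(M[, k], na.rm = TRUE)
      if (is.nan(mk)) mk <- 0
      M[is.na(M[, k]), k] <- round(mk)
    }
    message("read_genotypes: imputed ", n_imputed,
            " missing genotype(s) to rounded column means")
  }
  storage.mode(M) <- "integer"
  dimnames(M) <- list(ids,
                      if (is.null(header)) paste0("m", seq_len(ncol(M)))
                      else header)
  structure(M, n_imputed = n_imputed, class = c("genotype_matrix", "matrix",
                                                "array"))
}

#' Observed allele frequencies
#'
#' Frequency of the counted (B2) allele at each marker,
#' \eqn{p_k = \sum_i x_{ik} / (2n)}.
#'
#' @param G Allele-count matrix (animals x markers, entries 0/1/2).
#' @return Named numeric vector of frequencies in \eqn{[0,1]}.
#' @export
allele_frequencies <- function(G) {
  stopifnot(nrow(G) >= 1L)
  colMeans(G) / 2
}

#' Centered and scaled marker matrix (VanRaden methods 1 and 2)
#'
#' Builds \eqn{Z_c} with entries \eqn{(x_{ik} - 2p_k)/\sqrt{S_k}}. Method 1
#' uses the single global scale \eqn{S_k = \sum_l 2 p_l (1 - p_l)}; method 2
#' scales each marker by \eqn{S_k = m \cdot 2 p_k (1 - p_k)}.
#'
#' Monomorphic markers (\eqn{p_k} 0 or 1) center to exactly zero and are
#' retained under method 1; under method 2 they would divide by zero and are
#' dropped with a warning (the \eqn{m} in \eqn{S_k} is the number of markers
#' kept).
#'
#' @param G Allele-count matrix (animals x markers).
#' @param p Allele frequencies; defaults to the observed frequencies of
#'   \code{G}. Supplying base-population frequencies is preferred when they
#'   are known.
#' @param method \code{"vanraden1"} (global scale) or \code{"vanraden2"}
#'   (per-marker scale).
#' @return Numeric matrix \eqn{Z_c} with attributes \code{"method"},
#'   \code{"p"} (frequencies used, for kept markers) and
#'   \code{"kept_markers"}.
#' @export
center_scale <- function(G, p = allele_frequencies(G),
                         method = c("vanraden1", "vanraden2")) {
  method <- match.arg(method)
  stopifnot(length(p) == ncol(G))
  mono <- p <= 0 | p >= 1
  if (all(mono)) stop("all markers are monomorphic; cannot scale")
  keep <- seq_along(p)
  if (method == "vanraden2" && any(mono)) {
    warning("center_scale: dropped ", sum(mono),
            " monomorphic marker(s) under vanraden2 scaling")
    keep <- which(!mono)
  }
  Gk <- G[, keep, drop = FALSE]
  pk <- p[keep]
  het <- 2 * pk * (1 - pk)
  Sk <- if (method == "vanraden1") rep(sum(het), length(pk))
        else length(pk) * het
  Zc <- sweep(Gk, 2L, 2 * pk, "-")
  Zc <- sweep(Zc, 2L, sqrt(Sk), "/")
  structure(Zc, method = method, p = pk, kept_markers = colnames(Gk))
}

#' Blended genomic relationship matrix with a residual polygenic proportion
#'
#' \eqn{G_w = (1 - w) Z_c Z_c' + w A_{22}}: the marker-based relationship
#' matrix blended with the pedigree relationship matrix of the genotyped
#' animals, where \eqn{w} is the proportion of genetic variance assigned to
#' the residual polygenic effect.
#'
#' @param Zc Centered/scaled marker matrix from [center_scale()].
#' @param A22 Pedigree relationship matrix of the same animals, same order.
#' @param w Residual polygenic proportion in \eqn{[0, 1]}.
#' @return Symmetric matrix \eqn{G_w} with attribute \code{"w"}.
#' @export
blended_relationship <- function(Zc, A22, w) {
  stopifnot(w >= 0, w <= 1)
  if (nrow(Zc) != nrow(A22))
    stop("Zc and A22 have different numbers of animals")
  if (!is.null(rownames(Zc)) && !is.null(rownames(A22)) &&
      !identical(rownames(Zc), rownames(A22)))
    stop("animal ID order differs between Zc and A22")
  Gw <- (1 - w) * tcrossprod(Zc) + w * A22
  Gw <- (Gw + t(Gw)) / 2
  dimnames(Gw) <- dimnames(A22)
  attr(Gw, "w") <- w
  Gw
}
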
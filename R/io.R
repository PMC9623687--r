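#' Read a phenotype file
#'
#' CSV with columns animal, y (record value) and an optional weight column;
#' a header row is detected by a non-numeric second field. Missing weights
#' default to 1.
#'
#' @param path Path to the phenotype file.
#' @return A [phenotype_data()] data frame.
#' @export
read_phenotypes <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = FALSE, sep = detect_sep(path),
                           colClasses = "character", strip.white = TRUE)
  if (ncol(raw) < 2L) stop("phenotype file must have animal and value ",
                           "columns")
  if (is.na(suppressWarnings(as.numeric(raw[1L, 2L]))))
    raw <- raw[-1L, , drop = FALSE]
  y <- suppressWarnings(as.numeric(raw[[2L]]))
  if (anyNA(y)) stop("non-numeric phenotype value in ", path)
  weight <- if (ncol(raw) >= 3L) suppressWarnings(as.numeric(raw[[3L]]))
            else 1
  weight[is.na(weight)] <- 1
  phenotype_data(raw[[1L]], y, weight)
}

#' Write a pedigree to CSV
#' @param ped A \code{"pedigree"}.
#' @param path Output path.
#' @export
write_pedigree_csv <- function(ped, path) {
  utils::write.csv(as.data.frame(ped)[, c("animal", "sire", "dam")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genotype matrix to CSV (ID column + marker columns)
#' @param geno A \code{"genotype_matrix"}.
#' @param path Output path.
#' @export
write_genotype_csv <- function(geno, path) {
  df <- data.frame(animal = rownames(geno), unclass(geno),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write phenotypes to CSV
#' @param pheno A \code{"phenotype_data"}.
#' @param path Output path.
#' @export
write_phenotype_csv <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
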
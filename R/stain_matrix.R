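#' Construct a stain matrix
#'
#' A stain matrix holds the optical-density (OD) colour vectors of up to three
#' dyes: rows are stains, columns are the (R, G, B) OD components. Because OD
#' vectors of pure dyes are conventionally normalized, every row must have
#' Euclidean norm 1 within `norm_tol`.
#'
#' @param values 3x3 numeric matrix, rows = stains, columns = (R, G, B) OD
#'   components; all entries must be non-negative.
#' @param stain_names Character vector of 3 row labels.
#' @param norm_tol Allowed deviation of each row norm from 1 (default 0.001).
#' @return An object of class `stain_matrix`.
#' @seealso [trichrome_stain_matrix()] for the fixed Masson's trichrome basis.
#' @export
stain_matrix <- function(values,
                         stain_names = c("stain1", "stain2", "stain3"),
                         norm_tol = 0.001) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(3L, 3L))) stopf("stain matrix must be 3x3")
  if (any(!is.finite(values))) stopf("stain matrix entries must be finite")
  if (any(values < 0)) stopf("stain matrix entries must be non-negative")
  norms <- sqrt(rowSums(values^2))
  bad <- which(abs(norms - 1) > norm_tol)
  if (length(bad)) {
    stopf("stain row(s) %s not unit-norm (norms: %s)",
          paste(bad, collapse = ", "),
          paste(sprintf("%.4f", norms[bad]), collapse = ", "))
  }
  ## a (near-)singular basis cannot be unmixed; detect collinear stain pairs
  if (abs(det(values)) < 1e-8) {
    pair <- "unknown pair"
    for (i in 1:2) for (j in (i + 1):3) {
      cosang <- sum(values[i, ] * values[j, ]) / (norms[i] * norms[j])
      if (abs(cosang) > 1 - 1e-8) {
        pair <- paste(stain_names[i], "and", stain_names[j])
      }
    }
    stopf("stain matrix is singular (collinear stains: %s)", pair)
  }
  stopifnot(length(stain_names) == 3L)
  dimnames(values) <- list(stain_names, c("R", "G", "B"))
  structure(list(values = values, stain_names = stain_names),
            class = "stain_matrix")
}

#' The fixed Masson's trichrome stain matrix
#'
#' Returns the trichrome OD basis used throughout this package: row 1 is the
#' trichrome red (cytoplasm/muscle) dye, row 2 the trichrome blue (collagen)
#' dye, and row 3 a third counter-stain component completing the basis.
#' Columns are the normalized OD contributions in the red, green and blue
#' image channels.
#'
#' @return A [stain_matrix()] with rows `c("trichrome_red", "trichrome_blue",
#'   "counter")`.
#' @export
#' @examples
#' C <- trichrome_stain_matrix()
#' sqrt(rowSums(C$values^2))  # each row is unit-norm
trichrome_stain_matrix <- function() {
  v <- matrix(c(0.7995, 0.5914, 0.1053,
                0.1000, 0.7374, 0.6680,
                0.5923, 0.3264, 0.7366),
              nrow = 3, byrow = TRUE)
  stain_matrix(v, c("trichrome_red", "trichrome_blue", "counter"))
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("Stain matrix (rows = stains, columns = RGB optical density):\n")
  print(round(x$values, 4))
  invisible(x)
}
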
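#' Substitution model over a residue alphabet
#'
#' Wraps a substitution rate matrix `R` (off-diagonal entries nonnegative,
#' rows summing to zero) together with its stationary distribution `rho`
#' (`rho %*% R = 0`).  Inserted residues under the GGI model are drawn
#' independently from `rho`; matched residues substitute with probabilities
#' `expm(R * t)`.
#'
#' @param R Square numeric rate matrix; rows/columns may be named with the
#'   alphabet.
#' @param alphabet Character vector of residue symbols; defaults to the
#'   dimnames of `R` or single letters.
#' @param rho Optional stationary distribution; computed from `R` if omitted.
#' @param tol Tolerance for validity checks.
#' @return An object of class `"subst_model"` with elements `alphabet`, `R`,
#'   `rho`.
#' @seealso [jc_model()] for a symmetric one-parameter model,
#'   [substitution_probs()], [stationary_distribution()].
#' @export
subst_model <- function(R, alphabet = NULL, rho = NULL, tol = 1e-9) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("rate matrix must be square", call. = FALSE)
  K <- nrow(R)
  if (is.null(alphabet)) {
    alphabet <- rownames(R)
    if (is.null(alphabet)) alphabet <- LETTERS[seq_len(K)]
  }
  if (length(alphabet) != K)
    stop("alphabet length does not match rate matrix dimension", call. = FALSE)
  off <- R; diag(off) <- 0
  if (any(off < -tol))
    stop("off-diagonal rates must be nonnegative", call. = FALSE)
  if (any(abs(rowSums(R)) > tol))
    stop("rows of the rate matrix must sum to zero", call. = FALSE)
  if (is.null(rho)) {
    rho <- stationary_distribution(R, tol = tol)
  } else {
    if (length(rho) != K || any(rho < -tol) || abs(sum(rho) - 1) > tol)
      stop("'rho' must be a probability vector of matching length",
           call. = FALSE)
    if (max(abs(as.numeric(rho %*% R))) > tol)
      stop("'rho' is not stationary for R (rho %*% R != 0)", call. = FALSE)
  }
  dimnames(R) <- list(alphabet, alphabet)
  names(rho) <- alphabet
  structure(list(alphabet = alphabet, R = R, rho = rho),
            class = "subst_model")
}

#' Stationary distribution of a substitution rate matrix
#'
#' Solves `rho %*% R = 0`, `sum(rho) = 1`.  Errors if the stationary vector
#' is not unique (reducible generator), e.g. for the zero matrix.
#'
#' @param R Square rate matrix.
#' @param tol Tolerance used both for the null-space test and nonnegativity.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(R, tol = 1e-9) {
  R <- as.matrix(R)
  K <- nrow(R)
  e <- eigen(t(R))
  null_idx <- which(abs(e$values) < sqrt(tol))
  if (length(null_idx) != 1L)
    stop("stationary distribution is not unique: the rate matrix has ",
         length(null_idx), " (near-)null eigenvalues; the chain is reducible",
         call. = FALSE)
  v <- Re(e$vectors[, null_idx])
  rho <- v / sum(v)
  if (any(rho < -tol))
    stop("stationary vector has negative entries; invalid rate matrix",
         call. = FALSE)
  rho <- pmax(rho, 0); rho <- rho / sum(rho)
  names(rho) <- rownames(R)
  rho
}

#' Finite-time substitution probabilities
#'
#' Computes the row-stochastic matrix `M = expm(R * t)`.
#'
#' @param s A [subst_model()] object.
#' @param t Nonnegative divergence time.
#' @return Square stochastic matrix over the alphabet.
#' @export
substitution_probs <- function(s, t) {
  stopifnot(inherits(s, "subst_model"))
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("'t' must be a single nonnegative time", call. = FALSE)
  M <- as.matrix(Matrix::expm(Matrix::Matrix(s$R * t)))
  dimnames(M) <- dimnames(s$R)
  M
}

#' Symmetric one-parameter substitution model
#'
#' All off-diagonal rates equal; stationary distribution uniform.  The
#' default DNA alphabet gives a Jukes-Cantor-style model.
#'
#' @param alphabet Residue symbols.
#' @param rate Total substitution rate away from each residue.
#' @return A [subst_model()] object.
#' @export
jc_model <- function(alphabet = c("A", "C", "G", "T"), rate = 1) {
  K <- length(alphabet)
  R <- matrix(rate / (K - 1), K, K)
  diag(R) <- -rate
  dimnames(R) <- list(alphabet, alphabet)
  subst_model(R, alphabet)
}

#' Read and write substitution models as JSON
#'
#' The JSON schema is an object with fields `alphabet` (ordered array),
#' `rate_matrix` (row-major array of rows) and `rho`.
#'
#' @param s A [subst_model()] object.
#' @param path File path.
#' @return `read_subst_model()` returns a [subst_model()]; `write_subst_model()`
#'   returns `path` invisibly.
#' @export
write_subst_model <- function(s, path) {
  stopifnot(inherits(s, "subst_model"))
  obj <- list(alphabet = s$alphabet,
              rate_matrix = unname(lapply(seq_len(nrow(s$R)),
                                          function(i) unname(s$R[i, ]))),
              rho = unname(s$rho))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subst_model
#' @export
read_subst_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- if (is.list(obj$rate_matrix)) do.call(rbind, obj$rate_matrix)
       else as.matrix(obj$rate_matrix)
  subst_model(R, alphabet = obj$alphabet, rho = obj$rho)
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Substitution model over {", paste(x$alphabet, collapse = ", "), "}\n")
  cat("rate matrix:\n"); print(x$R)
  cat("stationary distribution:\n"); print(x$rho)
  invisible(x)
}
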
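#' Build a species-by-sample abundance table
#'
#' @param abundances numeric matrix, rows = species, columns = samples,
#'   non-negative; dimnames give species and sample ids.
#' @return validated abundance matrix of class \code{abundance_table}.
#' @export
abundance_table <- function(abundances) {
  m <- as.matrix(abundances)
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("sp", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("sample", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate species ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids", call. = FALSE)
  class(m) <- c("abundance_table", class(m))
  m
}

#' Read an abundance TSV (rows = species, columns = samples)
#' @param path TSV path with a species-id first column and sample columns.
#' @return an \code{abundance_table}.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  abundance_table(m)
}

#' Write an abundance table as TSV
#' @param table an \code{abundance_table} (or plain matrix).
#' @param path output path.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(species_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Jaccard co-occurrence between species
#'
#' Calls a species present in a sample when its abundance exceeds
#' \code{presence_threshold} (default 0: any strictly positive abundance).
#' The co-occurrence of two species is the Jaccard similarity of their
#' presence patterns: the number of samples where both are present divided by
#' the number where at least one is. Pairs present in no sample get 0 by
#' convention; the diagonal is 1 for species present somewhere (0 for species
#' absent everywhere, which also trigger a warning).
#'
#' @param table an \code{abundance_table} or species-by-sample matrix.
#' @param presence_threshold abundance strictly above which a species is
#'   called present.
#' @return symmetric numeric matrix in [0, 1] with species-id dimnames.
#' @export
jaccard_cooccurrence <- function(table, presence_threshold = 0) {
  m <- unclass(abundance_table(table))
  if (nrow(m) < 2L) stop("need at least 2 species", call. = FALSE)
  if (ncol(m) < 1L) stop("need at least 1 sample", call. = FALSE)
  pres <- (m > presence_threshold) * 1
  absent <- rowSums(pres) == 0
  if (any(absent)) {
    warning("species absent from every sample: ",
            paste(rownames(m)[absent], collapse = ", "), call. = FALSE)
  }
  inter <- pres %*% t(pres)
  totals <- rowSums(pres)
  union <- outer(totals, totals, `+`) - inter
  sim <- ifelse(union > 0, inter / union, 0)
  dimnames(sim) <- list(rownames(m), rownames(m))
  sim
}

# Pearson correlation over the off-diagonal cells of two square matrices.
offdiag_values <- function(m) m[row(m) != col(m)]

#' Mantel permutation test between two square matrices
#'
#' The statistic is the Pearson correlation r over all n(n-1) off-diagonal
#' cells of the two matrices (both triangles, so asymmetric interaction
#' matrices are handled without symmetrizing). The null distribution is
#' generated by jointly permuting the rows and columns of \code{m2} with the
#' same random permutation; \code{m1} is never permuted (permuting either is
#' statistically equivalent, one is fixed for reproducibility). The p-value
#' uses the add-one estimator and is two-sided by default.
#'
#' With \code{exact = TRUE} all n! permutations are enumerated (n <= 8) and p
#' is the exact fraction of permutations, the identity included, whose
#' statistic is at least as extreme as the observed one.
#'
#' @param m1,m2 square numeric matrices of identical dimension n >= 4.
#' @param n_perm number of random permutations (>= 99); ignored when
#'   \code{exact = TRUE}.
#' @param rng_seed integer seed for reproducibility (ignored when exact).
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @param exact enumerate all permutations instead of sampling.
#' @return object of class \code{mantel_result}: list with \code{r},
#'   \code{p}, \code{n_perm}, \code{rng_seed}, \code{alternative}.
#' @export
mantel_test <- function(m1, m2, n_perm = 999, rng_seed = 1L,
                        alternative = c("two.sided", "greater", "less"),
                        exact = FALSE) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n <- nrow(m1)
  if (ncol(m1) != n || !all(dim(m2) == n)) {
    stop("m1 and m2 must be square matrices of the same dimension",
         call. = FALSE)
  }
  if (n < 4L) stop("need at least 4 objects for a Mantel test", call. = FALSE)
  v1 <- offdiag_values(m1)
  v2 <- offdiag_values(m2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant off-diagonal entries: correlation undefined", call. = FALSE)
  }
  r_obs <- stats::cor(v1, v2)

  ii <- row(m1)[row(m1) != col(m1)]
  jj <- col(m1)[row(m1) != col(m1)]
  m <- length(ii)
  v1c <- v1 - mean(v1)
  ss1 <- sum(v1c^2)
  perm_r <- function(perms) {
    # perms: n_perm x n matrix of permutations; returns vector of r values
    A <- matrix(perms[, ii], nrow(perms), m)
    B <- matrix(perms[, jj], nrow(perms), m)
    V <- matrix(m2[cbind(as.vector(A), as.vector(B))], nrow(perms), m)
    Vc <- V - rowMeans(V)
    as.vector((Vc %*% v1c) / sqrt(rowSums(Vc^2) * ss1))
  }

  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8", call. = FALSE)
    perms <- all_permutations(n)
    r_null <- perm_r(perms)
    extreme <- switch(alternative,
                      two.sided = abs(r_null) >= abs(r_obs) - 1e-12,
                      greater = r_null >= r_obs - 1e-12,
                      less = r_null <= r_obs + 1e-12)
    p <- mean(extreme)
    n_used <- nrow(perms)
    seed_used <- NA_integer_
  } else {
    if (n_perm < 99L) stop("n_perm must be at least 99", call. = FALSE)
    perms <- with_seed(rng_seed, {
      t(replicate(n_perm, sample.int(n)))
    })
    r_null <- perm_r(perms)
    exceed <- switch(alternative,
                     two.sided = sum(abs(r_null) >= abs(r_obs) - 1e-12),
                     greater = sum(r_null >= r_obs - 1e-12),
                     less = sum(r_null <= r_obs + 1e-12))
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
    seed_used <- rng_seed
  }
  structure(list(r = r_obs, p = p, n_perm = n_used, rng_seed = seed_used,
                 alternative = alternative, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %s %d permutations)\n",
              x$r, x$p, x$alternative,
              if (x$exact) "exact," else "", x$n_perm))
  invisible(x)
}

# all n! permutations of 1..n as rows of a matrix (n <= 8)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}
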
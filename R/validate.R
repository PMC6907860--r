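# Internal validators shared across modules.  Matrices are gene-major
# (genes as rows); gene/sample identifiers live in dimnames and are frozen
# when a matrix enters the package.

.is_wholenumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol

# round half away from zero (base round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.expand_hyper <- function(x, n, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0))
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  if (length(x) != n)
    stop(sprintf("'%s' must be a scalar or have length %d, got %d",
                 name, n, length(x)), call. = FALSE)
  as.numeric(x)
}

.check_simplex <- function(x, name, tol = 1e-6) {
  if (any(x < -tol))
    stop(sprintf("'%s' has negative entries", name), call. = FALSE)
  if (abs(sum(x) - 1) > tol)
    stop(sprintf("'%s' must sum to 1 (got %.8f)", name, sum(x)), call. = FALSE)
  invisible(x)
}

.normalize <- function(x) x / sum(x)

# Validate a genes x samples count matrix; returns it with guaranteed unique
# dimnames (generated when absent so downstream registries always exist).
.validate_counts <- function(counts, require_integer = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes as rows, samples as columns)",
         call. = FALSE)
  if (anyNA(counts)) stop("counts contain NA values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (require_integer && !all(.is_wholenumber(counts)))
    stop("counts must be integers; round them or apply dilute_counts() first",
         call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts", call. = FALSE)
  if (any(colSums(counts) <= 0))
    stop("every sample must have at least one read (zero column sum found)",
         call. = FALSE)
  counts
}
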
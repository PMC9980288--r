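# Signature refitting: decompose a 96-context spectrum into non-negative
# contributions of catalog signatures by forward selection with non-negative
# least-squares sub-solves (a deterministic re-implementation of the
# deconstructSigs-style refit; same objective, NNLS instead of golden-section
# weight search).

#' Validate (and reorder) a signature catalog matrix
#'
#' A catalog is a 96 x k numeric matrix: rows named by [sbs_classes()],
#' columns by signature names, every column a probability vector summing to
#' 1 (tolerance 1e-6). Rows are reordered to canonical class order.
#'
#' @param m matrix-like catalog.
#' @return the validated matrix.
#' @export
signature_catalog <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != 96L)
    stop("signature catalog must have 96 rows", call. = FALSE)
  cls <- sbs_classes()
  if (is.null(rownames(m)) || !setequal(rownames(m), cls))
    stop("catalog rows must be named by the 96 substitution classes", call. = FALSE)
  m <- m[cls, , drop = FALSE]
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("catalog columns must carry unique signature names", call. = FALSE)
  if (any(m < 0))
    stop("catalog probabilities must be non-negative", call. = FALSE)
  s <- colSums(m)
  if (any(abs(s - 1) > 1e-6))
    stop(sprintf("catalog column '%s' does not sum to 1 (sum %.8f)",
                 colnames(m)[which(abs(s - 1) > 1e-6)[1L]],
                 s[which(abs(s - 1) > 1e-6)[1L]]), call. = FALSE)
  m
}

#' Read a signature catalog from TSV
#'
#' First column: class label (`"A[C>A]A"` style); remaining columns: one per
#' signature.
#'
#' @param path input TSV path.
#' @return a validated catalog matrix (96 x k).
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  signature_catalog(m)
}

#' Write a signature catalog to TSV
#'
#' @param catalog a catalog matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(class = rownames(catalog), catalog, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A small five-signature catalog for testing and demonstration
#'
#' Synthetic but shaped like the familiar catalog entries: an ageing-like
#' C>T-at-NCG signature (SBS1), an APOBEC C>T-at-TCW signature (SBS2), a
#' flat clock-like background (SBS5), an APOBEC C>G-at-TCW signature
#' (SBS13), and a T>G-at-TT signature (SBS17).
#'
#' @return a 96 x 5 catalog matrix.
#' @export
toy_signature_catalog <- function() {
  cls <- sbs_classes()
  blank <- stats::setNames(numeric(96L), cls)
  put <- function(v, at, w) { v[at] <- w; v / sum(v) }
  sbs1 <- put(blank, c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G"),
              c(0.30, 0.25, 0.20, 0.25))
  sbs2 <- put(blank, c("T[C>T]A", "T[C>T]T", "T[C>T]C", "T[C>T]G"),
              c(0.40, 0.40, 0.15, 0.05))
  sbs5 <- rep(1 / 96, 96L)
  sbs13 <- put(blank, c("T[C>G]A", "T[C>G]T", "T[C>G]C", "T[C>G]G"),
               c(0.40, 0.40, 0.15, 0.05))
  sbs17 <- put(blank, c("T[T>G]T", "C[T>G]T", "G[T>G]T", "T[T>G]A"),
               c(0.50, 0.20, 0.15, 0.15))
  m <- cbind(SBS1 = sbs1, SBS2 = sbs2, SBS5 = sbs5, SBS13 = sbs13,
             SBS17 = sbs17)
  rownames(m) <- cls
  signature_catalog(m)
}

nnls_sse <- function(mat, target) {
  fit <- pracma::lsqnonneg(mat, target)
  w <- as.numeric(fit$x)
  list(w = w, sse = sum((target - mat %*% w)^2))
}

#' Refit a spectrum against a signature catalog
#'
#' Forward selection: starting from the empty set, repeatedly add the
#' signature whose inclusion most reduces the squared reconstruction error
#' of the count-normalised spectrum under non-negative least squares; stop
#' when the improvement falls below `tolerance`. Weights below
#' `weight_floor` are then zeroed and the surviving set re-solved (repeated
#' until stable). Weight sums are capped at 1; the remainder is reported as
#' `unexplained`. Ties in selection are broken by catalog column order, so
#' the fit is deterministic. An optional 32-trinucleotide abundance vector
#' rescales the catalog between sequence spaces before fitting.
#'
#' @param spectrum a `spectrum96` (or named counts over [sbs_classes()])
#'   with positive total.
#' @param catalog a catalog matrix (see [signature_catalog()]).
#' @param weight_floor minimum retained weight (default 0.06).
#' @param tolerance minimum error improvement to continue selection.
#' @param abundance optional named vector over the 32 pyrimidine-centred
#'   trinucleotides giving target/source abundance ratios.
#' @return an object of class `signature_exposure` with fields `sample_id`,
#'   `weights` (named over all catalog signatures), `unexplained`,
#'   `reconstruction_error` (L2), and `selected`.
#' @export
refit <- function(spectrum, catalog, weight_floor = 0.06, tolerance = 1e-9,
                  abundance = NULL) {
  catalog <- signature_catalog(catalog)
  cls <- sbs_classes()
  counts <- if (inherits(spectrum, "spectrum96")) unclass(spectrum)
            else spectrum
  if (is.null(names(counts)) || !setequal(names(counts), cls))
    stop("spectrum must be named by the 96 substitution classes", call. = FALSE)
  counts <- counts[cls]
  total <- sum(counts)
  if (total <= 0) stop("cannot refit an empty spectrum", call. = FALSE)
  if (!is.null(abundance)) {
    tri <- paste0(substr(cls, 1, 1), substr(cls, 3, 3), substr(cls, 7, 7))
    if (is.null(names(abundance)) || !all(tri %in% names(abundance)))
      stop("abundance must be named over the 32 pyrimidine-centred trinucleotides",
           call. = FALSE)
    catalog <- catalog * abundance[tri]
    catalog <- sweep(catalog, 2L, colSums(catalog), "/")
  }
  target <- counts / total
  k <- ncol(catalog)
  sel <- integer(0)
  err <- sum(target^2)
  w_sel <- numeric(0)
  repeat {
    cand <- setdiff(seq_len(k), sel)
    if (!length(cand)) break
    fits <- lapply(cand, function(j)
      nnls_sse(catalog[, c(sel, j), drop = FALSE], target))
    sses <- vapply(fits, `[[`, 0, "sse")
    best <- which.min(sses)           # first minimum = catalog-order tie-break
    if (err - sses[best] < tolerance) break
    sel <- c(sel, cand[best])
    w_sel <- fits[[best]]$w
    err <- sses[best]
  }
  weights <- stats::setNames(numeric(k), colnames(catalog))
  weights[sel] <- w_sel
  # floor-and-refit until stable
  repeat {
    low <- weights > 0 & weights < weight_floor
    if (!any(low)) break
    weights[low] <- 0
    keep <- which(weights > 0)
    if (!length(keep)) break
    f <- nnls_sse(catalog[, keep, drop = FALSE], target)
    weights[] <- 0
    weights[keep] <- f$w
  }
  s <- sum(weights)
  if (s > 1) weights <- weights / s
  resid <- target - catalog %*% weights
  structure(list(sample_id = attr(spectrum, "sample_id") %||% NA_character_,
                 weights = weights,
                 unexplained = max(0, 1 - sum(weights)),
                 reconstruction_error = sqrt(sum(resid^2)),
                 selected = colnames(catalog)[weights > 0]),
            class = "signature_exposure")
}

#' @export
print.signature_exposure <- function(x, ...) {
  cat(sprintf("signature_exposure '%s' (L2 error %.4g, unexplained %.3f)\n",
              x$sample_id, x$reconstruction_error, x$unexplained))
  w <- x$weights[x$weights > 0]
  if (length(w))
    cat("  ", paste(sprintf("%s: %.3f", names(w), w), collapse = ", "), "\n")
  else cat("   no signature selected\n")
  invisible(x)
}

#' @export
coef.signature_exposure <- function(object, ...) object$weights

#' Percent contribution of the APOBEC C>T signature (SBS2)
#'
#' @param exposure a `signature_exposure`.
#' @param signature signature name (default `"SBS2"`).
#' @return percentage in `[0, 100]`; 0 when the signature was not selected
#'   or is absent from the catalog.
#' @export
percent_sbs2 <- function(exposure, signature = "SBS2") {
  w <- exposure$weights
  if (!signature %in% names(w)) return(0)
  100 * unname(w[signature])
}
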
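mz_matrix <- function(records) {
  if (is.matrix(records)) {
    m <- records
    if (ncol(m) != 6) stop("expected 6 Mood Zoom item columns", call. = FALSE)
    colnames(m) <- mz_items()
  } else {
    miss <- setdiff(mz_items(), names(records))
    if (length(miss)) {
      stop("missing Mood Zoom item columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(records[mz_items()])
  }
  if (anyNA(m)) stop("Mood Zoom records contain missing items", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Principal-component analysis of the six Mood Zoom items
#'
#' Eigendecomposition of the 6x6 covariance (or correlation) matrix of
#' pooled daily responses after column-mean centering. Components are
#' ordered by decreasing eigenvalue and labelled P1..P6; the first three
#' are conventionally interpreted as negative affect (MZneg), positive
#' affect (MZpos) and irritability (MZirr). Sign convention: each column is
#' flipped so that its largest-magnitude loading is positive, which makes
#' the negative-affect score increase with sadness/anxiety and the
#' positive-affect score with elation/energy.
#'
#' @param records Pooled daily records: a tibble/data frame with the six
#'   item columns of [mz_items()], or a numeric matrix with 6 columns.
#' @param type `"covariance"` (default; all items share the 1--7 scale) or
#'   `"correlation"`.
#' @return An object of class `mz_loadings`: list with `loadings` (6x6,
#'   rows = items, columns = P1..P6, orthonormal), `eigenvalues`,
#'   `pct_variance` (sums to 100), `cumulative_pct`, `item_means`,
#'   `item_sds`, `type`, `n`.
#' @export
fit_mz_pca <- function(records, type = c("covariance", "correlation")) {
  type <- match.arg(type)
  m <- mz_matrix(records)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 rows to fit a PCA", call. = FALSE)
  if (n < 7) {
    warning(sprintf("only %d rows for 6 items: covariance is rank-deficient", n))
  }
  sds <- apply(m, 2, stats::sd)
  degenerate <- names(which(sds == 0))
  if (length(degenerate)) {
    stop("zero-variance item(s): ", paste(degenerate, collapse = ", "),
         call. = FALSE)
  }
  cmat <- if (type == "covariance") stats::cov(m) else stats::cor(m)
  eig <- eigen(cmat, symmetric = TRUE)
  vectors <- eig$vectors
  values <- pmax(eig$values, 0)
  # sign convention: dominant loading of each component positive
  for (k in seq_len(ncol(vectors))) {
    j <- which.max(abs(vectors[, k]))
    if (vectors[j, k] < 0) vectors[, k] <- -vectors[, k]
  }
  dimnames(vectors) <- list(mz_items(), paste0("P", seq_len(6)))
  pct <- 100 * values / sum(values)
  structure(
    list(
      loadings = vectors,
      eigenvalues = values,
      pct_variance = pct,
      cumulative_pct = cumsum(pct),
      item_means = colMeans(m),
      item_sds = sds,
      type = type,
      n = n
    ),
    class = "mz_loadings"
  )
}

#' @export
print.mz_loadings <- function(x, ...) {
  cat(sprintf("Mood Zoom PCA loadings (%s matrix, n = %d rows)\n", x$type, x$n))
  print(round(x$loadings, 3))
  cat("% variance:  ", paste(sprintf("%5.1f", x$pct_variance), collapse = " "), "\n")
  cat("% cumulative:", paste(sprintf("%5.1f", x$cumulative_pct), collapse = " "), "\n")
  invisible(x)
}

#' Mood Zoom factor scores
#'
#' Projects (centered) item responses onto fitted principal-component
#' loadings. The first three components are labelled MZneg, MZpos and MZirr.
#'
#' @param records Daily records (tibble with the six item columns) or a
#'   6-column matrix.
#' @param loadings An `mz_loadings` object from [fit_mz_pca()].
#' @param n_components Number of leading components to return (1--6),
#'   default 3.
#' @return Tibble of factor scores, one row per record; columns MZneg,
#'   MZpos, MZirr (then P4..P6 if requested).
#' @export
factor_scores <- function(records, loadings, n_components = 3) {
  stopifnot(inherits(loadings, "mz_loadings"))
  if (n_components < 1 || n_components > 6) {
    stop("n_components must be in 1..6", call. = FALSE)
  }
  m <- mz_matrix(records)
  centered <- sweep(m, 2, loadings$item_means)
  if (loadings$type == "correlation") {
    centered <- sweep(centered, 2, loadings$item_sds, "/")
  }
  sc <- centered %*% loadings$loadings[, seq_len(n_components), drop = FALSE]
  nm <- c("MZneg", "MZpos", "MZirr", "P4", "P5", "P6")[seq_len(n_components)]
  colnames(sc) <- nm
  tibble::as_tibble(sc)
}

#' Tucker congruence coefficient between two loading vectors
#'
#' The cosine similarity of two component loading vectors; reported as an
#' absolute value because component signs are arbitrary.
#'
#' @param a,b Numeric loading vectors of equal length.
#' @return Congruence coefficient in \[0, 1\].
#' @export
tucker_congruence <- function(a, b) {
  stopifnot(length(a) == length(b))
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

#' Per-cohort stability of the pooled Mood Zoom components
#'
#' Refits the PCA within each cohort and reports the Tucker congruence
#' between each pooled leading component and its best-matching within-cohort
#' component. Matching is greedy on maximum congruence over the cohort's
#' six components, in pooled component order, without reusing a matched
#' component (ties broken by component order).
#'
#' @param study An `mz_study` object.
#' @param loadings Pooled loadings from [fit_mz_pca()].
#' @param n_components Number of pooled components to assess, default 3.
#' @return Tibble with columns `cohort`, `component` (P1..),
#'   `matched_component` (within-cohort), `congruence`, `n_rows`. Cohorts
#'   with fewer than 7 daily rows are skipped with a warning.
#' @export
per_group_stability <- function(study, loadings, n_components = 3) {
  stopifnot(inherits(study, "mz_study"), inherits(loadings, "mz_loadings"))
  daily <- dplyr::left_join(study$daily,
                            study$cohorts[c("participant_id", "cohort")],
                            by = "participant_id")
  out <- list()
  for (coh in unique(study$cohorts$cohort)) {
    rows <- daily[daily$cohort == coh, , drop = FALSE]
    if (nrow(rows) < 7) {
      warning(sprintf("cohort '%s' has only %d daily rows; skipped",
                      coh, nrow(rows)))
      next
    }
    fit <- fit_mz_pca(rows, type = loadings$type)
    available <- seq_len(6)
    for (k in seq_len(n_components)) {
      phis <- vapply(available, function(j) {
        tucker_congruence(loadings$loadings[, k], fit$loadings[, j])
      }, numeric(1))
      best <- available[which.max(phis)]
      out[[length(out) + 1]] <- tibble::tibble(
        cohort = coh,
        component = paste0("P", k),
        matched_component = paste0("P", best),
        congruence = max(phis),
        n_rows = nrow(rows)
      )
      available <- setdiff(available, best)
    }
  }
  dplyr::bind_rows(out)
}

#' Export fitted loadings as a data frame
#'
#' One row per item plus a `% variance` and a `% cumulative` row, mirroring
#' the usual published layout of a loading table.
#'
#' @param loadings An `mz_loadings` object.
#' @return Tibble with a `row` label column and P1..P6 columns.
#' @export
loadings_table <- function(loadings) {
  stopifnot(inherits(loadings, "mz_loadings"))
  m <- rbind(loadings$loadings,
             `% variance` = loadings$pct_variance,
             `% cumulative` = loadings$cumulative_pct)
  tibble::as_tibble(m, rownames = "row")
}
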
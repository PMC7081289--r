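#' Cytolytic activity score (CYT)
#'
#' The geometric mean of granzyme A (GZMA) and perforin-1 (PRF1) expression
#' (RPKM), a compact transcriptional signature of tumor-infiltrating
#' cytolytic T-cell activity. A pseudocount guards against zero expression:
#' `cyt = sqrt((gzma + eps) * (prf1 + eps))`.
#'
#' @param gzma_rpkm,prf1_rpkm nonnegative expression values; vectorized.
#' @param pseudocount small additive constant (default 0.01).
#' @return Numeric CYT scores.
#' @examples
#' cyt_score(4, 9, pseudocount = 0)  # 6
#' @export
cyt_score <- function(gzma_rpkm, prf1_rpkm, pseudocount = 0.01) {
  if (any(gzma_rpkm < 0, na.rm = TRUE) || any(prf1_rpkm < 0, na.rm = TRUE))
    stop("expression values must be nonnegative")
  sqrt((gzma_rpkm + pseudocount) * (prf1_rpkm + pseudocount))
}

#' Spearman association matrix with significance mask
#'
#' Pairwise Spearman rank correlations between per-patient immune measures
#' (typically immunogenicity, CYT, TMB, TIL burden, TIL clonality). Rank
#' correlation is used to damp the influence of outliers. Cells with
#' p > `alpha` are masked (the "no color" tiles of a correlogram). Missing
#' values are handled pairwise-complete; constant features yield `NA`
#' correlations, are masked, and trigger a warning.
#'
#' @param features data frame or matrix of numeric per-patient features.
#' @param alpha significance level for the mask (default 0.05 on raw
#'   p-values).
#' @param adjust `"none"` (default, raw p-values) or `"BH"` for
#'   Benjamini-Hochberg adjusted masking.
#' @return A list of class `assoc_matrix` with symmetric matrices `rho`,
#'   `pvalue` and logical `mask` (`TRUE` where not significant).
#' @export
association_matrix <- function(features, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  x <- as.data.frame(features)
  x <- x[vapply(x, is.numeric, logical(1))]
  k <- ncol(x)
  if (k < 2L) stop("need at least two numeric features")
  if (sum(stats::complete.cases(x)) < 3L) stop("need >= 3 complete patients")
  nm <- names(x)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(rho) <- 1; diag(p) <- 0
  warned <- FALSE
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    ok <- stats::complete.cases(x[[i]], x[[j]])
    if (sum(ok) >= 3 && sd(x[[i]][ok]) > 0 && sd(x[[j]][ok]) > 0) {
      ct <- suppressWarnings(cor.test(x[[i]][ok], x[[j]][ok],
                                      method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    } else warned <- TRUE
  }
  if (warned)
    warning("constant or insufficient feature pair(s); correlation undefined and masked")
  pm <- p
  if (adjust == "BH") {
    up <- upper.tri(p)
    pm[up] <- stats::p.adjust(p[up], "BH")
    pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
  }
  mask <- is.na(pm) | pm > alpha
  diag(mask) <- FALSE
  structure(list(rho = rho, pvalue = p, mask = mask, alpha = alpha,
                 adjust = adjust), class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, digits = 2, ...) {
  cat("Spearman association matrix (masked where p >", x$alpha,
      if (x$adjust == "BH") "after BH adjustment" else "", ")\n")
  disp <- format(round(x$rho, digits))
  disp[x$mask] <- "."
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.assoc_matrix <- function(x, ...) {
  nm <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  data.frame(feature_a = nm[idx[, 1]], feature_b = nm[idx[, 2]],
             rho = x$rho[idx], p = x$pvalue[idx],
             significant = !x$mask[idx])
}
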
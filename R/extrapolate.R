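# Principal-component-regression extrapolation from a measured gene panel
# to the full transcriptome.

#' Fit a principal-component-regression extrapolator
#'
#' Computes principal components of the reference compendium restricted to
#' the measured gene panel (samples as observations, genes as variables,
#' gene-wise centering, no scaling), then regresses every compendium gene on
#' the component scores by ordinary least squares. Because the scores are
#' centered and orthogonal, the regression is a single cross-product per
#' gene; the intercept is the gene's compendium mean.
#'
#' @param compendium a [Compendium-class].
#' @param measured gene panel; defaults to the compendium's measured set.
#' @param nComponents number of components to retain. Default: the smallest
#'   number explaining >= 95% of the panel variance, capped at 100.
#' @return An [ExtrapolationModel-class].
#' @examples
#' cp <- simulateCompendium(50, 300, 3, measuredFraction = 0.2,
#'                          noiseSd = 0, seed = 1)
#' fitExtrapolator(cp, nComponents = 3)
#' @export
fitExtrapolator <- function(compendium, measured = NULL, nComponents = NULL) {
  stopifnot(is(compendium, "Compendium"))
  X <- compendiumExpr(compendium)
  if (is.null(measured)) measured <- measuredGenes(compendium)
  bad <- setdiff(measured, rownames(X))
  if (length(bad))
    stopf("measured genes absent from the compendium: %s",
          paste(utils::head(bad, 3), collapse = ", "))
  Xm <- t(X[measured, , drop = FALSE])        # samples x measured genes
  centers <- colMeans(Xm)
  Xc <- sweep(Xm, 2L, centers)
  sv <- svd(Xc)
  maxK <- sum(sv$d > max(sv$d) * 1e-12)
  if (is.null(nComponents)) {
    varexp <- cumsum(sv$d^2) / sum(sv$d^2)
    nComponents <- min(which(varexp >= 0.95), 100L, maxK)
  }
  if (nComponents > min(length(measured), nrow(Xm)))
    stopf("nComponents (%d) exceeds min(measured genes, reference samples)",
          nComponents)
  k <- as.integer(nComponents)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- measured
  scores <- Xc %*% loadings                   # samples x k, centered/orthogonal
  ss <- colSums(scores^2)
  ss[ss == 0] <- 1                            # guard null directions
  intercepts <- rowMeans(X)
  # OLS on orthogonal centered scores: beta_gk = <score_k, x_g> / ||score_k||^2
  coefs <- crossprod(scores, t(X - intercepts)) / ss
  new("ExtrapolationModel", measuredGenes = measured, centers = centers,
      loadings = loadings, coefficients = coefs, intercepts = intercepts,
      nComponents = k, passthrough = TRUE)
}

#' Extrapolate new samples to the full transcriptome
#'
#' Projects panel measurements of new samples onto the stored loadings and
#' predicts every output gene from the component scores. Measured genes are
#' passed through verbatim (the model's `passthrough` flag; set it FALSE to
#' re-predict them too).
#'
#' @param model an [ExtrapolationModel-class].
#' @param measuredMatrix an [ExprMatrix-class] on the `"log2"` scale (or a
#'   plain log2 matrix) whose gene set equals the model's measured panel
#'   (order-insensitive).
#' @return An [ExprMatrix-class] on the `"log2"` scale over the model's full
#'   output gene set.
#' @export
applyExtrapolator <- function(model, measuredMatrix) {
  stopifnot(is(model, "ExtrapolationModel"))
  v <- if (is(measuredMatrix, "ExprMatrix")) {
    if (exprScale(measuredMatrix) != "log2")
      stopf("extrapolation expects log2-scale input")
    exprValues(measuredMatrix)
  } else measuredMatrix
  miss <- setdiff(model@measuredGenes, rownames(v))
  if (length(miss))
    stopf("input lacks measured gene(s): %s",
          paste(utils::head(miss, 5), collapse = ", "))
  extra <- setdiff(rownames(v), model@measuredGenes)
  if (length(extra))
    stopf("input has gene(s) outside the measured panel: %s",
          paste(utils::head(extra, 5), collapse = ", "))
  v <- v[model@measuredGenes, , drop = FALSE]
  scores <- crossprod(v - model@centers, model@loadings)  # samples x k
  pred <- model@intercepts + t(scores %*% model@coefficients)  # genes x samples
  dimnames(pred) <- list(names(model@intercepts), colnames(v))
  if (model@passthrough)
    pred[model@measuredGenes, ] <- v
  ExprMatrix(pred, "log2")
}
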
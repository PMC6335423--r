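#' @importFrom stats wilcox.test t.test p.adjust median
NULL

# Accept a plain genes-x-samples matrix or a SummarizedExperiment (first
# assay).  Checks the invariants every scoring entry point relies on.
.asExprMatrix <- function(expr) {
  if (!is.matrix(expr) && methods::is(expr, "SummarizedExperiment")) {
    expr <- SummarizedExperiment::assay(expr, 1)
  }
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric genes x samples matrix", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (!all(is.finite(expr)))
    stop("expression values must be finite (log-scale, no NA)",
         call. = FALSE)
  expr
}

#' Read an expression matrix from TSV
#'
#' Genes as rows (first column holds the gene identifier), header row of
#' sample ids, log-scale values.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  .asExprMatrix(m)
}

#' Refine a seed signature by quartile contrast on an anchor gene
#'
#' Samples are ranked by the anchor gene's expression (ties broken by
#' sample id, stable); the top and bottom `ceiling(quartile * n)` samples
#' form the contrast bins.  Each seed gene is tested one-sided for higher
#' expression in the top bin (Wilcoxon rank-sum by default, Welch t
#' optionally), p-values are Benjamini-Hochberg adjusted, and genes with
#' adjusted p <= alpha are retained.  Seed genes absent from the matrix
#' are silently excluded but recorded in the definition.
#'
#' @param expr genes x samples matrix (or SummarizedExperiment).
#' @param anchor_gene the ranking gene (e.g. `"PPARG"`).
#' @param seed_genes candidate signature genes.
#' @param quartile bin fraction in (0, 0.5], default 0.25.
#' @param alpha BH-adjusted significance level, default 0.05.
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @return a [SignatureDefinition-class].
#' @export
refineSignature <- function(expr, anchor_gene, seed_genes, quartile = 0.25,
                            alpha = 0.05, test = c("wilcoxon", "welch")) {
  expr <- .asExprMatrix(expr)
  test <- match.arg(test)
  stopifnot(quartile > 0, quartile <= 0.5, alpha > 0, alpha <= 1)
  if (!anchor_gene %in% rownames(expr))
    stop("anchor gene '", anchor_gene, "' absent from the matrix",
         call. = FALSE)
  seed_genes <- unique(seed_genes)
  present <- intersect(seed_genes, rownames(expr))
  missing <- setdiff(seed_genes, present)
  if (length(present) == 0L)
    stop("no seed gene present in the matrix", call. = FALSE)
  n <- ncol(expr)
  nbin <- ceiling(quartile * n)
  if (nbin < 2L)
    stop("fewer than 2 samples per quartile bin (n = ", n, ")",
         call. = FALSE)
  anchor <- expr[anchor_gene, ]
  if (diff(range(anchor)) == 0)
    stop("anchor gene is constant across samples; ranking undefined",
         call. = FALSE)
  ord <- order(-anchor, colnames(expr))
  top <- colnames(expr)[ord[seq_len(nbin)]]
  bottom <- colnames(expr)[ord[seq(n - nbin + 1L, n)]]
  pv <- vapply(present, function(g) {
    hi <- expr[g, top]; lo <- expr[g, bottom]
    if (test == "wilcoxon")
      wilcox.test(hi, lo, alternative = "greater", exact = FALSE)$p.value
    else
      t.test(hi, lo, alternative = "greater")$p.value
  }, numeric(1))
  adj <- p.adjust(pv, method = "BH")
  keep <- adj <= alpha
  stats <- data.frame(gene = present, p = unname(pv), adj_p = unname(adj),
                      retained = unname(keep), stringsAsFactors = FALSE)
  new("SignatureDefinition", seed_genes = seed_genes,
      refined_genes = present[keep], missing_genes = missing,
      stats = stats, anchor_gene = anchor_gene, quartile = quartile,
      alpha = alpha, test = test)
}

.emptySignature <- function(genes = character()) {
  new("SignatureDefinition", seed_genes = genes, refined_genes = genes,
      missing_genes = character(),
      stats = data.frame(gene = character(), p = numeric(),
                         adj_p = numeric(), retained = logical()),
      anchor_gene = NA_character_, quartile = 0.25, alpha = 0.05,
      test = "wilcoxon")
}

#' Compute per-sample activation scores
#'
#' Each signature gene is centered across samples (gene mean by default,
#' gene median optionally); a sample's score is the mean of its centered
#' values over the signature genes.  With gene-mean centering the scores
#' sum to zero over samples by construction.
#'
#' @param expr genes x samples matrix (or SummarizedExperiment).
#' @param signature a [SignatureDefinition-class] or a character vector
#'   of gene ids; all genes must be present in `expr` and non-empty.
#' @param centering `"gene_mean"` (default) or `"gene_median"`.
#' @return a [SignatureScoreResult-class].
#' @export
scoreSamples <- function(expr, signature,
                         centering = c("gene_mean", "gene_median")) {
  expr <- .asExprMatrix(expr)
  centering <- match.arg(centering)
  if (is(signature, "SignatureDefinition")) {
    genes <- refinedGenes(signature)
    sig <- signature
  } else {
    genes <- as.character(signature)
    sig <- .emptySignature(genes)
  }
  if (length(genes) == 0L)
    stop("empty signature gene set", call. = FALSE)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent))
    stop("signature gene(s) absent from the matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  sub <- expr[genes, , drop = FALSE]
  ctr <- if (centering == "gene_mean") rowMeans(sub)
         else apply(sub, 1, median)
  centered <- sub - ctr
  scores <- colMeans(centered)
  new("SignatureScoreResult", scores = scores, centering = centering,
      signature_genes = genes, signature = sig)
}

#' Classify samples as activation-high
#'
#' @param result a [SignatureScoreResult-class].
#' @param rule `"positive"` (score > 0, the default), `"top_quartile"`
#'   (highest `ceiling(n/4)` scores, ties broken by sample id), or
#'   `"fixed"` with `cutoff` (score > cutoff).
#' @param cutoff numeric cutoff for `rule = "fixed"`.
#' @return named logical vector (TRUE = activation-high), with the rule
#'   recorded in attribute `"rule"`.
#' @export
classifyActivation <- function(result, rule = "positive", cutoff = NULL) {
  stopifnot(is(result, "SignatureScoreResult"))
  s <- activationScores(result)
  cls <- switch(rule,
    positive = s > 0,
    top_quartile = {
      k <- ceiling(length(s) / 4)
      ord <- order(-s, names(s))
      out <- setNames(logical(length(s)), names(s))
      out[ord[seq_len(k)]] <- TRUE
      out
    },
    fixed = {
      if (is.null(cutoff) || !is.finite(cutoff))
        stop("rule 'fixed' needs a finite 'cutoff'", call. = FALSE)
      s > cutoff
    },
    stop("unknown classification rule '", rule, "'", call. = FALSE))
  attr(cls, "rule") <- rule
  cls
}

#' Order samples by descending activation score
#'
#' Ties are broken by sample identifier (stable, lexicographic), the
#' order used to lay out oncoprint columns.
#'
#' @param result a [SignatureScoreResult-class].
#' @return character vector of sample ids.
#' @export
sortByScore <- function(result) {
  stopifnot(is(result, "SignatureScoreResult"))
  s <- activationScores(result)
  names(s)[order(-s, names(s))]
}
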
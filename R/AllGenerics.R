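#' @rdname accessors
#' @export
setGeneric("refinedGenes", function(x) standardGeneric("refinedGenes"))

#' @rdname accessors
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' @rdname accessors
#' @export
setGeneric("activationScores", function(x) standardGeneric("activationScores"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname accessors
#' @export
setGeneric("contingencyTable", function(x) standardGeneric("contingencyTable"))

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setGeneric("interfaceSet", function(x, which = c("a", "b"))
  standardGeneric("interfaceSet"))

#' Accessors for ppargmut result objects
#'
#' Small accessor functions so downstream code never touches slots
#' directly.
#'
#' @param x a ppargmut S4 object.
#' @param which for [interfaceSet()], which side of the chain pair.
#' @return the corresponding component (gene vectors, named score vector,
#'   p-value, odds ratio, 2x2 matrix, atom table, chain ids or residue
#'   numbers).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("refinedGenes", "SignatureDefinition", function(x) x@refined_genes)

#' @rdname accessors
#' @export
setMethod("seedGenes", "SignatureDefinition", function(x) x@seed_genes)

#' @rdname accessors
#' @export
setMethod("refinedGenes", "SignatureScoreResult",
          function(x) x@signature_genes)

#' @rdname accessors
#' @export
setMethod("activationScores", "SignatureScoreResult", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("pValue", "AssociationResult", function(x) x@p_two_sided)

#' @rdname accessors
#' @export
setMethod("oddsRatio", "AssociationResult", function(x) x@odds_ratio)

#' @rdname accessors
#' @export
setMethod("direction", "AssociationResult", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("contingencyTable", "AssociationResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("chainIds", "StructureModel",
          function(x) sort(unique(x@atoms$chain[!x@atoms$het])))

#' @rdname accessors
#' @export
setMethod("interfaceSet", "InterfaceReport", function(x, which = c("a", "b")) {
  which <- match.arg(which)
  d <- if (which == "a") x@residues_a else x@residues_b
  d$resno
})

setMethod("show", "IsoformMap", function(object) {
  cat(sprintf("IsoformMap: %s -> %s (offset %+d, min target position %d)\n",
              object@from_isoform, object@to_isoform, object@offset,
              object@min_valid_target))
})

setMethod("show", "DomainMap", function(object) {
  cat(sprintf("DomainMap for %s (%s), length %d aa\n", object@gene,
              object@isoform, object@protein_length))
  d <- object@domains
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-6s %d-%d\n", d$name[i], d$start[i], d$end[i]))
  if (nrow(object@landmarks))
    cat("  landmarks:", paste(sprintf("%s@%d", object@landmarks$name,
                                      object@landmarks$position),
                              collapse = ", "), "\n")
})

setMethod("show", "AssociationResult", function(object) {
  cat("AssociationResult (two-sided Fisher exact test)\n")
  print(object@table)
  orv <- if (object@zero_cell) sprintf("%s (zero cell)",
                                       format(object@odds_ratio))
         else format(object@odds_ratio, digits = 4)
  cat(sprintf("  odds ratio: %s   p = %s   direction: %s%s\n", orv,
              format(object@p_two_sided, digits = 4), object@direction,
              if (object@degenerate) "   [degenerate margins]" else ""))
})

setMethod("show", "SignatureDefinition", function(object) {
  cat(sprintf(
    "SignatureDefinition: %d/%d seed genes retained (%s, q=%g, alpha=%g)\n",
    length(object@refined_genes), length(object@seed_genes), object@test,
    object@quartile, object@alpha))
  if (length(object@missing_genes))
    cat("  absent from matrix:", paste(object@missing_genes, collapse = ", "),
        "\n")
})

setMethod("show", "SignatureScoreResult", function(object) {
  cat(sprintf(
    "SignatureScoreResult: %d samples, %d signature genes, centering %s\n",
    length(object@scores), length(object@signature_genes), object@centering))
  cat(sprintf("  score range: [%.3f, %.3f]\n", min(object@scores),
              max(object@scores)))
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  poly <- a[!a$het, , drop = FALSE]
  cat(sprintf("StructureModel: %d chains, %d residues, %d heavy atoms",
              length(unique(poly$chain)),
              nrow(unique(poly[c("chain", "resno", "insert")])), nrow(poly)))
  if (any(a$het)) cat(sprintf(" (+%d ligand atoms)", sum(a$het)))
  cat("\n")
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf("InterfaceReport %s/%s at %.1f A: %d + %d interface residues\n",
              object@chain_a, object@chain_b, object@cutoff,
              nrow(object@residues_a), nrow(object@residues_b)))
})
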
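.STAGES <- c("NMIBC", "MIBC", "cell_line", "unknown")
.SOURCES <- c("cohort", "external_db")

#' Read a per-sample mutation table
#'
#' Tab-separated, UTF-8, `#` comment lines ignored.  Required columns:
#' `sample_id`, `cohort`, `stage`, `gene`, `protein_change`, `isoform`,
#' `source`.  Multi-allele labels (e.g. `S427F/Y`) are expanded into one
#' row per allele.
#'
#' @param path TSV file.
#' @return a variant data.frame: `sample_id`, `cohort`, `stage`, `gene`,
#'   `ref_aa`, `position`, `alt_aa`, `isoform`, `label`, `source`.
#' @export
readMutationTable <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c("sample_id", "cohort", "stage", "gene", "protein_change",
            "isoform", "source")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("mutation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    ch <- parseProteinChange(raw$protein_change[i], raw$isoform[i])
    cbind(raw[rep(i, nrow(ch)), c("sample_id", "cohort", "stage", "gene",
                                  "source"), drop = FALSE],
          ch[c("ref_aa", "position", "alt_aa", "isoform", "label")])
  })
  v <- do.call(rbind, rows)
  rownames(v) <- NULL
  validateVariants(v)
  v
}

#' Validate a variant data.frame
#'
#' Checks column presence, non-empty sample ids, stage and source
#' vocabularies.  Called by the readers and the aggregators; exported so
#' hand-built tables can be checked too.
#'
#' @param v variant data.frame (see [readMutationTable()]).
#' @return `v`, invisibly.
#' @export
validateVariants <- function(v) {
  need <- c("sample_id", "cohort", "stage", "gene", "ref_aa", "position",
            "alt_aa", "isoform", "label", "source")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(v$sample_id)) || anyNA(v$sample_id))
    stop("empty sample_id in variant table", call. = FALSE)
  badst <- setdiff(unique(v$stage), .STAGES)
  if (length(badst))
    stop("unknown stage value(s): ", paste(badst, collapse = ", "),
         call. = FALSE)
  badsrc <- setdiff(unique(v$source), .SOURCES)
  if (length(badsrc))
    stop("unknown source value(s): ", paste(badsrc, collapse = ", "),
         call. = FALSE)
  invisible(v)
}

# Collapse repeated reports of the same (sample, gene, change) in cohort
# data to a single observation.  External-database rows are kept one per
# reported occurrence: database entries have no stable sample identity.
.dedupVariants <- function(v) {
  coh <- v[v$source == "cohort", , drop = FALSE]
  ext <- v[v$source != "cohort", , drop = FALSE]
  if (nrow(coh)) {
    key <- paste(coh$sample_id, coh$gene, coh$label, sep = "\r")
    coh <- coh[!duplicated(key), , drop = FALSE]
  }
  rbind(coh, ext)
}

#' Call recurrent (hotspot) protein changes
#'
#' Aggregates deduplicated variant observations per distinct
#' (gene, change).  A change is recurrent when it was observed at least
#' `min_count` times among cohort samples (`recurrence_basis =
#' "cohort_only"`), or — with `pool_external = TRUE` — when cohort plus
#' external-database occurrences together reach `min_count`
#' (`recurrence_basis = "pooled"`).  This pooling is what promotes
#' singleton cohort changes that recur in public databases (e.g. E3K) to
#' recurrent status.
#'
#' @param variants variant data.frame; all rows of one gene must share an
#'   isoform frame (harmonize first, see [harmonizeIsoform()]).
#' @param min_count minimum number of observations (default 2).
#' @param pool_external count external-database occurrences toward the
#'   threshold (default TRUE).
#' @return data.frame of recurrence records: `gene`, `label`, `ref_aa`,
#'   `position`, `alt_aa`, `isoform`, `n_cohort`, `n_external`, `n_total`,
#'   `stages_seen`, `is_recurrent`, `recurrence_basis`, sorted by
#'   (gene, position, n_total descending).
#' @export
callRecurrent <- function(variants, min_count = 2L, pool_external = TRUE) {
  validateVariants(variants)
  stopifnot(min_count >= 1L)
  frames <- unique(variants[c("gene", "isoform")])
  dup <- frames$gene[duplicated(frames$gene)]
  if (length(dup))
    stop("gene(s) ", paste(unique(dup), collapse = ", "),
         " carry mixed isoform frames; harmonize with harmonizeIsoform() ",
         "before calling recurrence", call. = FALSE)
  v <- .dedupVariants(variants)
  key <- paste(v$gene, v$label, sep = "\r")
  idx <- split(seq_len(nrow(v)), key)
  rec <- do.call(rbind, lapply(idx, function(i) {
    rows <- v[i, , drop = FALSE]
    n_coh <- sum(rows$source == "cohort")
    n_ext <- sum(rows$source == "external_db")
    stages <- sort(unique(rows$stage[rows$source == "cohort"]))
    data.frame(gene = rows$gene[1], label = rows$label[1],
               ref_aa = rows$ref_aa[1], position = rows$position[1],
               alt_aa = rows$alt_aa[1], isoform = rows$isoform[1],
               n_cohort = n_coh, n_external = n_ext,
               n_total = n_coh + n_ext,
               stages_seen = paste(stages, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rec$recurrence_basis <- "none"
  rec$recurrence_basis[pool_external & rec$n_total >= min_count] <- "pooled"
  rec$recurrence_basis[rec$n_cohort >= min_count] <- "cohort_only"
  rec$is_recurrent <- rec$recurrence_basis != "none"
  rec <- rec[order(rec$gene, rec$position, -rec$n_total, rec$label), ]
  rownames(rec) <- NULL
  rec[c("gene", "label", "ref_aa", "position", "alt_aa", "isoform",
        "n_cohort", "n_external", "n_total", "stages_seen", "is_recurrent",
        "recurrence_basis")]
}

#' Build a lolliplot table
#'
#' One row per distinct change (duplicate labels aggregated by summing
#' counts), positions ascending, each annotated with its domain.  The
#' black/grey circle split of a lolliplot corresponds to the
#' `n_cohort` / `n_external` columns.
#'
#' @param records recurrence records from [callRecurrent()] (typically
#'   filtered to `is_recurrent`).
#' @param dm a [DomainMap-class], or a named list of them keyed by gene
#'   when `records` spans several genes.
#' @return data.frame: `gene`, `position`, `label`, `n_cohort`,
#'   `n_external`, `n_total`, `domain`.
#' @export
buildLolliplotTable <- function(records, dm) {
  if (nrow(records) == 0L)
    return(data.frame(gene = character(), position = integer(),
                      label = character(), n_cohort = integer(),
                      n_external = integer(), n_total = integer(),
                      domain = character(), stringsAsFactors = FALSE))
  if (is(dm, "DomainMap")) dm <- setNames(list(dm), dm@gene)
  key <- paste(records$gene, records$label, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  tab <- do.call(rbind, lapply(idx, function(i) {
    r <- records[i, , drop = FALSE]
    data.frame(gene = r$gene[1], position = r$position[1],
               label = r$label[1],
               n_cohort = sum(r$n_cohort), n_external = sum(r$n_external),
               n_total = sum(r$n_total), stringsAsFactors = FALSE)
  }))
  tab$domain <- vapply(seq_len(nrow(tab)), function(i) {
    m <- dm[[tab$gene[i]]]
    if (is.null(m))
      stop("no domain map supplied for gene ", tab$gene[i], call. = FALSE)
    annotateDomain(tab$position[i], m)
  }, character(1))
  tab <- tab[order(tab$gene, tab$position, tab$label), ]
  rownames(tab) <- NULL
  tab
}

#' Build an oncoprint alteration matrix
#'
#' Genes as rows, samples as columns (column order follows
#' `sample_order` exactly, typically produced by [sortByScore()]).  Cells
#' take one of `none`, `mutation`, `amplification`,
#' `mutation+amplification`.
#'
#' @param variants cohort variant data.frame (external-database rows are
#'   not sample-level observations and must be filtered out first).
#' @param amplifications data.frame with columns `sample_id`, `gene`
#'   (may be empty).
#' @param sample_order character vector covering every sample referenced.
#' @return character matrix, genes x samples.
#' @export
buildOncoprintMatrix <- function(variants,
                                 amplifications = data.frame(
                                   sample_id = character(),
                                   gene = character()),
                                 sample_order) {
  if (any(variants$source != "cohort"))
    stop("oncoprint takes cohort observations only; filter external_db rows",
         call. = FALSE)
  seen <- unique(c(variants$sample_id, amplifications$sample_id))
  missing <- setdiff(seen, sample_order)
  if (length(missing))
    stop("sample(s) absent from sample_order: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  genes <- sort(unique(c(variants$gene, amplifications$gene)))
  m <- matrix("none", nrow = length(genes), ncol = length(sample_order),
              dimnames = list(genes, sample_order))
  mut <- unique(variants[c("sample_id", "gene")])
  for (i in seq_len(nrow(mut)))
    m[mut$gene[i], mut$sample_id[i]] <- "mutation"
  amp <- unique(amplifications[c("sample_id", "gene")])
  for (i in seq_len(nrow(amp))) {
    cur <- m[amp$gene[i], amp$sample_id[i]]
    m[amp$gene[i], amp$sample_id[i]] <-
      if (cur == "mutation") "mutation+amplification" else "amplification"
  }
  m
}

# Deterministic TSV writer shared by the pipeline outputs: fixed column
# order, no quoting surprises, optional leading comment lines.
.writeTsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con, sep = "\n")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
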
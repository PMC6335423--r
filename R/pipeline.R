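#' Read a pipeline run configuration
#'
#' A single YAML file drives an end-to-end run; every statistical
#' parameter has the package default, so a minimal config is just the
#' simulation block (or input paths) and an output directory.  All
#' randomness flows from one master `seed`.
#'
#' @param path YAML file.
#' @return config list (class `RunConfig`) with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  runConfig(cfg)
}

#' Build / validate a run configuration
#'
#' @param config named list; recognised fields: `seed`, `out_dir`,
#'   `min_count`, `pool_external`, `quartile`, `alpha`, `centering`,
#'   `threshold_rule`, `anchor_gene`, `target_gene`, `simulate`
#'   (`cohort` and/or `expression` blocks of generator arguments),
#'   `inputs` (`mutations`, `samples`, `amplifications`, `expression`,
#'   `seed_genes` file paths), `isoform_maps` (list of
#'   `gene`/`from_isoform`/`to_isoform`/`offset` entries),
#'   `domains` (YAML path, defaults to the built-in PPARG/RXRA maps),
#'   `structure` (`pdb`, `chains`, `offsets`, `interface_cutoff`).
#' @return validated config (class `RunConfig`).
#' @export
runConfig <- function(config = list()) {
  defaults <- list(seed = 1L, out_dir = "ppargmut_run", min_count = 2L,
                   pool_external = TRUE, quartile = 0.25, alpha = 0.05,
                   centering = "gene_mean", threshold_rule = "positive",
                   anchor_gene = "PPARG", target_gene = "PPARG",
                   simulate = NULL, inputs = NULL, isoform_maps = NULL,
                   domains = NULL, structure = NULL)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either a 'simulate' block or an 'inputs' block",
         call. = FALSE)
  stopifnot(cfg$min_count >= 1, cfg$quartile > 0, cfg$quartile <= 0.5,
            cfg$alpha > 0, cfg$alpha <= 1)
  if (!cfg$centering %in% c("gene_mean", "gene_median"))
    stop("unknown centering '", cfg$centering, "'", call. = FALSE)
  class(cfg) <- "RunConfig"
  cfg
}

# Stable hash of the fully-resolved config for output provenance.  The
# output directory is where results land, not part of the analysis, so
# it is excluded: identical analyses hash identically wherever written.
.configHash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.applyIsoformMaps <- function(variants, maps) {
  for (m in maps) {
    im <- isoformMap(m$from_isoform, m$to_isoform, m$offset,
                     if (is.null(m$min_valid_target)) 1L
                     else m$min_valid_target)
    sel <- variants$gene == m$gene & variants$isoform == m$from_isoform
    if (!any(sel)) next
    mapped <- harmonizeIsoform(variants[sel, , drop = FALSE], im)
    if (any(!mapped$mappable))
      stop("isoform-specific change(s) cannot be harmonized to ",
           m$to_isoform, ": ",
           paste(mapped$label[!mapped$mappable], collapse = ", "),
           call. = FALSE)
    variants[sel, c("position", "isoform", "label")] <-
      mapped[c("position", "isoform", "label")]
  }
  variants
}

#' Run the end-to-end analysis pipeline
#'
#' Stages, in dependency order: load-or-simulate inputs, isoform
#' harmonization, recurrence calling, lolliplot table, activation
#' scoring (skipped, and reported skipped, when no expression data are
#' available), oncoprint matrix (columns sorted by activation score when
#' scores exist, else by sample id), subgroup-enrichment tests, optional
#' structure mapping.  Every output file carries the config hash in a
#' leading comment line; rerunning an identical config reproduces
#' byte-identical outputs.
#'
#' @param config a [runConfig()] list or the path to a YAML config.
#' @param out_dir overrides `config$out_dir`.
#' @param seed overrides `config$seed`.
#' @return run report: list with `stages` (status data.frame), `outputs`
#'   (named file paths), `summary` (the summary written to
#'   `summary.json`), invisibly.
#' @export
runPipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!inherits(config, "RunConfig")) config <- runConfig(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)
  hdr <- paste0("config_hash=", hash)
  stages <- list()
  outputs <- list()
  note <- function(stage, status) stages[[stage]] <<- status
  set.seed(config$seed)

  # ---- inputs -------------------------------------------------------
  expr <- NULL; seed_genes <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    cs <- config$simulate$cohort
    if (is.null(cs)) cs <- list()
    if (is.null(cs$seed)) cs$seed <- config$seed
    if (!is.null(cs$recurrent_positions))
      cs$recurrent_positions <- as.data.frame(cs$recurrent_positions)
    cohort <- simulateCohort(do.call(cohortSimSpec, cs))
    variants <- cohort$mutations
    samples <- cohort$samples
    amplifications <- cohort$amplifications
    truth <- cohort$truth
    if (!is.null(config$simulate$expression)) {
      es <- config$simulate$expression
      if (is.null(es$seed)) es$seed <- config$seed + 1L
      if (is.null(es$n_samples)) es$n_samples <- nrow(samples)
      sim <- simulateExpression(do.call(expressionSimSpec, es))
      expr <- sim$expr
      # align simulated expression columns with the cohort sample ids
      if (ncol(expr) == nrow(samples)) {
        map <- samples$sample_id
        names(map) <- colnames(expr)
        colnames(expr) <- map
        sim$truth$high_samples <- unname(map[sim$truth$high_samples])
      }
      seed_genes <- sim$truth$signature_genes
      truth$expression <- sim$truth
    }
  } else {
    variants <- readMutationTable(config$inputs$mutations)
    samples <- utils::read.delim(config$inputs$samples,
                                 comment.char = "#",
                                 stringsAsFactors = FALSE)
    amplifications <- if (!is.null(config$inputs$amplifications))
      utils::read.delim(config$inputs$amplifications, comment.char = "#",
                        stringsAsFactors = FALSE)
    else data.frame(sample_id = character(), gene = character())
    if (!is.null(config$inputs$expression)) {
      expr <- readExpressionMatrix(config$inputs$expression)
      seed_genes <- readLines(config$inputs$seed_genes)
      seed_genes <- seed_genes[nzchar(seed_genes)]
    }
  }
  note("inputs", "ok")

  # ---- harmonization ------------------------------------------------
  if (!is.null(config$isoform_maps))
    variants <- .applyIsoformMaps(variants, config$isoform_maps)
  note("harmonize", if (is.null(config$isoform_maps)) "noop" else "ok")

  # ---- recurrence ---------------------------------------------------
  records <- callRecurrent(variants, min_count = config$min_count,
                           pool_external = config$pool_external)
  outputs$recurrence <- .writeTsv(records,
                                  file.path(config$out_dir,
                                            "recurrence.tsv"), hdr)
  note("recurrence", "ok")

  dmaps <- if (!is.null(config$domains)) readDomainConfig(config$domains)
           else list(PPARG = ppargDomainMap(), RXRA = rxraDomainMap())
  lolli <- buildLolliplotTable(records[records$is_recurrent, , drop = FALSE],
                               dmaps)
  outputs$lolliplot <- .writeTsv(lolli,
                                 file.path(config$out_dir, "lolliplot.tsv"),
                                 hdr)
  note("lolliplot", "ok")

  # ---- activation score ---------------------------------------------
  score_res <- NULL; classification <- NULL
  if (!is.null(expr)) {
    sig <- refineSignature(expr, config$anchor_gene, seed_genes,
                           quartile = config$quartile, alpha = config$alpha)
    score_res <- scoreSamples(expr, sig, centering = config$centering)
    classification <- classifyActivation(score_res,
                                         rule = config$threshold_rule)
    sc <- activationScores(score_res)
    outputs$scores <- .writeTsv(
      data.frame(sample_id = names(sc), score = sprintf("%.10g", sc),
                 activation_high = unname(classification[names(sc)]),
                 stringsAsFactors = FALSE),
      file.path(config$out_dir, "scores.tsv"), hdr)
    outputs$signature <- .writeTsv(sig@stats,
                                   file.path(config$out_dir,
                                             "signature.tsv"), hdr)
    note("score", "ok")
  } else {
    note("score", "skipped (no transcriptomic data)")
  }

  # ---- oncoprint ----------------------------------------------------
  coh_var <- variants[variants$source == "cohort", , drop = FALSE]
  sample_order <- if (!is.null(score_res)) {
    ord <- sortByScore(score_res)
    c(ord, sort(setdiff(samples$sample_id, ord)))
  } else sort(samples$sample_id)
  onco <- buildOncoprintMatrix(coh_var, amplifications, sample_order)
  outputs$oncoprint <- .writeTsv(
    data.frame(gene = rownames(onco), as.data.frame(onco,
                                                    check.names = FALSE),
               check.names = FALSE),
    file.path(config$out_dir, "oncoprint.tsv"), hdr)
  note("oncoprint", "ok")

  # ---- enrichment ---------------------------------------------------
  enrich_rows <- NULL
  if (!is.null(classification)) {
    universe <- samples$sample_id
    high <- names(classification)[classification]
    tg <- config$target_gene
    mut_samples <- unique(coh_var$sample_id[coh_var$gene == tg])
    amp_samples <- unique(
      amplifications$sample_id[amplifications$gene == tg])
    tests <- list(mutation = mut_samples, amplification = amp_samples)
    enrich_rows <- do.call(rbind, lapply(names(tests), function(nm) {
      res <- subgroupEnrichment(tests[[nm]], high, universe)
      tab <- contingencyTable(res)
      data.frame(gene = tg, alteration = nm, group = "activation_high",
                 a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
                 odds_ratio = sprintf("%.10g", oddsRatio(res)),
                 p_two_sided = sprintf("%.10g", pValue(res)),
                 direction = direction(res), stringsAsFactors = FALSE)
    }))
    outputs$enrichment <- .writeTsv(enrich_rows,
                                    file.path(config$out_dir,
                                              "enrichment.tsv"), hdr)
    note("enrichment", "ok")
  } else {
    note("enrichment", "skipped (no activation classification)")
  }

  # ---- structure mapping --------------------------------------------
  struct_report <- NULL
  if (!is.null(config$structure)) {
    st <- config$structure
    model <- readStructure(st$pdb)
    chains <- unlist(st$chains)
    offsets <- if (is.null(st$offsets)) integer() else unlist(st$offsets)
    cut <- if (is.null(st$interface_cutoff)) 5.0 else st$interface_cutoff
    rec_changes <- records[records$is_recurrent &
                           records$gene %in% names(chains), , drop = FALSE]
    struct_report <- mapMutationsToStructure(rec_changes, model, chains,
                                             numbering_offset = offsets,
                                             interface_cutoff = cut)
    outputs$structure <- file.path(config$out_dir, "structure.json")
    jsonlite::write_json(list(config_hash = hash, cutoff = cut,
                              mutations = struct_report),
                         outputs$structure, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    note("structure", "ok")
  } else {
    note("structure", "skipped (no structure configured)")
  }

  # ---- summary ------------------------------------------------------
  freq_gene <- config$target_gene
  n_mut <- length(unique(coh_var$sample_id[coh_var$gene == freq_gene]))
  freq <- alterationFrequency(n_mut, nrow(samples))
  summary <- list(
    config_hash = hash,
    seed = config$seed,
    n_samples = nrow(samples),
    n_variant_observations = nrow(variants),
    target_gene = freq_gene,
    mutated_samples = freq$n_altered,
    mutation_percent = freq$percent_1dp,
    n_unique_changes = sum(records$gene == freq_gene),
    n_recurrent = sum(records$is_recurrent & records$gene == freq_gene),
    recurrent_labels = records$label[records$is_recurrent &
                                     records$gene == freq_gene],
    stages = stages)
  if (!is.null(enrich_rows))
    summary$enrichment <- enrich_rows
  outputs$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, outputs$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  report <- list(stages = data.frame(stage = names(stages),
                                     status = unlist(stages),
                                     row.names = NULL,
                                     stringsAsFactors = FALSE),
                 outputs = outputs, summary = summary, truth = truth)
  invisible(report)
}
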
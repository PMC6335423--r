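#' Synthetic bladder-cohort example data
#'
#' A fully synthetic, deterministic example dataset shaped like the
#' published bladder-tumor mutation landscape it emulates: a
#' Sanger-sequenced series of 359 tumors (199 NMIBC, 160 MIBC) with
#' PPARG mutations in 14 samples, and a deep-sequencing series of 455
#' MIBC (405 "TCGA-like" + 50 "MSKCC-like") with PPARG mutations in 14
#' samples.  Across both series there are 21 distinct PPARG changes:
#' six (P113S, R164W, R168K, S249L, I290M, T475M) recur within the
#' cohorts and occur in both NMIBC and MIBC; E3K and M280I appear once
#' each in the cohorts but recur once external-database occurrences are
#' pooled, giving eight recurrent changes in total; the remaining 13
#' (including the gamma-2-specific D7N) are singletons.  RXRA hotspot
#' mutations (S427F/Y) and PPARG amplification calls are included so
#' co-occurrence tests and oncoprints can be exercised.  No sample
#' identifier or count refers to a real patient; counts are arranged to
#' match published summary frequencies only.
#'
#' @return list with `mutations` (variant data.frame, cohort +
#'   external-database rows, PPARG2/RXRA numbering), `amplifications`
#'   (`sample_id`, `gene`), and `samples` (`sample_id`, `cohort`,
#'   `stage`) covering all 814 tumors.
#' @export
bladderCohortFixture <- function() {
  samples <- rbind(
    data.frame(sample_id = sprintf("CIT%03d", 1:199), cohort = "CIT",
               stage = "NMIBC", stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("CIT%03d", 200:359), cohort = "CIT",
               stage = "MIBC", stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("TCGA%03d", 1:405), cohort = "TCGA",
               stage = "MIBC", stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("MSK%03d", 1:50), cohort = "MSKCC",
               stage = "MIBC", stringsAsFactors = FALSE))

  mut <- function(sample, change, gene = "PPARG", iso = "PPARG2",
                  source = "cohort", cohort = NA, stage = NA) {
    if (is.na(cohort)) {
      cohort <- samples$cohort[match(sample, samples$sample_id)]
      stage <- samples$stage[match(sample, samples$sample_id)]
    }
    data.frame(sample_id = sample, cohort = cohort, stage = stage,
               gene = gene, protein_change = change, isoform = iso,
               source = source, stringsAsFactors = FALSE)
  }

  # Sanger series: 14 PPARG-mutated samples, 18 observations (4 samples
  # carry two mutations).  CIT010/020/030 are NMIBC, CIT2xx are MIBC.
  cit <- rbind(
    mut("CIT010", "T475M"), mut("CIT020", "T475M"), mut("CIT210", "T475M"),
    mut("CIT030", "P113S"), mut("CIT220", "P113S"),
    mut("CIT040", "R164W"),
    mut("CIT050", "R168K"),
    mut("CIT035", "S249L"),
    mut("CIT060", "I290M"),
    mut("CIT240", "E3K"),
    mut("CIT070", "M280I"),
    mut("CIT080", "D7N"),
    mut("CIT090", "A61T"),
    mut("CIT250", "S74F"),
    # second mutations on already-counted samples
    mut("CIT010", "E157K"), mut("CIT020", "G197E"),
    mut("CIT210", "R212Q"), mut("CIT030", "Q286H"))

  # Deep-sequencing series: 14 mutated samples, 14 observations.
  ngs <- rbind(
    mut("TCGA010", "T475M"), mut("TCGA020", "T475M"), mut("MSK010", "T475M"),
    mut("TCGA030", "P113S"),
    mut("TCGA040", "R164W"),
    mut("TCGA050", "R168K"),
    mut("TCGA060", "S249L"),
    mut("TCGA070", "I290M"),
    mut("TCGA080", "E324K"), mut("TCGA090", "K358N"),
    mut("TCGA100", "R385W"), mut("TCGA110", "H425Y"),
    mut("TCGA120", "D441N"), mut("MSK020", "P467L"))

  # External-database occurrences (COSMIC/cBioPortal-like); no stable
  # sample identity, counted once per reported entry.
  ext <- function(change, n)
    mut(sprintf("DB_%s_%d", change, seq_len(n)), change,
        source = "external_db", cohort = "COSMIC", stage = "unknown")
  external <- rbind(
    ext("E3K", 2), ext("M280I", 3), ext("T475M", 4),
    ext("P113S", 1), ext("S249L", 1), ext("I290M", 1))

  # RXRA hotspot: 6 MIBC samples in the Sanger series, 28 in the
  # deep-sequencing series.
  rxra <- rbind(
    mut(sprintf("CIT%03d", c(260, 262, 264, 266)), "S427F",
        gene = "RXRA", iso = "RXRA"),
    mut(sprintf("CIT%03d", c(268, 270)), "S427Y", gene = "RXRA",
        iso = "RXRA"),
    mut(sprintf("TCGA%03d", 200:217), "S427F", gene = "RXRA", iso = "RXRA"),
    mut(sprintf("TCGA%03d", 218:225), "S427Y", gene = "RXRA", iso = "RXRA"),
    mut(sprintf("MSK%03d", 30:31), "S427F", gene = "RXRA", iso = "RXRA"))

  raw <- rbind(cit, ngs, external, rxra)
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    ch <- parseProteinChange(raw$protein_change[i], raw$isoform[i])
    cbind(raw[rep(i, nrow(ch)), c("sample_id", "cohort", "stage", "gene",
                                  "source"), drop = FALSE],
          ch[c("ref_aa", "position", "alt_aa", "isoform", "label")])
  })
  mutations <- do.call(rbind, rows)
  rownames(mutations) <- NULL
  validateVariants(mutations)

  amplifications <- data.frame(
    sample_id = c(sprintf("CIT%03d", c(10, seq(100, 128))),     # 30 CIT
                  sprintf("TCGA%03d", c(10, 30, seq(300, 357)))),  # 60 NGS
    gene = "PPARG", stringsAsFactors = FALSE)

  list(mutations = mutations, amplifications = amplifications,
       samples = samples)
}
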
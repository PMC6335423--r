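test_that("protein-change labels parse, expand and round-trip", {
  x <- parseProteinChange("T475M", "PPARG2")
  expect_equal(x$ref_aa, "T")
  expect_equal(x$position, 475L)
  expect_equal(x$alt_aa, "M")
  expect_equal(x$isoform, "PPARG2")

  multi <- parseProteinChange("S427F/Y", "RXRA")
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$alt_aa, c("F", "Y"))
  expect_equal(multi$position, c(427L, 427L))

  # render-then-parse is the identity
  set.seed(42)
  for (i in 1:25) {
    ref <- sample(c("A", "C", "D", "R", "T"), 1)
    alt <- sample(setdiff(c("K", "M", "S", "W", "Y"), ref), 1)
    lab <- paste0(ref, sample.int(505, 1), alt)
    rt <- parseProteinChange(renderProteinChange(
      parseProteinChange(lab, "PPARG2")), "PPARG2")
    expect_equal(rt$label, lab)
  }

  expect_error(parseProteinChange("Q99Q", "PPARG2"), "identical")
  expect_error(parseProteinChange("475M", "PPARG2"), "malformed")
  expect_error(parseProteinChange("TxM", "PPARG2"), "malformed")
  expect_error(parseProteinChange("B12C", "PPARG2"), "invalid amino-acid")
})

test_that("isoform harmonization shifts by the offset and flags gamma-2-specific changes", {
  g1to2 <- isoformMap("PPARG1", "PPARG2", 28)
  out <- harmonizeIsoform(parseProteinChange("T447M", "PPARG1"), g1to2)
  expect_equal(out$position, 475L)
  expect_equal(out$label, "T475M")
  expect_true(out$mappable)

  out2 <- harmonizeIsoform(parseProteinChange("P85S", "PPARG1"), g1to2)
  expect_equal(out2$label, "P113S")

  # E3K and D7N exist only in the longer gamma-2 frame
  g2to1 <- invertIsoformMap(g1to2)
  back <- harmonizeIsoform(parseProteinChange(c("E3K", "D7N"), "PPARG2"),
                           g2to1)
  expect_false(any(back$mappable))
  expect_true(all(back$reason == "isoform_specific"))
  expect_true(all(is.na(back$position)))

  # frame mismatch is a contract error
  expect_error(harmonizeIsoform(parseProteinChange("E3K", "PPARG2"), g1to2),
               "frame mismatch")
})

test_that("harmonization round-trips wherever both directions are defined", {
  set.seed(7)
  for (k in c(5L, 28L, 100L)) {
    fwd <- isoformMap("A", "B", k)
    bwd <- invertIsoformMap(fwd)
    pos <- sample(seq(k + 1L, k + 400L), 20)
    labs <- paste0("T", pos, "M")
    ch <- parseProteinChange(labs, "B")
    there <- harmonizeIsoform(ch, bwd)
    expect_true(all(there$mappable))
    back <- harmonizeIsoform(there, fwd)
    expect_equal(back$position, ch$position)
    expect_equal(back$label, ch$label)
  }
})

test_that("domain annotation places the recurrent mutations in their domains", {
  dm <- ppargDomainMap()
  expect_equal(annotateDomain(c(3, 113), dm), c("A/B", "A/B"))
  expect_equal(annotateDomain(c(164, 168), dm), c("DBD", "DBD"))
  expect_equal(annotateDomain(c(249, 280, 290, 475), dm),
               rep("LBD", 4))
  expect_equal(annotateDomain(215, dm), "linker")
  expect_error(annotateDomain(506, dm), "outside protein length")
  expect_error(annotateDomain(parseProteinChange("T447M", "PPARG1"), dm),
               "isoform frame")
})

test_that("domain maps read from YAML config match the built-ins", {
  path <- system.file("extdata", "domains.yaml", package = "ppargmut")
  maps <- readDomainConfig(path)
  expect_named(maps, c("PPARG", "RXRA"))
  expect_equal(maps$PPARG@domains, ppargDomainMap()@domains)
  expect_equal(annotateDomain(427, maps$RXRA), "LBD")
})

test_that("recurrence calling counts, pools and sorts correctly", {
  v <- tinyVariants()
  rec <- callRecurrent(v, min_count = 2, pool_external = TRUE)
  t475 <- rec[rec$label == "T475M", ]
  expect_equal(t475$n_cohort, 4L)
  expect_true(t475$is_recurrent)
  expect_equal(t475$recurrence_basis, "cohort_only")
  expect_equal(t475$stages_seen, "MIBC,NMIBC")

  e3k <- rec[rec$label == "E3K", ]
  expect_equal(e3k$n_cohort, 1L)
  expect_equal(e3k$n_external, 1L)
  expect_true(e3k$is_recurrent)
  expect_equal(e3k$recurrence_basis, "pooled")

  m280 <- rec[rec$label == "M280I", ]
  expect_false(m280$is_recurrent)
  expect_equal(m280$recurrence_basis, "none")

  # pooling off drops the pooled call but not the cohort-only one
  rec_np <- callRecurrent(v, min_count = 2, pool_external = FALSE)
  expect_false(rec_np$is_recurrent[rec_np$label == "E3K"])
  expect_true(rec_np$is_recurrent[rec_np$label == "T475M"])

  # sorted by (gene, position)
  expect_equal(rec$position, sort(rec$position))
})

test_that("recurrence deduplicates cohort reports and conserves counts", {
  v <- tinyVariants()
  v_dup <- rbind(v, v[v$source == "cohort", ][1:3, ])   # repeated reports
  rec <- callRecurrent(v_dup)
  n_cohort_obs <- nrow(unique(v[v$source == "cohort",
                                c("sample_id", "gene", "label")]))
  n_ext_obs <- sum(v$source == "external_db")
  expect_equal(sum(rec$n_total), n_cohort_obs + n_ext_obs)
  expect_equal(rec, callRecurrent(v))   # duplicates change nothing
})

test_that("recurrence is monotone in min_count and pooling", {
  set.seed(11)
  genes <- c("PPARG", "RXRA")
  v <- do.call(rbind, lapply(1:60, function(i) {
    lab <- paste0("T", sample.int(400, 1) + 10, "M")
    g <- sample(genes, 1)
    data.frame(sample_id = paste0("s", sample.int(30, 1)), cohort = "X",
               stage = "MIBC", gene = g, ref_aa = "T",
               position = parseProteinChange(lab, "F")$position,
               alt_aa = "M", isoform = "F", label = lab,
               source = sample(c("cohort", "external_db"), 1,
                               prob = c(0.8, 0.2)),
               stringsAsFactors = FALSE)
  }))
  prev <- NULL
  for (mc in 1:4) {
    rec <- callRecurrent(v, min_count = mc, pool_external = TRUE)
    cur <- rec$label[rec$is_recurrent]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
    # enabling pooling never removes recurrent records
    off <- callRecurrent(v, min_count = mc, pool_external = FALSE)
    expect_true(all(off$label[off$is_recurrent] %in% cur))
  }
})

test_that("mixed isoform frames within a gene are rejected", {
  v <- rbind(tinyVariants(),
             within(tinyVariants()[1, ], isoform <- "PPARG1"))
  expect_error(callRecurrent(v), "harmonize")
})

test_that("the example bladder cohort reproduces the published recurrence structure", {
  fx <- bladderCohortFixture()
  rec <- callRecurrent(fx$mutations, min_count = 2, pool_external = TRUE)
  pparg <- rec[rec$gene == "PPARG", ]
  expect_equal(nrow(pparg), 21L)                       # 21 unique changes
  expect_equal(sum(pparg$is_recurrent), 8L)            # 8 with pooling
  expect_setequal(pparg$label[pparg$is_recurrent],
                  c("E3K", "P113S", "R164W", "R168K", "S249L", "M280I",
                    "I290M", "T475M"))
  # six recurrent within the cohorts alone, each seen in both stages
  core <- pparg[pparg$recurrence_basis == "cohort_only", ]
  expect_equal(nrow(core), 6L)
  expect_true(all(core$stages_seen == "MIBC,NMIBC"))
  # E3K and M280I only become recurrent through database pooling
  pooled <- pparg$label[pparg$recurrence_basis == "pooled"]
  expect_setequal(pooled, c("E3K", "M280I"))
  # T475M is the most frequent recurrent change
  expect_equal(pparg$label[which.max(pparg$n_total)], "T475M")
})

test_that("lolliplot table aggregates, sorts and annotates", {
  fx <- bladderCohortFixture()
  rec <- callRecurrent(fx$mutations)
  lolli <- buildLolliplotTable(rec[rec$is_recurrent & rec$gene == "PPARG", ],
                               ppargDomainMap())
  expect_equal(nrow(lolli), 8L)
  expect_equal(lolli$position, sort(lolli$position))
  expect_equal(lolli$domain[lolli$label == "T475M"], "LBD")
  expect_equal(lolli$domain[lolli$label == "E3K"], "A/B")
  expect_equal(lolli$domain[lolli$label == "R164W"], "DBD")
  # counts conserved
  expect_equal(sum(lolli$n_total),
               sum(rec$n_total[rec$is_recurrent & rec$gene == "PPARG"]))
  # duplicate rows collapse into one with summed counts
  dup <- rbind(rec[rec$label == "T475M", ], rec[rec$label == "T475M", ])
  one <- buildLolliplotTable(dup, ppargDomainMap())
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_total, 2 * rec$n_total[rec$label == "T475M"])
  # empty in, empty out
  expect_equal(nrow(buildLolliplotTable(rec[0, ], ppargDomainMap())), 0L)
})

test_that("oncoprint matrix encodes alteration classes per cell", {
  v <- tinyVariants()[tinyVariants()$source == "cohort", ]
  amps <- data.frame(sample_id = c("s1", "s9"), gene = "PPARG")
  order <- c("s9", paste0("s", 1:6))
  m <- buildOncoprintMatrix(v, amps, order)
  expect_equal(colnames(m), order)
  expect_equal(m["PPARG", "s1"], "mutation+amplification")
  expect_equal(m["PPARG", "s2"], "mutation")
  expect_equal(m["PPARG", "s9"], "amplification")
  # no alterations -> all none
  m0 <- buildOncoprintMatrix(v[0, ], amps[0, ], order)
  expect_equal(dim(m0), c(0L, 7L))
  m1 <- buildOncoprintMatrix(v[0, ], data.frame(sample_id = character(),
                                                gene = character()),
                             order)
  expect_true(all(m1 == "none"))
  # sample missing from the order is a contract error
  expect_error(buildOncoprintMatrix(v, amps, c("s1", "s2")), "absent")
  # external rows are refused
  expect_error(buildOncoprintMatrix(tinyVariants(), amps, order),
               "cohort")
})

test_that("mutation tables round-trip through TSV with comments and multi-alleles", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("# example mutation table",
               paste("sample_id", "cohort", "stage", "gene",
                     "protein_change", "isoform", "source", sep = "\t"),
               paste("s1", "C", "MIBC", "RXRA", "S427F/Y", "RXRA",
                     "cohort", sep = "\t"),
               paste("s2", "C", "NMIBC", "PPARG", "T475M", "PPARG2",
                     "cohort", sep = "\t")), tsv)
  v <- readMutationTable(tsv)
  expect_equal(nrow(v), 3L)   # multi-allele expanded
  expect_setequal(v$label, c("S427F", "S427Y", "T475M"))
})
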
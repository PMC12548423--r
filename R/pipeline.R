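# Orchestration: simulate -> profile -> context -> report, with a manifest.

#' Run the simulate/profile/context/report pipeline
#'
#' Generates a ground-truth provirus, simulates deamination, profiles the
#' edited provirus against its template, extracts target-site contexts and a
#' logo, calls the target-site preference, and writes all outputs plus a
#' JSON manifest (inputs, parameters, package version, seed) enabling exact
#' re-runs. All randomness flows from `seed`.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed propagated to generator and simulator.
#' @param totalLen,ltrLen,gcFraction,nTggCodons template parameters, see
#'   [generateProvirus()].
#' @param config an [editConfig()]; its `seed` is overridden by `seed`.
#' @param window,step sliding-window parameters, see [windowCounts()].
#' @return invisibly, a list with the template, simulation, profile, logo,
#'   preference call, summary row, and manifest path.
#' @export
runPipeline <- function(outDir, seed = 1L,
                        totalLen = 8000L, ltrLen = 1300L,
                        gcFraction = 0.42, nTggCodons = 20L,
                        config = editConfig(),
                        window = 400L, step = 100L) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  config$seed <- as.integer(seed)

  template <- generateProvirus(totalLen = totalLen, ltrLen = ltrLen,
                               gcFraction = gcFraction,
                               nTggCodons = nTggCodons, seed = seed)
  sim <- simulateEditing(template, config)

  tmplSet <- Biostrings::DNAStringSet(templateSeq(template))
  names(tmplSet) <- "template"
  writeFasta(tmplSet, file.path(outDir, "template.fa"))
  writeFasta(sim$edited, file.path(outDir, "edited.fa"))
  writeTruthTsv(sim$truth, file.path(outDir, "truth.tsv"))

  aln <- ingestAlignedFasta(
    c(template = templateSeq(template),
      edited = as.character(sim$edited[[1L]])),
    refId = "template"
  )[["edited"]]

  records <- classifyMismatches(aln)
  writeMismatchTsv(records, file.path(outDir, "mismatches.tsv"))
  profile <- profileAlignment(aln)
  writeProfileJson(profile, file.path(outDir, "profile.json"))

  track <- windowCounts(records, alignedRefLength(profile),
                        window = window, step = step)
  writeTrackTsv(track, file.path(outDir, "windows.tsv"))

  gaRecords <- records[records$klass == "G>A", , drop = FALSE]
  sites <- extractContexts(gaRecords, aln, source = "reference")
  logo <- if (nrow(sites)) buildLogo(sites) else NULL
  if (!is.null(logo)) writeLogoJson(logo, file.path(outDir, "logo.json"))
  minusComp <- table(factor(.compChars(.chars(templateSeq(template))),
                            levels = DNA_BASES))
  bg <- stats::setNames(as.numeric(minusComp) / sum(minusComp), DNA_BASES)
  pref <- classifyPreference(sites, background = bg)

  row <- makeRow(profile, name = "simulated")
  utils::write.table(row[, setdiff(names(row),
                                   c("pctGAFull", "GAperKbFull"))],
                     file.path(outDir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifestPath <- file.path(outDir, "manifest.json")
  manifest <- list(
    package = "hypermutR",
    version = as.character(utils::packageVersion("hypermutR")),
    seed = as.integer(seed),
    parameters = list(
      totalLen = totalLen, ltrLen = ltrLen, gcFraction = gcFraction,
      nTggCodons = nTggCodons, window = window, step = step,
      edit = config[setdiff(names(config), "contextWeights")],
      contextWeights = as.list(config$contextWeights)
    ),
    outputs = list.files(outDir)
  )
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(template = template, sim = sim, profile = profile,
                 logo = logo, preference = pref, row = row,
                 manifest = manifestPath))
}
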
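.PIPELINE_KEYS <- c("seed", "outdir", "stages", "synth", "spectrum",
                    "signatures")

#' Default pipeline configuration
#'
#' A small synth -> spectrum -> signatures run: two populations, one with a
#' planted 1.5x boost of the four signature-1 classes, doubleton spectrum,
#' ATA>C normalization, rank-2 NMF with ICA initialization.
#'
#' @param outdir output directory.
#' @param seed integer seed used by every stochastic stage.
#' @return named configuration list.
#' @export
default_config <- function(outdir = tempfile("mutspect_run"), seed = 1) {
  list(
    seed = seed,
    outdir = outdir,
    stages = c("synth", "spectrum", "signatures"),
    synth = list(
      genome_length = 60000, cpg_boost = 1,
      populations = list(
        list(name = "POP1", region = "regionA", n_samples = 20,
             boost_classes = c("TCT>T", "TCC>T", "CCC>T", "ACC>T"),
             boost = 1.5),
        list(name = "POP2", region = "regionB", n_samples = 20)),
      n_variants = 20000, freq_source = "fixed_f"),
    spectrum = list(stratum = "f2", normalization = "ata_c"),
    signatures = list(rank = 2, init = "ica", n_starts = 10)
  )
}

#' Save / load a pipeline configuration
#' @param config configuration list.
#' @param path YAML file.
#' @return `path` (save) or the configuration list (load).
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the staged analysis pipeline
#'
#' Executes the configured stages in dependency order (`synth` ->
#' `spectrum` -> `signatures`), writing every artifact under
#' `config$outdir` and returning a manifest with an MD5 checksum per file.
#' Identical configurations produce identical checksums. Unknown
#' configuration keys are rejected by name before any computation; a stage
#' failure yields a partial manifest carrying the failure record.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @return object of class `pipeline_manifest`: list with `files`
#'   (data.frame: file, md5), `failed` (NULL or list with `stage`,
#'   `message`), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stop("config$seed is required")
  outdir <- config$outdir
  if (is.null(outdir)) stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  ord <- c("synth", "spectrum", "signatures")
  bad <- setdiff(stages, ord)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- ord[ord %in% stages]

  files <- character(0)
  failed <- NULL
  state <- new.env(parent = emptyenv())
  log_lines <- c(paste("mutspect pipeline | seed", config$seed),
                 paste("stages:", paste(stages, collapse = " -> ")))

  run_stage <- function(name, fn) {
    if (!is.null(failed)) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- list(stage = name, message = conditionMessage(res))
      log_lines <<- c(log_lines, paste("FAILED", name, ":", failed$message))
    } else {
      files <<- c(files, res)
      log_lines <<- c(log_lines, paste("done", name))
    }
  }

  if ("synth" %in% stages) run_stage("synth", function() {
    sy <- config$synth
    ref <- generate_reference(genome_spec(sy$genome_length,
                                          cpg_boost = sy$cpg_boost %||% 1,
                                          seed = config$seed))
    pops <- lapply(sy$populations, function(p) {
      mult <- NULL
      if (!is.null(p$boost_classes)) {
        mult <- setNames(rep(p$boost, length(p$boost_classes)),
                         unlist(p$boost_classes))
      }
      population_spec(p$name, p$region, p$n_samples, class_multipliers = mult)
    })
    panel <- generate_panel(ref, pops, sy$n_variants,
                            freq_source = sy$freq_source %||% "fixed_f",
                            seed = config$seed)
    state$ref <- ref
    state$panel <- panel
    c(write_reference_fasta(ref, file.path(outdir, "reference.fasta")),
      write_panel_vcf(panel, file.path(outdir, "panel.vcf")),
      write_sample_metadata(panel$samples, file.path(outdir, "samples.tsv")),
      write_truth_json(panel$truth[c("class", "origin", "allele_count")],
                       file.path(outdir, "truth.json")))
  })

  if ("spectrum" %in% stages) run_stage("spectrum", function() {
    if (is.null(state$panel)) stop("spectrum stage needs the synth stage")
    sp <- config$spectrum
    counts <- count_spectrum(state$panel, state$ref,
                             stratum = sp$stratum %||% "f2")
    intens <- normalize_spectrum(counts, mode = sp$normalization %||% "ata_c")
    state$counts <- counts
    state$intens <- intens
    c(write_spectrum_tsv(counts, file.path(outdir, "spectrum.tsv")),
      write_spectrum_tsv(intens, file.path(outdir, "intensity.tsv")))
  })

  if ("signatures" %in% stages) run_stage("signatures", function() {
    if (is.null(state$intens)) stop("signatures stage needs the spectrum stage")
    sg <- config$signatures
    fit <- nmf_fit(state$intens, rank = sg$rank %||% 2,
                   init = sg$init %||% "ica", seed = config$seed)
    c(write_spectrum_tsv(fit$weights, file.path(outdir, "signatures.tsv")),
      {
        p <- file.path(outdir, "loadings.tsv")
        utils::write.table(data.frame(factor = rownames(fit$loadings),
                                      fit$loadings, check.names = FALSE),
                           p, sep = "\t", quote = FALSE, row.names = FALSE)
        p
      })
  })

  log_path <- file.path(outdir, "log.txt")
  writeLines(log_lines, log_path)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  structure(list(files = manifest, failed = failed, config = config),
            class = "pipeline_manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
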
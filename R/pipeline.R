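#' @name cli_report
#' @title One-config orchestration of the full analysis
#'
#' @description
#' Runs the full analysis from a single configuration (an R list or a YAML
#' file): simulate or ingest a cohort, compute fibrotic scores and strata,
#' run differential expression, select the fibrosis signature, cluster
#' samples on the signature, classify progenitor archetypes from a 2x2
#' design, intersect the modulated sets, and scan a UTR for seed sites.
#' Every stage writes TSV outputs under the configured directory and is
#' recorded in a machine-readable JSON report. Identical configuration and
#' seed give byte-identical outputs.
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Default pipeline configuration
#'
#' @param seed master RNG seed; stage generators derive their seeds from it.
#' @param out_dir output directory.
#' @return a configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, out_dir = tempfile("fibromir_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    threshold = 0.25,
    r_min = 0.5,
    k = 25,
    de = list(padj = 0.05, lfc = 1),
    clustering_k = 2,
    archetype = list(e_min = 1, l_min = 1),
    cohort = list(),
    design = list(),
    mirna_seq = "ACAGCAGGCACAGACAGGCAGU",
    utr = list(utr_length = 500,
               planted = data.frame(position = c(100, 300),
                                    site_type = c("8mer", "7mer-m8")))
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("'config' must be a list or a YAML file path")
  defaults <- default_pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.list(config$utr) && is.list(config$utr$planted)) {
    config$utr$planted <- as.data.frame(config$utr$planted)
  }
  # any configured input path must resolve before any stage runs
  for (nm in c("counts", "samples", "markers", "utr_fasta")) {
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]])) {
      stopf("configured %s path '%s' does not exist", nm, config[[nm]])
    }
  }
  config
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages run in dependency order: data (simulate or ingest), fibrotic
#' scoring, differential expression (DMD vs control), signature selection,
#' sample clustering on the signature, 2x2 design archetypes plus the
#' intersection of the DMD-modulated and archetype miRNA sets, and seed
#' scanning. A failing stage is recorded in the report and its dependents
#' are skipped; completed outputs are kept.
#'
#' @param config configuration list or YAML file path; see
#'   [default_pipeline_config()] for the recognized fields. Supplying
#'   `counts`, `samples` and `markers` TSV paths switches the data stage
#'   from simulation to ingestion.
#' @param out_dir output directory (overrides the config entry).
#' @return the run report, invisibly: per-stage status, parameters, output
#'   files and row counts, plus seed and package version. Also written to
#'   `report.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_pipeline_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  report <- list(
    package = "fibromiR",
    version = as.character(utils::packageVersion("fibromiR")),
    seed = config$seed,
    stages = list()
  )
  state <- new.env(parent = emptyenv())

  record <- function(name, fun, needs = character()) {
    failed <- vapply(report$stages, function(s) s$status != "ok", logical(1))
    blocked <- intersect(needs,
                         names(report$stages)[failed])
    if (length(blocked) > 0) {
      report$stages[[name]] <<- list(name = name, status = "skipped",
                                     reason = paste("needs", blocked[1]))
      return(invisible(NULL))
    }
    warns <- character()
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(name = name, status = "failed",
                                     error = conditionMessage(res),
                                     warnings = warns)
    } else {
      res$name <- name
      res$status <- "ok"
      res$warnings <- warns
      # record file names relative to out_dir so the report (and reruns in
      # different directories) are byte-identical under the same seed
      if (!is.null(res$outputs)) res$outputs <- basename(res$outputs)
      report$stages[[name]] <<- res
    }
    invisible(NULL)
  }
  path_in <- function(f) file.path(config$out_dir, f)

  record("data", function() {
    if (!is.null(config$counts)) {
      state$counts <- as.matrix(read.delim(config$counts, row.names = 1,
                                           check.names = FALSE))
      state$samples <- read.delim(config$samples, stringsAsFactors = FALSE)
      state$markers <- read.delim(config$markers, stringsAsFactors = FALSE)
      list(source = "files", rows = nrow(state$counts), outputs = character())
    } else {
      sim <- do.call(simulate_cohort,
                     c(config$cohort, list(seed = config$seed)))
      state$counts <- sim$counts
      state$samples <- sim$samples
      state$markers <- sim$markers
      state$truth <- sim$mirnas
      outs <- c(
        write_matrix_tsv(sim$counts, path_in("counts.tsv"), "mirna_id"),
        write_tsv(sim$samples, path_in("samples.tsv")),
        write_tsv(sim$markers, path_in("markers.tsv")),
        write_tsv(sim$mirnas, path_in("mirna_truth.tsv"))
      )
      list(source = "simulate_cohort", rows = nrow(sim$counts),
           outputs = outs)
    }
  })

  record("score", function() {
    ann <- annotate_fibrosis(state$markers, threshold = config$threshold,
                             groups = state$samples$group)
    state$annotation <- ann
    list(rows = nrow(ann),
         outputs = write_tsv(ann, path_in("fibrosis_annotation.tsv")))
  }, needs = "data")

  record("de", function() {
    de <- differential_expression(state$counts,
                                  factor(state$samples$group,
                                         levels = c("control", "DMD")))
    state$de <- de
    state$modulated_dmd <- de$mirna_id[de$padj < config$de$padj &
                                         abs(de$log2FC) >= config$de$lfc]
    list(rows = nrow(de),
         outputs = write_tsv(de, path_in("de_results.tsv")))
  }, needs = "data")

  record("signature", function() {
    log2n <- normalized_log2(state$counts)
    sig <- correlate_with_score(log2n, state$annotation)
    sig <- select_signature(sig, r_min = config$r_min, k = config$k)
    state$log2n <- log2n
    state$signature <- sig
    list(rows = nrow(sig), n_selected = sum(sig$selected),
         outputs = write_tsv(sig, path_in("signature.tsv")))
  }, needs = c("data", "score"))

  record("clustering", function() {
    # samples are clustered on the miRNAs deregulated between the High and
    # Low strata: a two-directional set (induced and repressed miRNAs) is
    # required for the correlation distance between samples to carry the
    # stratum block structure
    strata_de <- differential_expression(
      state$counts, factor(state$annotation$stratum, levels = c("Low", "High"))
    )
    sel <- strata_de$mirna_id[strata_de$padj < config$de$padj &
                                abs(strata_de$log2FC) >= config$de$lfc]
    if (length(sel) < 2) stopf("fewer than two strata-modulated miRNAs to cluster")
    z <- zscore_rows(state$log2n[sel, , drop = FALSE])
    hc <- hac_complete(z, axis = "cols")
    labels <- stats::cutree(hc, k = config$clustering_k)
    out <- data.frame(sample_id = names(labels), cluster = unname(labels),
                      stringsAsFactors = FALSE)
    merges <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                         height = hc$height)
    list(rows = nrow(out), n_modulated = length(sel),
         outputs = c(write_tsv(out, path_in("sample_clusters.tsv")),
                     write_tsv(merges, path_in("sample_merges.tsv"))))
  }, needs = c("score", "signature"))

  record("archetypes", function() {
    sim <- do.call(simulate_design,
                   c(config$design, list(seed = config$seed + 1)))
    cm <- condition_means(sim$counts, sim$samples$condition)
    calls <- classify_archetypes(cm, e_min = config$archetype$e_min,
                                 l_min = config$archetype$l_min)
    state$archetypes <- calls
    venn <- intersect_modulated(
      state$modulated_dmd,
      calls$mirna_id[calls$class != "unclassified"]
    )
    venn_df <- data.frame(n_dmd_only = venn$n_a_only, n_both = venn$n_both,
                          n_design_only = venn$n_b_only)
    list(rows = nrow(calls),
         outputs = c(write_tsv(calls, path_in("archetypes.tsv")),
                     write_tsv(venn_df, path_in("venn_counts.tsv")),
                     write_tsv(venn$membership, path_in("venn_membership.tsv"))))
  }, needs = "de")

  record("seedscan", function() {
    if (!is.null(config$utr_fasta)) {
      utrs <- read_fasta(config$utr_fasta)
    } else {
      sim <- simulate_utr_sites(config$utr$utr_length, config$mirna_seq,
                                planted = config$utr$planted,
                                seed = config$seed + 2)
      utrs <- c(UTR1 = sim$sequence)
    }
    sites <- do.call(rbind, lapply(names(utrs), function(id) {
      seed_sites(config$mirna_seq, utrs[[id]], utr_id = id)
    }))
    list(rows = nrow(sites),
         outputs = c(write_tsv(sites, path_in("seed_sites.tsv")),
                     write_tsv(sites_to_bed(sites), path_in("seed_sites.bed"))))
  }, needs = character())

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, file.path(config$out_dir, "report.json"))
  invisible(report)
}
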
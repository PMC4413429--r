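#' Default pipeline configuration
#'
#' Every default is echoed into the run manifest, so no setting is silent.
#' In simulation mode (`simulate = TRUE`, the default) the generator fields
#' of [sim_config()] may be supplied as top-level keys; in file mode, paths
#' to an expression TSV + metadata TSV, an annotation, and coverage tracks
#' are required.
#'
#' @param ... Overrides of the defaults (see Details in the package
#'   vignette). File-mode keys: `expression`, `metadata`, `annotation`,
#'   `annotation_dialect`, `tracks` (list of lists with `path`, `dialect`,
#'   `assay`, `genotype`), `gmt`.
#' @return Named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    simulate = TRUE,
    transform = "vst",          # "vst" or "log2"
    fc_threshold = 2,
    p_threshold = 0.05,
    p_mode = "raw",             # "raw" or "adjusted"
    span = 6000, window = 100, slide = 20,
    proximal_halfwidth = 500,
    strand_flip = TRUE,
    depth_norm = TRUE,
    write_per_gene = FALSE,
    gmt = NULL,
    seed = 1)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  unknown_ok <- c(names(formals(sim_config)),
                  "expression", "metadata", "annotation",
                  "annotation_dialect", "tracks")
  bad <- setdiff(names(over), c(names(defaults), unknown_ok))
  if (length(bad)) stop2("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a flat JSON file
#' @param path Path to a JSON object of configuration keys.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full expression-to-chromatin pipeline
#'
#' Executes the complete chain: input acquisition (synthetic generation or
#' file loading), variance-stabilizing transform, robust spline
#' normalization, moderated-t differential expression with fold-change /
#' p-value calls, TSS stratification, depth normalization of coverage
#' tracks, per-stratum composite profiles for every track, paired WT-vs-KO
#' proximal-signal comparisons per assay and stratum (BH-adjusted across the
#' family), and optional gene-set enrichment. Writes a TSV/JSON report
#' bundle that is byte-identical for a fixed config and seed (manifests
#' carry no timestamps).
#'
#' @param config A [pipeline_config()], a list of overrides, or a path to a
#'   JSON config file.
#' @param out_dir Report directory (created; existing files overwritten).
#' @param seed Overrides the config seed.
#' @return Invisibly, a list with all intermediate objects (`annotation`,
#'   `de`, `strata`, `tracks`, `profiles`, `comparisons`, `enrichment`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  if (is_string(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "PipelineConfig")) config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (isTRUE(config$simulate)) {
    sim_keys <- intersect(names(config), names(formals(sim_config)))
    sim <- stage("simulate",
                 simulate_dataset(do.call(sim_config, config[sim_keys])))
    annotation <- sim$annotation; expr <- sim$expression
    tracks <- sim$tracks; truth <- sim$truth
  } else {
    annotation <- stage("load_annotation", read_annotation(
      config$annotation, dialect = config$annotation_dialect %||% "bed6"))
    meta <- stage("load_metadata", utils::read.delim(config$metadata))
    expr <- stage("load_expression",
                  read_expression(config$expression, meta))
    tracks <- stage("load_tracks", lapply(config$tracks, function(tr)
      read_coverage(tr$path, dialect = tr$dialect %||% "bedgraph",
                    annotation = annotation,
                    sample_id = tr$sample_id %||%
                      tools::file_path_sans_ext(basename(tr$path)),
                    assay = tr$assay %||% NA_character_,
                    genotype = tr$genotype %||% NA_character_)))
    names(tracks) <- vapply(tracks, function(t) t$sample_id, character(1))
    truth <- NULL
  }

  transformed <- stage("vst", vst_transform(expr, method = config$transform))
  normalized <- stage("rsn", rsn_normalize(transformed))
  fit <- stage("fit_moderation", fit_moderation(normalized))
  de <- stage("moderated_t", moderated_t_test(normalized, fit))
  de <- stage("filter_de", filter_de(de, fc_threshold = config$fc_threshold,
                                     p_threshold = config$p_threshold,
                                     p_mode = config$p_mode))
  strata <- stage("stratify", stratify_tss(de, annotation))
  if (isTRUE(config$depth_norm))
    tracks <- stage("depth_normalize", depth_normalize(tracks))
  grid <- stage("grid", window_grid(config$span, config$window, config$slide))

  strata_names <- c("down", "up", "unchanged")
  profiles <- list()
  excluded <- list()
  for (id in names(tracks)) for (s in strata_names) {
    if (!length(strata[[s]])) next
    p <- stage("composite", composite_profile(
      tracks[[id]], annotation, strata[[s]], grid, gene_set_id = s,
      strand_flip = isTRUE(config$strand_flip)))
    profiles[[paste(id, s, sep = ".")]] <- p
    excluded[[paste(id, s, sep = ".")]] <- length(p$excluded)
  }

  comparisons <- list()
  for (assay in c("H3ac", "input")) {
    wt <- tracks[vapply(tracks, function(t)
      identical(t$assay, assay) && identical(t$genotype, "WT"), logical(1))]
    ko <- tracks[vapply(tracks, function(t)
      identical(t$assay, assay) && identical(t$genotype, "KO"), logical(1))]
    if (!length(wt) || !length(ko)) next
    for (i in seq_len(min(length(wt), length(ko)))) for (s in strata_names) {
      if (!length(strata[[s]])) next
      pw <- profiles[[paste(wt[[i]]$sample_id, s, sep = ".")]]
      pk <- profiles[[paste(ko[[i]]$sample_id, s, sep = ".")]]
      cmp <- stage("compare", compare_from_profiles(
        pw, pk, proximal_halfwidth = config$proximal_halfwidth, stratum = s))
      cmp$assay <- assay
      comparisons[[length(comparisons) + 1L]] <- cmp
    }
  }
  cmp_tab <- data.frame(
    stratum = vapply(comparisons, `[[`, character(1), "stratum"),
    assay = vapply(comparisons, `[[`, character(1), "assay"),
    n = vapply(comparisons, `[[`, numeric(1), "n"),
    effect_wt_minus_ko = vapply(comparisons, `[[`, numeric(1), "effect"),
    p_value = vapply(comparisons, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  cmp_tab$p_adj <- p.adjust(cmp_tab$p_value, method = "BH")

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    gsc <- stage("load_gmt", read_gmt(config$gmt))
    universe <- de$table$gene_id
    enrichment <- stage("enrich", list(
      down = enrichment_test(strata$down, universe, gsc),
      up = enrichment_test(strata$up, universe, gsc)))
  }

  # ---- report bundle ----
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(de$table, "de_table.tsv")
  writeLines(strata$down, file.path(out_dir, "genes_down.txt"))
  writeLines(strata$up, file.path(out_dir, "genes_up.txt"))
  for (nm in names(profiles))
    write_composite(profiles[[nm]],
                    file.path(out_dir, sprintf("composite_%s.tsv", nm)),
                    per_gene = isTRUE(config$write_per_gene))
  wt(cmp_tab, "comparisons.tsv")
  if (!is.null(enrichment)) {
    wt(as.data.frame(enrichment$down), "enrichment_down.tsv")
    wt(as.data.frame(enrichment$up), "enrichment_up.tsv")
  }
  manifest <- list(
    tool = "chipcomposite",
    version = as.character(utils::packageVersion("chipcomposite")),
    seed = config$seed,
    config = lapply(unclass(config), function(v) v %||% NA),
    moderation = list(d0 = if (is.infinite(fit$d0)) "Inf" else fit$d0,
                      s0sq = fit$s0sq, df_residual = fit$df_residual),
    strata = list(down = length(strata$down), up = length(strata$up),
                  unchanged = length(strata$unchanged),
                  dropped = length(strata$dropped)),
    boundary_exclusions = excluded,
    pairing = "single library per genotype: inference pairs genes, not samples",
    vst_lambda = attr(transformed, "vst_lambda"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(annotation = annotation, expression = expr,
                 normalized = normalized, de = de, strata = strata,
                 tracks = tracks, profiles = profiles,
                 comparisons = comparisons, comparison_table = cmp_tab,
                 enrichment = enrichment, truth = truth,
                 manifest = manifest, out_dir = out_dir))
}
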
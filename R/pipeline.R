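.default_config <- function() list(
  simulate = NULL,
  inputs = NULL,
  pop_a = "POP_A",
  pop_b = "POP_B",
  species = "mouse",
  signature = list(k = 10L, min_mean = 0),
  validation_k = 200L,
  markers = list(n_top = 10L, fc_threshold = 2, q_threshold = 0.05,
                 order_by = "significance"),
  gsea = list(n_perm = 1000L, weight_p = 1),
  seed = 1L,
  out_dir = "progmark_out"
)

.merge_strict <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    pm_config_error(paste0("config: unknown key(s): ",
                           paste0(path, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- .merge_strict(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Validate a run configuration
#'
#' Reads a YAML config (or takes a list), checks it against the schema,
#' fills every default, and returns the fully materialized configuration.
#' Exactly one of the `simulate` block (simulation parameters, see
#' [sim_params()]) and the `inputs` block (paths to bulk/single-cell
#' matrices and the surface annotation) must be present. Unknown keys and
#' type violations are named-field errors.
#'
#' @param config path to a YAML file, or a list.
#' @return a validated `run_config` list with all defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      pm_config_error(paste0("validate_config: no such file: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    pm_config_error("validate_config: config must be a list or a YAML path")
  defaults <- .default_config()
  # simulate/inputs blocks have their own schemas
  sim_block <- config$simulate
  in_block <- config$inputs
  config$simulate <- NULL; config$inputs <- NULL
  cfg <- .merge_strict(defaults, config)
  if (is.null(sim_block) == is.null(in_block))
    pm_config_error("config: exactly one of `simulate` and `inputs` must be supplied")
  if (!is.null(sim_block)) {
    sim_defaults <- formals(sim_params)
    unknown <- setdiff(names(sim_block), names(sim_defaults))
    if (length(unknown))
      pm_config_error(paste0("config: unknown simulate key(s): simulate.",
                             paste(unknown, collapse = ", simulate.")))
    if (is.null(sim_block$seed)) sim_block$seed <- cfg$seed
    cfg$simulate <- do.call(sim_params, sim_block)
  }
  if (!is.null(in_block)) {
    need <- c("bulk", "sc", "surface")
    miss <- setdiff(need, names(in_block))
    if (length(miss))
      pm_config_error(paste0("config: inputs block missing: inputs.",
                             paste(miss, collapse = ", inputs.")))
    allowed <- c(need, "sc_format", "bulk_scale", "sc_scale")
    unknown <- setdiff(names(in_block), allowed)
    if (length(unknown))
      pm_config_error(paste0("config: unknown inputs key(s): inputs.",
                             paste(unknown, collapse = ", inputs.")))
    in_block$sc_format <- in_block$sc_format %||% "dense-tsv"
    in_block$bulk_scale <- in_block$bulk_scale %||% "counts"
    in_block$sc_scale <- in_block$sc_scale %||% "counts"
    cfg$inputs <- in_block
  }
  if (cfg$signature$k < 1)
    pm_config_error("config: signature.k must be >= 1")
  if (cfg$validation_k < 1)
    pm_config_error("config: validation_k must be >= 1")
  if (cfg$markers$n_top < 1)
    pm_config_error("config: markers.n_top must be >= 1")
  if (!cfg$markers$order_by %in% c("significance", "log2fc"))
    pm_config_error("config: markers.order_by must be 'significance' or 'log2fc'")
  if (cfg$gsea$n_perm < 100)
    pm_config_error("config: gsea.n_perm must be >= 100")
  class(cfg) <- "run_config"
  cfg
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full discovery loop
#'
#' Executes the whole pipeline from one validated configuration:
#' simulate or ingest the data, normalize counts to log2(TPM + 1), derive
#' the discovery (size `signature.k`) and validation (size `validation_k`)
#' signatures of both populations from bulk, Z-score the single cells and
#' score them with the progenitor signature, stratify score tertiles,
#' find genes upregulated in the score-low stratum, filter candidates to
#' surface molecules, and validate the strata with GSEA of both
#' validation signatures (score-low vs score-high cells). All artifacts
#' are written under `out_dir`; an empty candidate list is a reported
#' outcome, not an error. Per-stage seeds derive from the master seed by
#' fixed offsets, so the run is reproducible end to end.
#'
#' @param config a `run_config` from [validate_config()], or anything it
#'   accepts.
#' @return a `run_report` list: derived signatures, result tables, paths,
#'   enrichment results, ground truth (simulation mode), and an md5
#'   fingerprint over all written artifacts.
#' @export
run_discovery <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- simulate_dataset(cfg$simulate)
    bulk <- sim$bulk; sc <- sim$sc; truth <- sim$truth
    ann <- surface_annotation(sim$surface$symbol, sim$surface$is_surface == 1,
                              provenance = "simulated")
  } else {
    bulk <- read_expression(cfg$inputs$bulk, "dense-tsv",
                            scale = cfg$inputs$bulk_scale, role = "bulk")
    sc <- read_expression(cfg$inputs$sc, cfg$inputs$sc_format,
                          scale = cfg$inputs$sc_scale, role = "single-cell")
    ann <- read_surface_annotation(cfg$inputs$surface)
  }
  if (expr_scale(bulk) == "counts") bulk <- normalize_to_log_tpm(bulk)
  if (expr_scale(sc) == "counts") sc <- normalize_to_log_tpm(sc)

  sig_a <- derive_signature(bulk, cfg$pop_a, cfg$pop_b, k = cfg$signature$k,
                            min_mean = cfg$signature$min_mean,
                            species = cfg$species)
  sig_b <- derive_signature(bulk, cfg$pop_b, cfg$pop_a, k = cfg$signature$k,
                            min_mean = cfg$signature$min_mean,
                            species = cfg$species)
  val_a <- derive_signature(bulk, cfg$pop_a, cfg$pop_b, k = cfg$validation_k,
                            min_mean = cfg$signature$min_mean,
                            species = cfg$species)
  val_b <- derive_signature(bulk, cfg$pop_b, cfg$pop_a, k = cfg$validation_k,
                            min_mean = cfg$signature$min_mean,
                            species = cfg$species)

  z <- zscore_by_gene(sc)
  scores <- stratify_tertiles(score_cells(z, sig_a))

  markers_all <- find_markers(sc, scores, n_top = Inf,
                              fc_threshold = cfg$markers$fc_threshold,
                              q_threshold = cfg$markers$q_threshold,
                              order_by = cfg$markers$order_by)
  markers_top <- utils::head(markers_all, cfg$markers$n_top)
  surface_hits <- filter_surface(markers_all, ann)

  low_cells <- scores$cell[scores$stratum == "low"]
  high_cells <- scores$cell[scores$stratum == "high"]
  enr <- list(
    pop_b_in_low = gsea(sc, low_cells, high_cells, val_b,
                        n_perm = cfg$gsea$n_perm, weight_p = cfg$gsea$weight_p,
                        seed = cfg$seed + 1000L),
    pop_a_in_low = gsea(sc, low_cells, high_cells, val_a,
                        n_perm = cfg$gsea$n_perm, weight_p = cfg$gsea$weight_p,
                        seed = cfg$seed + 2000L))

  paths <- list(
    signatures = file.path(cfg$out_dir, "signatures.gmt"),
    scores = file.path(cfg$out_dir, "cell_scores.tsv"),
    markers = file.path(cfg$out_dir, "markers.tsv"),
    surface = file.path(cfg$out_dir, "surface_candidates.tsv"),
    enrichment = file.path(cfg$out_dir, "enrichment.tsv"),
    summary = file.path(cfg$out_dir, "summary.json"))
  write_gmt(list(sig_a, sig_b, val_a, val_b), paths$signatures)
  .write_tsv(scores, paths$scores)
  .write_tsv(as.data.frame(markers_top), paths$markers)
  .write_tsv(as.data.frame(surface_hits), paths$surface)
  enr_df <- do.call(rbind, lapply(names(enr), function(nm) data.frame(
    comparison = nm, set = enr[[nm]]$set_name, es = enr[[nm]]$es,
    nes = enr[[nm]]$nes, p_perm = enr[[nm]]$p_perm,
    n_perm = enr[[nm]]$n_perm, stringsAsFactors = FALSE)))
  .write_tsv(enr_df, paths$enrichment)
  for (nm in names(enr))
    .write_tsv(data.frame(position = seq_along(enr[[nm]]$running_sum),
                          running_sum = enr[[nm]]$running_sum),
               file.path(cfg$out_dir, paste0("running_sum_", nm, ".tsv")))

  artifact_files <- sort(setdiff(list.files(cfg$out_dir, full.names = TRUE),
                                 paths$summary))
  fingerprint <- unname(tools::md5sum(artifact_files))
  summary <- list(
    n_genes = nrow(sc), n_cells = ncol(sc),
    signature_k = cfg$signature$k, validation_k = cfg$validation_k,
    seed = cfg$seed,
    n_markers_at_thresholds = nrow(markers_all),
    n_surface_candidates = nrow(surface_hits),
    top_surface_candidate = if (nrow(surface_hits) > 0)
      surface_hits$symbol[1] else NA,
    no_markers_at_thresholds = nrow(markers_all) == 0,
    enrichment = lapply(enr, function(e)
      list(set = e$set_name, es = e$es, nes = e$nes, p_perm = e$p_perm)),
    fingerprint = paste(fingerprint, collapse = ""))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  structure(list(config = cfg, signatures = list(pop_a = sig_a, pop_b = sig_b,
                                                 val_a = val_a, val_b = val_b),
                 scores = scores, markers = markers_top,
                 markers_all = markers_all, surface_candidates = surface_hits,
                 enrichment = enr, truth = truth, paths = paths,
                 fingerprint = summary$fingerprint),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<run_report> %d marker(s) at thresholds, %d surface candidate(s)%s\n",
    "  downstream-signature GSEA in score-low cells: ES=%.3f, p_perm=%.4g\n"),
    nrow(x$markers_all), nrow(x$surface_candidates),
    if (nrow(x$surface_candidates) > 0)
      paste0("; top: ", x$surface_candidates$symbol[1]) else "",
    x$enrichment$pop_b_in_low$es, x$enrichment$pop_b_in_low$p_perm))
  invisible(x)
}
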
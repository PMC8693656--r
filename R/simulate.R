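#' Simulation parameters
#'
#' Parameters for [simulate_dataset()]. The generator emulates a sorted
#' progenitor gate that is nominally homogeneous but contains a latent
#' lineage-committed subpopulation: committed cells up-regulate a
#' downstream (GMP-like) program, down-regulate the progenitor (CMP-like)
#' program, switch on a handful of lineage-restricted genes that naive
#' cells do not express at all, and up-regulate one surface-molecule gene
#' co-regulated with the downstream program (the actionable marker).
#'
#' Counts are negative-binomial with log-normal per-gene baseline means and
#' log-normal per-cell library-size factors. Bulk replicates of the two
#' reference populations are sequenced deeper and with lower dispersion
#' than single cells, as in real RNA-seq; only the single-cell matrix is
#' zero-inflated, by a logistic dropout in the log of the per-cell mean.
#'
#' @param n_genes total number of genes (default 2000).
#' @param n_cells number of single cells (default 300).
#' @param n_bulk_reps bulk replicates per population (default 3).
#' @param committed_fraction fraction of cells in the latent committed
#'   subpopulation, in `[0, 1]` (default 0.33).
#' @param n_program_genes genes per population program (default 10,
#'   matching the 10-gene signatures the pipeline derives).
#' @param n_lineage_restricted genes expressed only in committed cells
#'   (default 3, the CTSG/MPO/ELANE analogs).
#' @param marker_log2fc committed-vs-naive effect for the planted surface
#'   marker, log2 units (default 2.0).
#' @param program_log2fc effect size for program genes, log2 units
#'   (default 2.0).
#' @param baseline_log_mean,baseline_log_sd natural-log parameters of the
#'   log-normal per-gene baseline mean counts (defaults 1.5, 1.0).
#' @param dispersion single-cell negative-binomial dispersion (default 0.3).
#' @param bulk_dispersion bulk negative-binomial dispersion (default 0.02);
#'   bulk libraries are far less over-dispersed than single cells.
#' @param bulk_depth bulk sequencing depth as a multiple of single-cell
#'   depth (default 100).
#' @param library_size_log_sd natural-log sd of per-cell depth factors
#'   (default 0.3).
#' @param dropout_midpoint,dropout_slope logistic dropout parameters: a
#'   gene-cell entry with pre-dropout mean mu is zeroed with probability
#'   `plogis(-slope * (log(mu) - midpoint))` (defaults 0, 1).
#' @param n_decoy_surface unplanted genes flagged as surface molecules in
#'   the emitted annotation, so the surface filter has a realistic null
#'   universe (default 50, reduced automatically when few genes are free).
#' @param seed random seed driving every draw (default 1).
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_genes = 2000, n_cells = 300, n_bulk_reps = 3,
                       committed_fraction = 0.33,
                       n_program_genes = 10, n_lineage_restricted = 3,
                       marker_log2fc = 2.0, program_log2fc = 2.0,
                       baseline_log_mean = 1.5, baseline_log_sd = 1.0,
                       dispersion = 0.3, bulk_dispersion = 0.02,
                       bulk_depth = 100, library_size_log_sd = 0.3,
                       dropout_midpoint = 0, dropout_slope = 1,
                       n_decoy_surface = NULL, seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
            n_bulk_reps = as.integer(n_bulk_reps),
            committed_fraction = committed_fraction,
            n_program_genes = as.integer(n_program_genes),
            n_lineage_restricted = as.integer(n_lineage_restricted),
            marker_log2fc = marker_log2fc, program_log2fc = program_log2fc,
            baseline_log_mean = baseline_log_mean,
            baseline_log_sd = baseline_log_sd,
            dispersion = dispersion, bulk_dispersion = bulk_dispersion,
            bulk_depth = bulk_depth,
            library_size_log_sd = library_size_log_sd,
            dropout_midpoint = dropout_midpoint,
            dropout_slope = dropout_slope,
            n_decoy_surface = NA_integer_,
            seed = as.integer(seed))
  free <- p$n_genes - 2L * p$n_program_genes - p$n_lineage_restricted - 1L
  p$n_decoy_surface <- as.integer(n_decoy_surface %||% min(50L, free))
  if (p$n_program_genes * 2L + p$n_lineage_restricted + 1L > p$n_genes)
    pm_config_error(
      "sim_params: n_program_genes*2 + n_lineage_restricted + 1 must be <= n_genes")
  if (p$committed_fraction < 0 || p$committed_fraction > 1)
    pm_config_error("sim_params: committed_fraction must lie in [0, 1]")
  if (p$dispersion <= 0)
    pm_config_error("sim_params: dispersion must be > 0")
  if (p$bulk_dispersion <= 0)
    pm_config_error("sim_params: bulk_dispersion must be > 0")
  if (p$n_cells < 1 || p$n_bulk_reps < 1)
    pm_config_error("sim_params: n_cells and n_bulk_reps must be >= 1")
  if (p$n_decoy_surface < 0 ||
      p$n_decoy_surface > p$n_genes - 2L * p$n_program_genes -
        p$n_lineage_restricted - 1L)
    pm_config_error("sim_params: n_decoy_surface exceeds available genes")
  class(p) <- "sim_params"
  p
}

# Fixed baseline mean counts of the planted gene classes (single-cell
# scale). These are generator constants, not dials: the progenitor program
# and the marker are well-expressed genes, the downstream program is
# moderate, and lineage-restricted genes are essentially off in naive
# cells (0.05 expected counts) and switch on in committed cells.
.PLANT_MU <- c(cmp = 20, gmp = 8, marker = 40, lineage_off = 0.05)
# Extra log2 shift for lineage-restricted genes on top of program_log2fc:
# "restricted" expression means an on/off contrast, not a 4-fold one.
.LINEAGE_EXTRA_LOG2FC <- 6

#' Simulate a progenitor-gate dataset with a latent committed subpopulation
#'
#' Generates (i) bulk count replicates of two reference populations, POP_A
#' (naive, CMP-like) and POP_B (downstream, GMP-like), in which only the
#' two planted programs are differential; (ii) a single-cell count matrix
#' of the POP_A-like gate in which `round(committed_fraction * n_cells)`
#' latent committed cells carry the planted shifts; (iii) a ground-truth
#' record of everything planted; and (iv) a surface-molecule annotation
#' covering all genes, flagging the planted marker plus decoy surface
#' genes. The marker and the lineage-restricted genes are deliberately not
#' differential between the bulk populations: they are discoverable only
#' through single-cell heterogeneity, which is the analysis this generator
#' exists to exercise.
#'
#' Identical parameters (including the seed) give bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @return a list of class `pm_simulation` with elements `bulk` and `sc`
#'   (count-scale [expression_matrix()] objects), `truth` (list:
#'   `committed_cell_ids`, `cmp_program_genes`, `gmp_program_genes`,
#'   `lineage_restricted_genes`, `planted_marker`, `effect_table`), and
#'   `surface` (data.frame `symbol`, `is_surface`).
#' @export
simulate_dataset <- function(params = sim_params()) {
  if (!inherits(params, "sim_params"))
    pm_config_error("simulate_dataset: `params` must come from sim_params()")
  p <- params
  with_seed(p$seed, {
    genes <- sprintf("Gene%04d", seq_len(p$n_genes))
    cells <- sprintf("cell%04d", seq_len(p$n_cells))

    base_mu <- exp(rnorm(p$n_genes, p$baseline_log_mean, p$baseline_log_sd))
    names(base_mu) <- genes

    n_plant <- 2L * p$n_program_genes + p$n_lineage_restricted + 1L
    planted_idx <- sample.int(p$n_genes, n_plant)
    cmp_genes <- genes[planted_idx[seq_len(p$n_program_genes)]]
    gmp_genes <- genes[planted_idx[p$n_program_genes + seq_len(p$n_program_genes)]]
    lin_genes <- if (p$n_lineage_restricted > 0)
      genes[planted_idx[2L * p$n_program_genes + seq_len(p$n_lineage_restricted)]]
    else character(0)
    marker <- genes[planted_idx[n_plant]]

    base_mu[cmp_genes] <- .PLANT_MU[["cmp"]]
    base_mu[gmp_genes] <- .PLANT_MU[["gmp"]]
    base_mu[lin_genes] <- .PLANT_MU[["lineage_off"]]
    base_mu[marker] <- .PLANT_MU[["marker"]]

    decoys <- sample(setdiff(genes, genes[planted_idx]), p$n_decoy_surface)
    surface <- data.frame(symbol = genes,
                          is_surface = as.integer(genes %in% c(marker, decoys)),
                          stringsAsFactors = FALSE)

    n_committed <- round(p$committed_fraction * p$n_cells)
    committed <- sort(sample(cells, n_committed))

    lineage_fc <- p$program_log2fc + .LINEAGE_EXTRA_LOG2FC
    effect_table <- data.frame(
      gene = c(cmp_genes, gmp_genes, lin_genes, marker),
      log2fc = c(rep(-p$program_log2fc, length(cmp_genes)),
                 rep(p$program_log2fc, length(gmp_genes)),
                 rep(lineage_fc, length(lin_genes)),
                 p$marker_log2fc),
      stringsAsFactors = FALSE)

    # --- bulk: symmetric program shifts only, deeper and tighter libraries
    bulk_fc <- setNames(numeric(p$n_genes), genes)
    bulk_fc[cmp_genes] <- p$program_log2fc
    bulk_fc[gmp_genes] <- -p$program_log2fc
    mu_a <- base_mu * 2^(bulk_fc / 2) * p$bulk_depth
    mu_b <- base_mu * 2^(-bulk_fc / 2) * p$bulk_depth
    bulk_mu <- cbind(matrix(mu_a, p$n_genes, p$n_bulk_reps),
                     matrix(mu_b, p$n_genes, p$n_bulk_reps))
    bulk <- matrix(rnbinom(length(bulk_mu), mu = as.vector(bulk_mu),
                           size = 1 / p$bulk_dispersion),
                   p$n_genes, 2L * p$n_bulk_reps)
    dimnames(bulk) <- list(genes, c(
      sprintf("POP_A_rep%d", seq_len(p$n_bulk_reps)),
      sprintf("POP_B_rep%d", seq_len(p$n_bulk_reps))))

    # --- single cells: committed cells carry the effect-table shifts
    sc_fc <- matrix(0, p$n_genes, p$n_cells, dimnames = list(genes, cells))
    if (n_committed > 0)
      sc_fc[effect_table$gene, committed] <- effect_table$log2fc
    lib <- exp(rnorm(p$n_cells, 0, p$library_size_log_sd))
    sc_mu <- base_mu * 2^sc_fc
    sc_mu <- sweep(sc_mu, 2, lib, "*")
    sc <- matrix(rnbinom(length(sc_mu), mu = as.vector(sc_mu),
                         size = 1 / p$dispersion),
                 p$n_genes, p$n_cells, dimnames = dimnames(sc_mu))
    p_drop <- plogis(-p$dropout_slope * (log(sc_mu) - p$dropout_midpoint))
    sc[matrix(runif(length(sc)), p$n_genes) < p_drop] <- 0L

    truth <- list(committed_cell_ids = committed,
                  cmp_program_genes = cmp_genes,
                  gmp_program_genes = gmp_genes,
                  lineage_restricted_genes = lin_genes,
                  planted_marker = marker,
                  effect_table = effect_table)
    structure(list(
      bulk = expression_matrix(bulk, scale = "counts", role = "bulk"),
      sc = expression_matrix(sc, scale = "counts", role = "single-cell"),
      truth = truth,
      surface = surface),
      class = "pm_simulation")
  })
}

#' @export
print.pm_simulation <- function(x, ...) {
  cat(sprintf(
    "<pm_simulation> bulk %dx%d, sc %dx%d, %d committed cells, marker %s\n",
    nrow(x$bulk), ncol(x$bulk), nrow(x$sc), ncol(x$sc),
    length(x$truth$committed_cell_ids), x$truth$planted_marker))
  invisible(x)
}
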
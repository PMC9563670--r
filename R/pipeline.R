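#' Read a detection dataset from tab-delimited files
#'
#' Expects a probes-by-samples expression matrix and a detection-call matrix
#' of identical shape (probe ids in the first column, sample ids as header),
#' a two-column probe-to-gene map, and a sample metadata table with at least
#' `sample_id` and `condition` columns.
#'
#' @param expr_file,calls_file,probe_map_file,samples_file File paths.
#' @param ... Passed to [detection_dataset()].
#' @return A [detection_dataset()].
#' @export
read_detection_dataset <- function(expr_file, calls_file, probe_map_file,
                                   samples_file, ...) {
  read_mat <- function(path, numeric = TRUE) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    if (numeric) storage.mode(m) <- "double"
    m
  }
  detection_dataset(
    expr = read_mat(expr_file),
    calls = read_mat(calls_file, numeric = FALSE),
    probe_map = utils::read.delim(probe_map_file, stringsAsFactors = FALSE),
    samples = utils::read.delim(samples_file, stringsAsFactors = FALSE),
    ...
  )
}

#' Configuration of a pipeline run
#'
#' Collects inputs and thresholds for [run_pipeline()]. Inputs may be given
#' either as file paths (`kgml_files` plus the four dataset files) or as
#' in-memory objects (`graphs`, `dataset`).
#'
#' @param kgml_files Character vector of KGML file paths (or XML strings).
#' @param graphs List of [pathway_graph()] objects (alternative to
#'   `kgml_files`).
#' @param expr_file,calls_file,probe_map_file,samples_file Dataset file paths.
#' @param dataset A [detection_dataset()] (alternative to the files).
#' @param paired Paired or unpaired cohort.
#' @param p_threshold Per-gene DE threshold.
#' @param alpha Subpathway significance threshold.
#' @param n_permutations Permutations for the empirical null.
#' @param seed Integer seed for all randomness in the run.
#' @param max_path_length,max_paths_per_pathway,binding_subset_cap,start_policy
#'   Enumeration settings, see [enumeration_config()].
#' @param out_dir Optional directory for TSV reports and the JSON manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(kgml_files = NULL, graphs = NULL,
                       expr_file = NULL, calls_file = NULL,
                       probe_map_file = NULL, samples_file = NULL,
                       dataset = NULL, paired = TRUE,
                       p_threshold = 0.05, alpha = 0.05,
                       n_permutations = 10L, seed = 1L,
                       max_path_length = 30L,
                       max_paths_per_pathway = 50000L,
                       binding_subset_cap = 81L,
                       start_policy = "entry_only",
                       out_dir = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1, alpha > 0, alpha < 1)
  if (is.null(graphs) && is.null(kgml_files)) {
    stop("supply kgml_files or graphs", call. = FALSE)
  }
  if (is.null(dataset) &&
      (is.null(expr_file) || is.null(calls_file) ||
       is.null(probe_map_file) || is.null(samples_file))) {
    stop("supply dataset or all four dataset files", call. = FALSE)
  }
  structure(
    list(kgml_files = kgml_files, graphs = graphs,
         expr_file = expr_file, calls_file = calls_file,
         probe_map_file = probe_map_file, samples_file = samples_file,
         dataset = dataset, paired = paired, p_threshold = p_threshold,
         alpha = alpha, n_permutations = as.integer(n_permutations),
         seed = as.integer(seed),
         enumeration = enumeration_config(max_path_length,
                                          max_paths_per_pathway,
                                          binding_subset_cap, start_policy),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full subpathway analysis workflow
#'
#' Executes the stages in order: load pathways, per-gene differential
#' expression, pathway enrichment, subpathway enumeration, impact scoring with
#' the permutation null, and FDR adjustment. All randomness flows from the
#' config seed, so two runs with the same config produce identical tables.
#'
#' @param config A [run_config()].
#' @return List with `gene_stats`, `enrichment`, `scores` (per-subpathway
#'   table with impact factor, empirical p and q), `graphs`, and `manifest`
#'   (inputs, seed, thresholds). When `out_dir` is set, the tables are also
#'   written as TSV (plus a JSON manifest when jsonlite is installed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  graphs <- config$graphs
  if (is.null(graphs)) graphs <- lapply(config$kgml_files, parse_kgml)
  ds <- config$dataset
  if (is.null(ds)) {
    ds <- read_detection_dataset(config$expr_file, config$calls_file,
                                 config$probe_map_file, config$samples_file)
  }

  stats <- gene_stats(ds, paired = config$paired,
                      p_threshold = config$p_threshold)
  de <- stats$gene[stats$is_de]
  universe <- intersect(stats$gene,
                        unique(unlist(lapply(graphs, pathway_genes))))
  enrichment <- enrich_pathways(intersect(de, universe), graphs,
                                universe = universe)
  scores <- subpathway_impact(ds, graphs, paired = config$paired,
                              n_permutations = config$n_permutations,
                              seed = config$seed,
                              config = config$enumeration,
                              p_threshold = config$p_threshold)

  manifest <- list(
    paired = config$paired, p_threshold = config$p_threshold,
    alpha = config$alpha, n_permutations = config$n_permutations,
    seed = config$seed, n_pathways = length(graphs),
    n_genes = nrow(stats), n_subpathways = nrow(scores),
    inputs = list(kgml_files = config$kgml_files,
                  expr_file = config$expr_file,
                  samples_file = config$samples_file)
  )
  result <- list(gene_stats = stats, enrichment = enrichment,
                 scores = scores, graphs = graphs, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) {
      utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(stats, "gene_stats.tsv")
    wt(enrichment, "enrichment.tsv")
    wt(scores, "subpathway_scores.tsv")
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, null = "null")
    }
  }
  result
}

#' Combine two cohort runs into overlap reports
#'
#' Given the result bundles (or configs) of two cohorts analyzed over the
#' same pathway set, reports the overlapping differentially expressed genes
#' (with the hypergeometric overlap test) and the overlapping significant
#' upregulated subpathways with their FDR.
#'
#' @param a,b [run_pipeline()] results, or [run_config()] objects to run.
#' @param alpha Per-cohort subpathway significance threshold.
#' @return List with `genes` (up/down overlap counts and hypergeometric
#'   p-values with BH FDR) and the `subpathways`/`summary` tables of
#'   [overlap_subpathways()].
#' @export
run_overlap <- function(a, b, alpha = 0.05) {
  if (inherits(a, "run_config")) a <- run_pipeline(a)
  if (inherits(b, "run_config")) b <- run_pipeline(b)
  universe <- intersect(a$gene_stats$gene, b$gene_stats$gene)
  if (!setequal(vapply(a$graphs, `[[`, character(1), "pathway_id"),
                vapply(b$graphs, `[[`, character(1), "pathway_id"))) {
    stop("cohorts analyzed different pathway sets", call. = FALSE)
  }

  gene_overlap <- function(direction) {
    pick <- function(st) st$gene[st$is_de & st$direction == direction]
    ga <- pick(a$gene_stats); gb <- pick(b$gene_stats)
    ov <- overlap_test(ga, gb, length(universe))
    data.frame(direction = direction, n_a = length(ga), n_b = length(gb),
               overlap = ov$overlap, p_value = ov$p_value,
               stringsAsFactors = FALSE)
  }
  genes <- rbind(gene_overlap("up"), gene_overlap("down"))
  genes$fdr <- fdr_adjust(genes$p_value)

  sub <- overlap_subpathways(a$scores, b$scores, alpha = alpha)
  c(list(genes = genes), sub)
}
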
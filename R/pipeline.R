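# End-to-end orchestration: coarse filter -> {CPE, MIxy, MIp} -> Joint
# N-Best per method -> merged call set -> helix extension -> purity ->
# neighbor effects -> evaluation. Every stage is a pure function of its
# inputs and the configuration, so reruns are bitwise identical.

#' Default pipeline configuration
#'
#' All thresholds of the analysis with their study defaults: coarse-filter
#' entropy tolerance 0.2 bits and MI rank cutoff 100; Joint N-Best ratio
#' threshold 0.5; minimum total events 10; helix-extension canonical
#' fraction 0.85; neighbor-effect ratio 0.85, CPE cutoff 0.25, event
#' minimum 10; MIp Z-score cutoff 4 (a configurable stand-in — the
#' originating analysis names no value).
#'
#' @param ... Named overrides of individual keys.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(entropy_tol = 0.2, top_k = 100, nbest_threshold = 0.5,
              min_total_events = 10, canonical_fraction = 0.85,
              neighbor_ratio_min = 0.85, cpe_min = 0.25, events_min = 10,
              mip_z_cutoff = 4)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, a YAML subset) key-value file; keys as in
#' [default_config()], which supplies any missing value.
#'
#' @param path Config file path.
#' @return Named configuration list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Run the full covariation pipeline
#'
#' Executes the whole analysis on an alignment and phylogeny: coarse
#' filtering, the event-counting scan (CPE), MIxy and MIp scoring, Joint
#' N-Best calling per method, the merged MI call set and the PEC/MI union,
#' helix extension from the union, purity scores for all retained pairs,
#' neighbor-effect identification, and — when a reference structure and
#' reference sequence are supplied — evaluation against the structure.
#' When a simulation truth table is supplied, planted-pair precision and
#' recall are reported per method.
#'
#' @param alignment An `rna_alignment`.
#' @param phylogeny A `pec_phylogeny` over the alignment's sequences.
#' @param structure Optional `reference_structure`.
#' @param truth Optional truth table (data frame with `col_i`, `col_j`,
#'   `role`; rows with role `"planted"` are the expected calls).
#' @param config Configuration list from [default_config()] /
#'   [read_config()].
#' @param output_dir Optional directory; when given, all intermediates are
#'   written as TSV plus a JSON run manifest.
#' @return A list with elements `candidates`, `pec`, `jn_pec`, `jn_mixy`,
#'   `jn_mip`, `calls_pec`, `calls_mi`, `calls_all`, `helix`, `purity`,
#'   `neighbors`, `evaluation` (or `NULL`), `truth_metrics` (or `NULL`),
#'   `config`.
#' @export
run_pipeline <- function(alignment, phylogeny, structure = NULL,
                         truth = NULL, config = default_config(),
                         output_dir = NULL) {
  pm <- if (!is.null(structure)) {
    build_position_map(alignment, structure$reference_sequence_id)
  } else NULL

  candidates <- coarse_filter(alignment, entropy_tol = config$entropy_tol,
                              top_k = config$top_k)
  if (nrow(candidates) == 0L) stop("coarse filter retained no pairs")

  pec <- pec_scan(alignment, phylogeny, candidates[c("col_i", "col_j")],
                  min_total_events = config$min_total_events)
  sm_cpe <- cpe_scores(pec)
  sm_mixy <- score_matrix(candidates, method = "MIxy", score = "mixy")
  mip_df <- mip(sm_mixy, z = FALSE)
  sm_mip <- score_matrix(mip_df, method = "MIp", score = "mip")

  jn_pec <- joint_nbest(sm_cpe, threshold = config$nbest_threshold)
  jn_mixy <- joint_nbest(sm_mixy, threshold = config$nbest_threshold)
  jn_mip <- joint_nbest(sm_mip, threshold = config$nbest_threshold)

  calls_pec <- nbest_calls(jn_pec)
  calls_mi <- merge_calls(nbest_calls(jn_mixy), nbest_calls(jn_mip),
                          labels = c("mixy", "mip"))
  calls_all <- merge_calls(calls_pec, calls_mi, labels = c("pec", "mi"))

  helix <- helix_extend(alignment, calls_all[c("col_i", "col_j")],
                        canonical_fraction = config$canonical_fraction)
  scored_pairs <- rbind(calls_all[c("col_i", "col_j")],
                        helix$extended[c("col_i", "col_j")])
  purity_tab <- do.call(rbind, lapply(seq_len(nrow(scored_pairs)), function(r) {
    p <- purity(pair_state_table(alignment, scored_pairs$col_i[r],
                                 scored_pairs$col_j[r]))
    data.frame(col_i = scored_pairs$col_i[r], col_j = scored_pairs$col_j[r],
               purity = p$purity, gu_plus_purity = p$gu_plus_purity)
  }))

  neighbors <- neighbor_effects(pec, called_pairs = calls_all,
                                structure = structure, position_map = pm,
                                ratio_min = config$neighbor_ratio_min,
                                cpe_min = config$cpe_min,
                                events_min = config$events_min)

  evaluation <- if (!is.null(structure)) {
    evaluate_calls(rbind(
      data.frame(col_i = calls_all$col_i, col_j = calls_all$col_j,
                 score = NA_real_),
      data.frame(col_i = helix$extended$col_i, col_j = helix$extended$col_j,
                 score = NA_real_)), pm, structure)
  } else NULL

  truth_metrics <- if (!is.null(truth)) {
    planted <- truth[truth$role == "planted", , drop = FALSE]
    list(pec = precision_recall(calls_pec, planted),
         mi = precision_recall(calls_mi, planted),
         union = precision_recall(calls_all, planted))
  } else NULL

  result <- list(candidates = candidates, pec = pec, jn_pec = jn_pec,
                 jn_mixy = jn_mixy, jn_mip = jn_mip, calls_pec = calls_pec,
                 calls_mi = calls_mi, calls_all = calls_all, helix = helix,
                 purity = purity_tab, neighbors = neighbors,
                 evaluation = evaluation, truth_metrics = truth_metrics,
                 config = config)
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir, pm)
  result
}

#' Precision and recall of a call set against expected pairs
#'
#' @param calls,expected Data frames with `col_i`, `col_j`.
#' @return List with `precision`, `recall`, `n_calls`, `n_expected`,
#'   `n_hit`.
#' @export
precision_recall <- function(calls, expected) {
  key <- function(d) paste(pmin(d$col_i, d$col_j), pmax(d$col_i, d$col_j))
  hit <- key(calls) %in% key(expected)
  list(precision = if (nrow(calls)) mean(hit) else NA_real_,
       recall = if (nrow(expected)) sum(hit) / nrow(expected) else NA_real_,
       n_calls = nrow(calls), n_expected = nrow(expected),
       n_hit = sum(hit))
}

write_pipeline_outputs <- function(result, dir, position_map = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(result$candidates, "candidates.tsv")
  wt(as.data.frame(result$pec), "pec_events.tsv")
  wt(result$jn_pec, "jnbest_cpe.tsv")
  wt(result$jn_mixy, "jnbest_mixy.tsv")
  wt(result$jn_mip, "jnbest_mip.tsv")
  wt(result$calls_all, "calls.tsv")
  wt(result$helix$extended, "helix_extended.tsv")
  wt(result$purity, "purity.tsv")
  wt(result$neighbors, "neighbors.tsv")
  if (!is.null(result$evaluation)) {
    wt(result$evaluation$per_call, "evaluation_calls.tsv")
    wt(result$evaluation$topn, "precision_topn.tsv")
  }
  manifest <- list(
    package = "rnacov",
    version = as.character(utils::packageVersion("rnacov")),
    config = result$config,
    n_candidates = nrow(result$candidates),
    n_calls = nrow(result$calls_all))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
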
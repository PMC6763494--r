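# One-shot analysis pipeline: run every stage on a suite + choice table and
# write the TSV/JSON artifacts to an output directory.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline and write a report
#'
#' Executes, in order: index breakdowns (raw and translocation-adjusted),
#' index/choice correlations for every index variant, pixel-wise salience
#' maps for both sides, salient-cluster extraction, the replication and
#' part-repeat analyses, across-team concordance and inter-individual
#' correlations. Results are written as TSV/JSON files under `out_dir` and
#' returned as a summary list (also serialized to `summary.json`).
#'
#' @param cases List of `test_case`s.
#' @param choices Choice-record data frame covering the cases.
#' @param pair Governing `training_pair`.
#' @param out_dir Output directory (created if absent). `NULL` skips all
#'   file output.
#' @param r_threshold Cluster salience threshold.
#' @param seed Seed for the feature-pair control sampling.
#' @return The summary list, invisibly when writing files.
#' @export
analysis_report <- function(cases, choices, pair = training_pair("A"),
                            out_dir = NULL, r_threshold = 0.30, seed = 1L) {
  check_cases(cases)
  check_choices(choices)
  scores <- test_scores(choices)
  idx <- index_table(cases, pair)
  idx_adj <- index_table(cases, pair, adjust_translocation = TRUE)

  variants <- c("richness", "base", "base_adjusted", "minus_inhib",
                "plus_zh", "plus_n", "select")
  corrs <- lapply(variants, function(v) {
    cc <- index_choice_correlation(cases, scores, variant = v, pair = pair)
    data.frame(variant = v, r = cc$r, p = cc$p, n = cc$n)
  })
  corrs <- do.call(rbind, corrs)

  maps <- list(Z = pixelwise_correlation(cases, scores, side = "Z"),
               H = pixelwise_correlation(cases, scores, side = "H"))
  clusters <- list(Z = salient_clusters(maps$Z, r_threshold),
                   H = salient_clusters(maps$H, r_threshold))
  repl <- replication_table(cases, scores)
  part <- part_repeat_table(cases, scores)
  conc <- team_concordance(choices)
  inter <- interindividual_correlations(choices)

  summary <- list(
    n_tests = length(cases),
    n_pigeons = length(unique(choices$pigeon_id)),
    mean_percent_correct = mean(scores$score),
    index_correlations = corrs,
    clusters = list(
      Z = lapply(clusters$Z$clusters, as.character),
      H = lapply(clusters$H$clusters, as.character)),
    replication = list(n_repeats = repl$n_repeats,
                       mean_difference = repl$mean_difference,
                       r_difference_vs_gap = repl$r),
    part_repeats = list(n = nrow(part), n_flips = sum(part$flip)),
    concordance = list(k = conc$k, n = conc$n, p = conc$p),
    interindividual = list(mean_all = inter$mean_all,
                           mean_within_team =
                             as.list(inter$mean_within_team),
                           mean_between_team = inter$mean_between_team))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(idx, file.path(out_dir, "index.tsv"))
    write_tsv(idx_adj, file.path(out_dir, "index_adjusted.tsv"))
    write_tsv(corrs, file.path(out_dir, "index_correlations.tsv"))
    write_tsv(as.data.frame(maps$Z), file.path(out_dir, "pixelmap_Z.tsv"))
    write_tsv(as.data.frame(maps$H), file.path(out_dir, "pixelmap_H.tsv"))
    write_clusters(clusters$Z, file.path(out_dir, "clusters_Z.json"))
    write_clusters(clusters$H, file.path(out_dir, "clusters_H.json"))
    if (repl$n_repeats > 0L)
      write_tsv(repl$rows, file.path(out_dir, "replication.tsv"))
    if (nrow(part) > 0L)
      write_tsv(part, file.path(out_dir, "part_repeats.tsv"))
    write_tsv(conc$table, file.path(out_dir, "concordance.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(summary))
  }
  summary
}
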
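# End-to-end orchestration: enumerate candidate sites, evaluate pose
# ensembles per docking window, rank sites by S1 occupancy, and map the top
# proximal+distal site pair to fragments.

#' Run the full cleavage-site prediction pipeline
#'
#' Chains the pipeline stages over one substrate region: candidate
#' enumeration under the specificity rules, per-window pose evaluation
#' against the selection criteria, ensemble summaries with RMSD group
#' contrast, occupancy-based site ranking, and a fragment map pairing the
#' proximal site with the top-ranked distal site. Pose sources are supplied
#' per window as `pose_set` objects or file paths to multi-model PDB files
#' (named by window label, with a `residue_offset` attribute when read from
#' file numbering).
#'
#' @param receptor a `protease_receptor`.
#' @param substrate a `substrate_sequence`.
#' @param region length-2 author-number interval to scan for candidates.
#' @param pose_sources named list: window label -> `pose_set` or file path.
#' @param criteria a `selection_criteria`.
#' @param rules a `specificity_rules`.
#' @param proximal_site author position of the proximal (furin-region)
#'   cleavage site used for the fragment map; `NULL` skips fragment mapping.
#' @param tract_span,key_span passed to [tract_release_check()];
#'   `tract_span = NULL` derives the tract as (proximal_site, top distal site].
#' @param test RMSD group-comparison method, see [summarize_ensemble()].
#' @param outdir optional directory; when given, TSV/JSON reports are written.
#' @return an object of class `cleavage_report`: list with `candidates`,
#'   `summaries`, `ranking`, `fragments`, `tract`, `config_echo`.
#' @export
run_full_pipeline <- function(receptor, substrate, region, pose_sources,
                              criteria = selection_criteria(),
                              rules = specificity_rules(),
                              proximal_site = NULL, tract_span = NULL,
                              key_span = NULL, test = "mann_whitney",
                              outdir = NULL) {
  validate_receptor(receptor)
  if (region[2] < region[1]) {
    warning("empty region; returning empty report")
    empty <- suppressWarnings(
      enumerate_candidates(substrate, rep(substrate$start_number, 2L), rules))
    empty <- empty[0, , drop = FALSE]
    empty_rank <- data.frame(rank = integer(), p1_position = integer(),
                             p1_residue = character(), occupancy = integer(),
                             n_total = integer(), peptide_label = character(),
                             excluded = logical(), exclusion_reason = character(),
                             stringsAsFactors = FALSE)
    return(structure(list(candidates = empty, summaries = list(),
                          ranking = empty_rank, fragments = NULL, tract = NULL,
                          config_echo = list(region = region)),
                     class = "cleavage_report"))
  }
  candidates <- enumerate_candidates(substrate, region, rules)
  summaries <- list()
  for (label in names(pose_sources)) {
    src <- pose_sources[[label]]
    if (is.character(src)) {
      if (!file.exists(src))
        stop("pose file for window '", label, "' not found: ", src)
      offset <- attr(src, "residue_offset")
      src <- read_pose_ensemble(src, label,
                                residue_offset = if (is.null(offset)) 0L else offset)
    }
    stopifnot(inherits(src, "pose_set"))
    evals <- evaluate_pose_set(src, receptor, criteria, rules)
    summaries[[label]] <- summarize_ensemble(evals, src, test = test)
  }
  ranking <- site_ranking(summaries, rules, candidates)
  fragments <- NULL
  tract <- NULL
  if (!is.null(proximal_site) && nrow(ranking) > 0L) {
    distal <- ranking$p1_position[ranking$p1_position > proximal_site &
                                    !ranking$excluded]
    if (length(distal) > 0L) {
      top_distal <- distal[1]
      events <- sort(c(proximal_site, top_distal))
      fragments <- fragment_map(substrate, events)
      ts <- if (is.null(tract_span)) c(proximal_site + 1L, top_distal) else tract_span
      tract <- c(tract_release_check(events, ts, key_span),
                 list(tract_span = ts, events = events))
    }
  }
  report <- structure(list(candidates = candidates, summaries = summaries,
                           ranking = ranking, fragments = fragments,
                           tract = tract,
                           config_echo = list(region = region,
                                              criteria = unclass(criteria),
                                              rules = unclass(rules),
                                              proximal_site = proximal_site,
                                              windows = names(pose_sources))),
                      class = "cleavage_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write a cleavage report bundle to a directory
#'
#' Emits `candidates.tsv`, `occupancy.tsv`, `ranking.tsv`, per-window
#' `summary_<window>.json`, `fragments.tsv` (when present) and
#' `report.json`. Output is deterministic given the report (no timestamps).
#'
#' @param report a `cleavage_report`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_candidates_tsv(report$candidates, file.path(dir, "candidates.tsv"))
  occ <- do.call(rbind, lapply(report$summaries, function(s) {
    if (length(s$occupancy_counts) == 0L) return(NULL)
    data.frame(peptide = s$peptide_label,
               p1_position = as.integer(names(s$occupancy_counts)),
               selected_modes = as.integer(s$occupancy_counts),
               n_total = s$n_total,
               pass_fraction_percent = round(s$pass_fraction_percent, 1),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(occ))
    utils::write.table(occ, file.path(dir, "occupancy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(report$ranking, file.path(dir, "ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in report$summaries)
    write_summary_json(s, file.path(dir, paste0("summary_", s$peptide_label, ".json")))
  if (!is.null(report$fragments))
    write_fragments_tsv(report$fragments, file.path(dir, "fragments.tsv"))
  main <- list(
    ranking = report$ranking,
    pass_fractions = lapply(report$summaries, function(s) s$pass_fraction_percent),
    tract = report$tract, config = report$config_echo)
  jsonlite::write_json(main, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  invisible(dir)
}

#' @export
print.cleavage_report <- function(x, ...) {
  cat("Cleavage-site prediction report\n")
  cat("  candidates in region ", x$config_echo$region[1], "-",
      x$config_echo$region[2], ": ", nrow(x$candidates),
      " (", sum(x$candidates$excluded), " excluded by P2 rule)\n", sep = "")
  for (s in x$summaries)
    cat(sprintf("  %s: %.1f%% of %d modes selected\n",
                s$peptide_label, s$pass_fraction_percent, s$n_total))
  if (nrow(x$ranking) > 0L) {
    cat("  site ranking (by S1 occupancy):\n")
    print.data.frame(utils::head(x$ranking, 10), row.names = FALSE)
  }
  if (!is.null(x$tract))
    cat("  inhibitory tract ", x$tract$tract_span[1], "-", x$tract$tract_span[2],
        ": ", x$tract$status, "\n", sep = "")
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Convenience loader for scripted runs: returns the YAML as a list after
#' checking the seed is present, so a run is fully reproducible from its
#' config file.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run config must declare a seed")
  cfg
}
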
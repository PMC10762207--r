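# End-to-end orchestration: simulate -> assign -> build -> cascade
# statistics -> similarity -> gradient trends, with a written manifest.
# The numbered scripts under analysis/ are thin drivers over this module.

#' Run the degradation-cascade pipeline on a synthetic study
#'
#' Executes the enabled stages in order and writes each stage's table under
#' `out_dir`, plus a manifest listing every artifact. Deterministic for a
#' fixed config (one master seed drives simulation, similarity and
#' selection stages).
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output and returns results only.
#' @param stages Character vector of stages to run, subset of
#'   c("simulate", "assign", "universal", "classes", "wmass", "similarity",
#'   "trends"). The assign stage round-trips one sample through peak-list
#'   emulation and formula assignment as a fidelity check.
#' @param assignment An [assignment_config()].
#' @param similarity_depth,similarity_iterations Rarefied-similarity
#'   settings; the reference pool is the dataset-wide universal set.
#' @return List with the stage results and the manifest data frame.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         stages = c("simulate", "universal", "classes",
                                    "wmass", "similarity", "trends"),
                         assignment = assignment_config(),
                         similarity_depth = 1500,
                         similarity_iterations = 200) {
  t0 <- Sys.time()
  res <- list()
  manifest <- list()
  note <- function(stage, artifact, n) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, artifact = artifact, rows = n,
      seed = config$seed, stringsAsFactors = FALSE)
  }
  emit <- function(stage, obj, file) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(obj, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    note(stage, file, nrow(obj))
  }

  sim <- simulate_dataset(config)
  res$dataset <- sim$dataset
  res$truth <- sim$truth
  note("simulate", "dataset", nrow(sim$dataset$intensity))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(sim$dataset, file.path(out_dir, "intensities.tsv"),
                  file.path(out_dir, "metadata.tsv"))
    note("simulate", "intensities.tsv", sum(sim$dataset$intensity > 0))
  }

  if ("assign" %in% stages) {
    s1 <- colnames(sim$dataset$intensity)[1]
    tab <- data.frame(formula = rownames(sim$dataset$intensity),
                      intensity = sim$dataset$intensity[, s1])
    tab <- tab[tab$intensity > 0, ]
    pk <- simulate_peaklist(tab, config)
    asg <- assign_peaklist(pk, assignment)
    recovered <- mean(tab$formula %in% asg$table$formula)
    res$assignment <- list(sample_id = s1, table = asg$table, log = asg$log,
                           recovery = recovered)
    emit("assign", asg$log, "assignment_log.tsv")
  }

  pool <- universal_set(res$dataset)
  res$pool <- pool
  if ("universal" %in% stages) {
    uf <- universal_fractions(res$dataset, pool)
    res$universal <- merge(uf, res$dataset$samples, by = "sample_id")
    emit("universal", res$universal, "universal_fractions.tsv")
  }
  if ("classes" %in% stages) {
    res$pool_classes <- pool_class_composition(res$dataset, pool$formulas)
    res$class_profiles <- rbind(
      class_profile(res$dataset, "count", "all"),
      class_profile(res$dataset, "intensity", "all"),
      class_profile(res$dataset, "intensity", "non-universal", pool = pool))
    emit("classes", res$pool_classes, "universal_pool_classes.tsv")
    emit("classes", res$class_profiles, "class_profiles.tsv")
  }
  if ("wmass" %in% stages) {
    groups <- c("all", "carbohydrate-like", "unsaturated-hydrocarbon-like",
                "tannin-like", "lignin-like")
    res$weighted_mass <- do.call(rbind, lapply(groups, function(g)
      weighted_mass(res$dataset, group = g, subset = "non-universal",
                    pool = pool)))
    emit("wmass", res$weighted_mass, "weighted_mass.tsv")
  }
  if ("similarity" %in% stages) {
    res$similarity <- similarity_to_reference(
      res$dataset, pool$formulas, depth = similarity_depth,
      iterations = similarity_iterations, seed = config$seed)
    emit("similarity", res$similarity, "similarity.tsv")
  }
  if ("trends" %in% stages) {
    uf <- res$universal %||% merge(universal_fractions(res$dataset, pool),
                                   res$dataset$samples, by = "sample_id")
    soil <- uf[uf$sample_type == "soil", ]
    soil$share <- soil$intensity_pct / 100
    res$trend_depth <- fit_trend(soil, "share", family = "gaussian-logit",
                                 focal = "depth")
    res$trend_position <- fit_trend(soil, "share", family = "gaussian-logit",
                                    focal = "position")
    emit("trends", res$trend_depth$emmeans, "trend_depth_emmeans.tsv")
    emit("trends", res$trend_position$emmeans, "trend_position_emmeans.tsv")
  }

  res$manifest <- do.call(rbind, manifest)
  res$manifest$elapsed_s <- round(as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs")), 2)
  if (!is.null(out_dir)) {
    utils::write.table(res$manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
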
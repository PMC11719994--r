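# End-to-end orchestration: featurize -> train-qsar -> filter-ad ->
# predict-nc -> potency -> profile -> bbb -> sources, with a provenance
# manifest (config hash, seed, per-stage row counts, output hashes).

#' Build a pipeline configuration
#'
#' All tunables of the screening pipeline in one validated list.
#' `activities` and `candidates` may be file paths (CSV, see
#' [read_compound_table()]) or in-memory data frames.
#'
#' @param activities Activity table or CSV path (`id`, `smiles`,
#'   `target`, `ic50_nm`).
#' @param candidates Candidate table or CSV path (`id`, `smiles`,
#'   optionally `sources`).
#' @param out_dir Output directory for stage CSVs and the manifest.
#' @param n_bits,radius Fingerprint parameters. Defaults 2048 / 2.
#' @param train_fraction Train split fraction. Default 0.8.
#' @param k_folds CV folds. Default 5.
#' @param num_trees Forest size. Default 500.
#' @param pic50_min Applicability activity floor. Default 5.
#' @param residual_q Residual-percentile level. Default 0.95.
#' @param similarity_threshold Cosine hit threshold. Default 0.5.
#' @param k_range Candidate cluster counts. Default 2:10.
#' @param min_count Source bar-chart cutoff. Default 10.
#' @param mcs_timeout_s Per-pair MCS deadline. Default 10.
#' @param seed Integer seed for every random stage.
#' @return Object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(activities, candidates, out_dir = tempfile("ncscreen_run_"),
                            n_bits = 2048L, radius = 2L, train_fraction = 0.8,
                            k_folds = 5L, num_trees = 500L, pic50_min = 5,
                            residual_q = 0.95, similarity_threshold = 0.5,
                            k_range = 2:10, min_count = 10L, mcs_timeout_s = 10,
                            seed = 1L) {
  check_number(n_bits, "n_bits", lower = 64)
  check_number(radius, "radius", lower = 0)
  check_number(train_fraction, "train_fraction", lower = 1e-12, upper = 1 - 1e-12)
  check_number(k_folds, "k_folds", lower = 2)
  check_number(num_trees, "num_trees", lower = 1)
  check_number(residual_q, "residual_q", lower = 1e-12, upper = 1 - 1e-12)
  check_number(similarity_threshold, "similarity_threshold", lower = 0, upper = 1)
  check_number(seed, "seed")
  if (any(k_range < 2L)) stop_config("`k_range` values must be >= 2.")
  structure(
    list(
      activities = activities, candidates = candidates, out_dir = out_dir,
      n_bits = as.integer(n_bits), radius = as.integer(radius),
      train_fraction = train_fraction, k_folds = as.integer(k_folds),
      num_trees = as.integer(num_trees), pic50_min = pic50_min,
      residual_q = residual_q, similarity_threshold = similarity_threshold,
      k_range = as.integer(k_range), min_count = as.integer(min_count),
      mcs_timeout_s = mcs_timeout_s, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' The round trip `read_pipeline_config(write_pipeline_config(cfg, f))`
#' reproduces the configuration (table inputs must be file paths for a
#' faithful round trip).
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return The configuration (read) or `path` invisibly (write).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (is.data.frame(x$activities)) x$activities <- "<in-memory>"
  if (is.data.frame(x$candidates)) x$candidates <- "<in-memory>"
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "ncscreen_stage_error", stage = stage, parent = e
    )
  })
}

load_table <- function(x, kind) {
  if (is.character(x)) read_compound_table(x, kind = kind) else {
    out <- parse_compounds(x)
    if (kind == "activities") {
      check_columns(out, c("target", "ic50_nm"), "activity table")
      if (!"pic50" %in% names(out)) out$pic50 <- ic50_to_pic50(out$ic50_nm)
    }
    out
  }
}

#' Run the full screening pipeline
#'
#' Executes all stages in order and writes per-stage outputs plus a
#' provenance manifest to `config$out_dir`:
#' `activities_filtered.csv`, per-target `model_metrics.csv`, `hits.csv`,
#' `potency.csv`, `clusters.csv`, `cluster_selection.csv`,
#' `sar_summary.csv`, `mcs_per_class.json`, `groups.csv`, `bbb.csv`,
#' `top_sources.csv`, `venn_regions.json`, and `manifest.json`. Any stage
#' failure halts the run with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  activities <- run_stage("featurize", load_table(config$activities, "activities"))
  counts$featurize <- c(activities = nrow(activities))

  targets <- sort(unique(activities$target))
  models <- run_stage("train-qsar", {
    setNames(lapply(seq_along(targets), function(i) {
      acts <- activities[activities$target == targets[i], , drop = FALSE]
      parts <- split_dataset(acts, config$train_fraction, seed = config$seed + i)
      m <- train_qsar(parts$train,
        n_bits = config$n_bits, radius = config$radius,
        num_trees = config$num_trees, k_folds = config$k_folds,
        seed = config$seed + i
      )
      evaluate_model(m, parts$test)
    }), targets)
  })
  counts$`train-qsar` <- c(models = length(models))

  filtered <- run_stage("filter-ad", {
    out <- purrr::map_dfr(targets, function(tg) {
      acts <- activities[activities$target == tg, , drop = FALSE]
      filter_applicability(acts, models[[tg]],
        q = config$residual_q, pic50_min = config$pic50_min
      )
    })
    out
  })
  counts$`filter-ad` <- c(
    input = nrow(activities), retained = nrow(filtered)
  )

  candidates <- run_stage("predict-nc", load_table(config$candidates, "candidates"))
  hits <- run_stage("predict-nc", {
    predict_candidates(candidates, filtered,
      threshold = config$similarity_threshold,
      n_bits = config$n_bits, radius = config$radius
    )
  })
  hit_ids <- unique(hits$id[hits$is_hit])
  counts$`predict-nc` <- c(
    candidates = nrow(candidates), pairs = nrow(hits), hit_compounds = length(hit_ids)
  )

  hit_candidates <- candidates[as.character(candidates$id) %in% hit_ids, , drop = FALSE]
  potency <- run_stage("potency", {
    if (nrow(hit_candidates) == 0L) stop_domain("No candidate passed the similarity screen.")
    preds <- purrr::map_dfr(targets, function(tg) {
      mutate(predict_potency(models[[tg]], hit_candidates), target = tg)
    })
    # per-candidate potency = best predicted interaction across targets
    preds |>
      group_by(.data$id) |>
      slice_max(.data$predicted_pic50, n = 1L, with_ties = FALSE) |>
      ungroup()
  })
  counts$potency <- c(input = nrow(hit_candidates), scored = nrow(potency))

  profile <- run_stage("profile", {
    prof <- compute_descriptors(hit_candidates)
    prof <- inner_join(prof,
      select(potency, "id", "predicted_pic50", best_target = "target"),
      by = "id"
    )
    feats <- scale(as.matrix(prof[, c(descriptor_cols, "predicted_pic50")]))
    feats <- feats[, apply(feats, 2, function(x) all(is.finite(x))), drop = FALSE]
    rownames(feats) <- prof$id
    k_range <- config$k_range[config$k_range <= nrow(feats) - 1L]
    if (length(k_range) == 0L) stop_domain("Too few hits to cluster over `k_range`.")
    sel <- choose_k(feats, k_range = k_range, seed = config$seed)
    assignments <- cluster_kmeans(feats, sel$chosen_k, seed = config$seed)
    fp <- compute_fingerprints(prof, n_bits = config$n_bits, radius = config$radius)
    sar <- sar_summary(assignments, prof, fingerprints = fp)
    prof$activity_class <- classify_activity(prof$predicted_pic50)
    mcs_per_class <- lapply(split(prof, prof$activity_class), function(sub) {
      if (nrow(sub) < 2L) return(NULL)
      find_mcs(sub, timeout_s = config$mcs_timeout_s)
    })
    groups <- detect_functional_groups(prof)
    list(profile = prof, selection = sel, assignments = assignments,
         sar = sar, mcs_per_class = mcs_per_class, groups = groups)
  })
  counts$profile <- c(input = nrow(potency), clustered = nrow(profile$assignments))

  bbb <- run_stage("bbb", bbb_score(profile$profile))
  counts$bbb <- c(input = nrow(profile$profile), scored = nrow(bbb))

  sources_out <- run_stage("sources", {
    if (!"sources" %in% names(hit_candidates) ||
        all(lengths(hit_candidates$sources) == 0L)) {
      NULL
    } else {
      m <- source_map(hit_candidates)
      top <- top_sources(m, n = Inf, min_count = config$min_count)
      venn <- if (nrow(top) >= 2L) {
        venn_intersections(m, head(top$source, 6L))
      } else {
        NULL
      }
      list(map = m, top = top, venn = venn)
    }
  })
  counts$sources <- c(
    sources = if (is.null(sources_out)) 0L else length(sources_out$map$by_source)
  )

  # ---- write outputs ----
  p <- function(f) file.path(config$out_dir, f)
  write_compound_table(filtered, p("activities_filtered.csv"))
  readr::write_csv(
    purrr::map_dfr(targets, function(tg) {
      m <- models[[tg]]
      bind_rows(
        mutate(m$train_metrics, set = "train"),
        mutate(m$test_metrics, set = "test")
      ) |> mutate(target = tg, .before = 1)
    }),
    p("model_metrics.csv"), progress = FALSE
  )
  readr::write_csv(hits, p("hits.csv"), progress = FALSE)
  write_compound_table(potency, p("potency.csv"))
  readr::write_csv(profile$assignments, p("clusters.csv"), progress = FALSE)
  readr::write_csv(profile$selection$table, p("cluster_selection.csv"), progress = FALSE)
  readr::write_csv(profile$sar$summary, p("sar_summary.csv"), progress = FALSE)
  jsonlite::write_json(
    lapply(profile$mcs_per_class, function(m) {
      if (is.null(m)) NULL else m[c("smarts", "n_atoms", "n_bonds", "exact", "found")]
    }),
    p("mcs_per_class.json"), auto_unbox = TRUE, null = "null"
  )
  readr::write_csv(profile$groups, p("groups.csv"), progress = FALSE)
  write_compound_table(
    select(bbb, -any_of(c("sources"))) |>
      select("id", all_of(descriptor_cols), ends_with("_ok"),
             "score_fraction", "score_percent"),
    p("bbb.csv")
  )
  if (!is.null(sources_out)) {
    readr::write_csv(sources_out$top, p("top_sources.csv"), progress = FALSE)
    if (!is.null(sources_out$venn)) {
      jsonlite::write_json(
        setNames(as.list(sources_out$venn$count), sources_out$venn$bitmask),
        p("venn_regions.json"), auto_unbox = TRUE
      )
    }
  }

  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL
  out_files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    config_hash = rlang::hash(cfg_for_hash),
    seed = config$seed,
    stage_counts = counts,
    outputs = out_files,
    output_hash = rlang::hash(lapply(file.path(config$out_dir, out_files), readLines))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    activities = activities, candidates = candidates, models = models,
    filtered = filtered, hits = hits, potency = potency, profile = profile,
    bbb = bbb, sources = sources_out, manifest = manifest
  ))
}
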
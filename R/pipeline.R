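#' Run the habitat-imaging analysis end-to-end
#'
#' Orchestrates the full pipeline on a synthetic cohort: simulate ->
#' preprocess (resample + window) -> habitat clustering (with optional CH
#' cluster-number selection) -> peritumoral rings -> feature extraction ->
#' selection cascade per branch -> signature models -> evaluation. Every
#' stage is a pure function of the configs and seeds, so a rerun with the
#' same configuration reproduces the exact result; `out_dir` (optional)
#' receives CSV tables and a JSON manifest.
#'
#' @param cohort_cfg A [cohort_config()].
#' @param phantom_cfg A [phantom_config()].
#' @param extraction_cfg An [extraction_config()].
#' @param selection_cfg A [selection_config()].
#' @param target_spacing_mm Resampling target; `NULL` keeps the phantom
#'   grid (useful when the phantom is already isotropic).
#' @param ring_radii_mm Peritumoral radii in mm; default `c(1, 3, 5)` (each
#'   must be at least one voxel at the working spacing).
#' @param k_habitats Fixed habitat count, or `NULL` to select it with
#'   [select_k_by_ch()] over `k_range`.
#' @param k_range Candidate cluster counts when selecting k.
#' @param model_kinds Classifier kinds to grid-search per branch; the best
#'   by validation AUC is kept. Default `"logistic"`.
#' @param icc Run the two-reader ICC stage on the tumor and ring branches
#'   (doubles extraction cost); the habitat branch never uses ICC.
#' @param seed Pipeline seed (clustering, folds, SMOTE).
#' @param out_dir Optional output directory.
#' @return A `habitat_run`: list with the cohort, habitat maps, selection,
#'   feature tables, signatures, branch scores, evaluation tibble, and the
#'   combined model.
#' @export
run_pipeline <- function(cohort_cfg,
                         phantom_cfg = phantom_config(),
                         extraction_cfg = extraction_config(),
                         selection_cfg = selection_config(),
                         target_spacing_mm = NULL,
                         ring_radii_mm = c(1, 3, 5),
                         k_habitats = 3,
                         k_range = 3:10,
                         model_kinds = "logistic",
                         icc = FALSE,
                         seed = 1,
                         out_dir = NULL) {
  cohort <- generate_cohort(cohort_cfg, phantom_cfg)
  if (length(cohort$patients) == 0) stop("empty cohort")

  # -- preprocess ------------------------------------------------------------
  for (id in names(cohort$patients)) {
    p <- cohort$patients[[id]]
    if (!is.null(target_spacing_mm)) {
      p$phases <- lapply(p$phases, resample_fixed, target_spacing_mm)
      p$tumor_mask_reader1 <- resample_fixed(p$tumor_mask_reader1, target_spacing_mm)
      p$tumor_mask_reader2 <- resample_fixed(p$tumor_mask_reader2, target_spacing_mm)
    }
    cohort$patients[[id]] <- p
  }

  # -- habitat maps (per patient, per phase) ---------------------------------
  fmaps <- lapply(cohort$patients, function(p) {
    lapply(p$phases, function(v) {
      local_feature_map(window_hu(v), p$tumor_mask_reader1)
    })
  })
  selection <- NULL
  if (is.null(k_habitats)) {
    selection <- select_k_by_ch(unlist(fmaps, recursive = FALSE),
                                k_range = k_range, seed = seed)
    k_habitats <- selection$k_star
  }
  habitats <- lapply(fmaps, function(maps_p) {
    lapply(maps_p, function(m) {
      knn_fill(cluster_habitats(m, k_habitats, seed = seed))
    })
  })

  # -- rings -----------------------------------------------------------------
  rings <- lapply(cohort$patients, function(p) {
    out <- lapply(ring_radii_mm, function(r) dilate_ring(p$tumor_mask_reader1, r))
    stats::setNames(out, paste0("ring", ring_radii_mm))
  })

  # -- extraction ------------------------------------------------------------
  tabs <- build_feature_tables(cohort$patients, habitats = habitats,
                               rings = rings, config = extraction_cfg)
  tabs_b <- NULL
  if (icc) {
    rings_b <- lapply(cohort$patients, function(p) {
      out <- lapply(ring_radii_mm, function(r) dilate_ring(p$tumor_mask_reader2, r))
      stats::setNames(out, paste0("ring", ring_radii_mm))
    })
    tabs_b <- build_feature_tables(cohort$patients, rings = rings_b,
                                   config = extraction_cfg,
                                   tables = c("radiomics", "peri"),
                                   mask_field = "tumor_mask_reader2")
  }

  # -- splits ----------------------------------------------------------------
  tab <- cohort$table
  tr <- tab$split == "train"
  va <- tab$split == "validation"
  if (!any(va)) va <- !tr

  branches <- c(radiomics = list(tabs$radiomics),
                stats::setNames(tabs$peri, paste0("peri", ring_radii_mm)),
                ith = list(tabs$ith))
  branch_b <- function(nm) {
    if (is.null(tabs_b) || nm == "ith") return(NULL)
    if (nm == "radiomics") return(tabs_b$radiomics)
    tabs_b$peri[[sub("^peri", "ring", nm)]]
  }

  signatures <- list(); scores <- list(); models <- list()
  for (nm in names(branches)) {
    ft <- branches[[nm]]
    ft_b <- branch_b(nm)
    sig <- run_selection_cascade(
      ft[tr, ], tab$grade[tr],
      table_b = if (is.null(ft_b)) NULL else ft_b[tr, ],
      config = selection_cfg)
    signatures[[nm]] <- sig
    rs <- predict(sig, ft)

    # model the rad-score-selected features; fall back to the rad-score
    # itself if the LASSO kept nothing
    feats <- if (length(sig$selected_features) > 0) {
      dplyr::select(ft, dplyr::all_of(sig$selected_features))
    } else {
      tibble::tibble(rad_score = rs)
    }
    best <- NULL; best_auc <- -Inf
    for (kind in model_kinds) {
      m <- train_signature(feats[tr, ], tab$grade[tr],
                           model_spec(kind, seed = seed), branch = nm)
      pv <- predict(m, feats[va, ])
      a <- auc_rank(pv, tab$grade[va])
      if (!is.na(a) && a > best_auc) { best_auc <- a; best <- m }
    }
    models[[nm]] <- best
    scores[[nm]] <- predict(best, feats)
  }

  # -- clinical + combined ---------------------------------------------------
  clin_cols <- setdiff(names(tab), c("patient_id", "split", "grade"))
  screen <- clinical_screen(tab[tr, clin_cols], tab$grade[tr])
  best_peri <- {
    peri_names <- grep("^peri", names(models), value = TRUE)
    aucs <- vapply(peri_names,
                   function(nm) auc_rank(scores[[nm]][va], tab$grade[va]), 0)
    peri_names[which.max(aucs)]
  }
  comb_df <- dplyr::bind_cols(
    tibble::tibble(ith_score = scores[["ith"]],
                   peri_score = scores[[best_peri]]),
    tab[union(character(), screen$selected)])
  comb <- combined_model(comb_df[tr, ], tab$grade[tr])
  scores$combined <- predict(comb, comb_df)

  # -- evaluation ------------------------------------------------------------
  reports <- list()
  for (nm in names(scores)) {
    thr <- youden_threshold(scores[[nm]][tr], tab$grade[tr])
    for (sp in unique(tab$split)) {
      rows <- tab$split == sp
      if (length(unique(tab$grade[rows])) < 2) next
      reports[[paste(nm, sp, sep = "_")]] <-
        evaluate_scores(scores[[nm]][rows], tab$grade[rows], thr,
                        branch = nm, split = sp)
    }
  }
  evaluation <- purrr::map_dfr(reports, function(r) r$summary)

  run <- structure(
    list(cohort = cohort, habitats = habitats, rings = rings,
         cluster_selection = selection, k_habitats = k_habitats,
         feature_tables = tabs, signatures = signatures, models = models,
         scores = scores, clinical = screen, best_peri = best_peri,
         combined = comb, reports = reports, evaluation = evaluation,
         seed = seed),
    class = "habitat_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.habitat_run <- function(x, ...) {
  cat(sprintf("<habitat_run> %d patients, k = %d habitats\n",
              nrow(x$cohort$table), x$k_habitats))
  print(x$evaluation[, c("branch", "split", "auc", "accuracy",
                         "sensitivity", "specificity")])
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$cohort$table, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(run$evaluation, file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  for (nm in names(run$signatures)) {
    jsonlite::write_json(
      list(branch = nm,
           selected_features = run$signatures[[nm]]$selected_features,
           coefficients = as.list(run$signatures[[nm]]$coefficients)),
      file.path(out_dir, paste0("signature_", nm, ".json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- lapply(files, function(f) {
    list(file = basename(f), bytes = file.info(f)$size,
         md5 = as.character(tools::md5sum(f)))
  })
  jsonlite::write_json(list(seed = run$seed, k_habitats = run$k_habitats,
                            files = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
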
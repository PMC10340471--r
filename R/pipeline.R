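#' Combine spectrum sets by stacking samples
#'
#' @param ... `spectrum_set`s on the same grid with the same label columns.
#' @return A single `spectrum_set`.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, logical(1),
                                          "spectrum_set")))
  for (s in sets[-1]) stop_grid_mismatch(sets[[1]], s)
  vals <- do.call(rbind, lapply(sets, function(s) s$values))
  ids <- unlist(lapply(sets, function(s) s$sample_id))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  labels <- if (all(vapply(sets, function(s) !is.null(s$labels), logical(1)))) {
    do.call(rbind, lapply(sets, function(s) s$labels))
  }
  spectrum_set(vals, sets[[1]]$grid, sample_id = ids, labels = labels)
}

#' Average replicate scans by sample identifier
#'
#' Collapses repeated acquisitions of the same sample (shared
#' `sample_id`) to their mean spectrum, emulating the averaging of
#' replicate radiation-flux readings before analysis. Labels are taken
#' from the first replicate of each sample.
#'
#' @param set A `spectrum_set` possibly holding replicate rows.
#' @return A `spectrum_set` with one spectrum per distinct `sample_id`,
#'   in first-appearance order.
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  ids <- unique(set$sample_id)
  vals <- t(vapply(ids, function(id) {
    colMeans(set$values[set$sample_id == id, , drop = FALSE])
  }, numeric(length(set$grid))))
  labels <- if (!is.null(set$labels)) {
    set$labels[match(ids, set$sample_id), , drop = FALSE]
  }
  spectrum_set(vals, set$grid, sample_id = ids, labels = labels)
}

model_metrics <- function(y_tr, p_tr, y_te, p_te) {
  data.frame(rc2 = r2_score(y_tr, p_tr), rmsec = rmse(y_tr, p_tr),
             rp2 = r2_score(y_te, p_te), rmsep = rmse(y_te, p_te))
}

#' Run the moisture-prediction model comparison
#'
#' End-to-end moisture workflow: scatter-correct the spectra (MSC with the
#' training-set mean as frozen reference), split 4:1, select wavelengths
#' by SPA and components by PCA on the training data, then fit and score
#' the full model panel: Full-PLSR, Full-BP, SPA-BP, PCA-BP with 5/4/3
#' components, SPA-PLSR, PCA-PLSR, and SPA-SSA-BP. Each model row reports
#' RC2/RMSEC on the training set and Rp2/RMSEP on the held-out test set,
#' with RMSE in moisture percentage points.
#'
#' @param set A `spectrum_set` whose labels include `moisture_pct`, or
#'   `NULL` to generate synthetic spectra from `generator`.
#' @param seed Integer seed controlling the split, hidden-size scan and
#'   sparrow search.
#' @param generator [generator_config()] used when `set` is `NULL`. The
#'   default emulates a fresh, uniformly white (grade-1) moisture cohort,
#'   so browning does not confound the moisture signal, and shares `seed`.
#' @param preprocess_method One of `"msc"`, `"snv"`, `"sg"`,
#'   `"normalization"`, or `"none"`.
#' @param spa_max_size Largest SPA subset scanned (default 10).
#' @param hidden Hidden-size scan range for the BP models.
#' @param ssa [ssa_config()] for the SPA-SSA-BP row.
#' @param models Character subset of the panel to run (default all).
#' @param out_dir Optional directory; when given, the comparison table
#'   (CSV) and a reproducibility manifest (JSON, if jsonlite is installed)
#'   are written there.
#' @return List with `table` (the comparison data frame), `spa`, `pca`,
#'   `models` (fitted model objects), `split`, and `manifest`.
#' @export
run_moisture <- function(set = NULL, seed = 1L,
                         generator = generator_config(grade_mix = c(1, 0, 0, 0),
                                                      seed = seed),
                         preprocess_method = "msc",
                         spa_max_size = 10, hidden = 5:10,
                         ssa = ssa_config(seed = seed),
                         models = c("Full-PLSR", "Full-BP", "SPA-BP",
                                    "PCA-BP (5 components)",
                                    "PCA-BP (4 components)",
                                    "PCA-BP (3 components)",
                                    "SPA-PLSR", "PCA-PLSR", "SPA-SSA-BP"),
                         out_dir = NULL) {
  if (is.null(set)) set <- generate_spectra(generator)$set
  if (is.null(set$labels) || is.null(set$labels$moisture_pct)) {
    stop("moisture workflow requires 'moisture_pct' labels")
  }
  y_all <- set$labels$moisture_pct

  sp <- split_train_test(set, seed = seed)
  tr_idx <- setdiff(seq_len(length(set)), sp$test_idx)

  if (preprocess_method == "none") {
    Xtr <- sp$train$values
    Xte <- sp$test$values
  } else if (preprocess_method == "msc") {
    ref <- colMeans(sp$train$values)
    Xtr <- msc(sp$train, reference = ref)$values
    Xte <- msc(sp$test, reference = ref)$values
  } else {
    Xtr <- preprocess(sp$train, preprocess_method)$values
    Xte <- preprocess(sp$test, preprocess_method)$values
  }
  y_tr <- y_all[tr_idx]
  y_te <- y_all[sp$test_idx]
  wl <- as.numeric(set$grid)

  spa <- spa_select(Xtr, y_tr, max_size = spa_max_size, wavelengths = wl)
  pca <- pca_select(pca_fit(Xtr), 0.95)

  fitted <- list()
  rows <- list()
  add_row <- function(name, p_tr, p_te, model) {
    rows[[name]] <<- cbind(data.frame(model = name), model_metrics(y_tr, p_tr, y_te, p_te))
    fitted[[name]] <<- model
  }
  bp_cfg <- bp_config(seed = seed)

  run_plsr <- function(Xa, Xb) {
    k <- plsr_select_k(Xa, y_tr, k_max = min(15, ncol(Xa)))$k
    m <- plsr_fit(Xa, y_tr, k)
    list(m = m, p_tr = plsr_predict(m, Xa), p_te = plsr_predict(m, Xb))
  }
  run_bp <- function(Xa, Xb) {
    m <- bp_scan_hidden(Xa, y_tr, hidden = hidden, config = bp_cfg, seed = seed)
    list(m = m, p_tr = bp_predict(m, Xa), p_te = bp_predict(m, Xb))
  }

  Xtr_spa <- Xtr[, spa$selected_indices, drop = FALSE]
  Xte_spa <- Xte[, spa$selected_indices, drop = FALSE]
  pca_scores <- function(k, X) pca_transform(pca, X, n_components = k)

  for (name in models) {
    if (name == "Full-PLSR") {
      r <- run_plsr(Xtr, Xte)
    } else if (name == "Full-BP") {
      r <- run_bp(Xtr, Xte)
    } else if (name == "SPA-BP") {
      r <- run_bp(Xtr_spa, Xte_spa)
    } else if (grepl("^PCA-BP", name)) {
      k <- as.integer(sub("PCA-BP \\((\\d+) components?\\)", "\\1", name))
      r <- run_bp(pca_scores(k, Xtr), pca_scores(k, Xte))
    } else if (name == "SPA-PLSR") {
      r <- run_plsr(Xtr_spa, Xte_spa)
    } else if (name == "PCA-PLSR") {
      k <- pca$n_selected
      r <- run_plsr(pca_scores(k, Xtr), pca_scores(k, Xte))
    } else if (name == "SPA-SSA-BP") {
      h_best <- if (!is.null(fitted[["SPA-BP"]])) fitted[["SPA-BP"]]$n_hidden else bp_cfg$n_hidden
      cfg <- bp_cfg
      cfg$n_hidden <- h_best
      m <- ssa_bp_train(Xtr_spa, y_tr, cfg, ssa)
      r <- list(m = m, p_tr = bp_predict(m, Xtr_spa),
                p_te = bp_predict(m, Xte_spa))
    } else {
      stop(sprintf("unknown model '%s'", name))
    }
    add_row(name, r$p_tr, r$p_te, r$m)
  }

  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  manifest <- list(task = "moisture", seed = seed,
                   n_samples = length(set), n_train = length(y_tr),
                   n_test = length(y_te),
                   preprocess = preprocess_method,
                   spa_bands = spa$selected_wavelengths,
                   pca_components = pca$n_selected,
                   generator = unclass(generator),
                   package_version = as.character(utils::packageVersion("mushspec")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table, file.path(out_dir, "moisture_models.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(table = table, spa = spa, pca = pca, models = fitted,
       split = sp, manifest = manifest)
}

#' Run the whiteness workflow
#'
#' Computes per-sample colorimetric whiteness (tristimulus, chromaticity,
#' Ganz W10, grade) for a batch of spectra, summarizes whiteness by true
#' grade (min, median, max per level), tests for differences across
#' grades with a Kruskal-Wallis rank test, and optionally fits a BP
#' regression predicting whiteness from SPA-selected bands.
#'
#' @param set A `spectrum_set` (labels `grade` enable the per-grade
#'   statistics; `whiteness` enables the regression), or `NULL` to
#'   generate four synthetic batches of `n_per_grade` mushrooms per grade.
#' @param seed Integer seed.
#' @param n_per_grade Samples per grade for the synthetic default
#'   (default 40, i.e. 160 in total).
#' @param regression Fit the whiteness BP regression (default `FALSE`).
#' @param spa_max_size SPA scan limit for the regression inputs
#'   (default 32).
#' @param hidden Hidden-size scan range for the regression.
#' @param out_dir Optional output directory (per-sample CSV + manifest).
#' @return List with `results` (per-sample data frame), `grade_stats`,
#'   `kruskal` (an `htest` or `NULL` with a notice when fewer than two
#'   grades are present), optional `regression` metrics, and `manifest`.
#' @export
run_whiteness <- function(set = NULL, seed = 1L, n_per_grade = 40,
                          regression = FALSE, spa_max_size = 32,
                          hidden = 5:10, out_dir = NULL) {
  if (is.null(set)) {
    batches <- lapply(1:4, function(g) {
      mix <- numeric(4)
      mix[g] <- 1
      generate_spectra(generator_config(n_samples = n_per_grade,
                                        grade_mix = mix,
                                        seed = seed * 10L + g))$set
    })
    set <- do.call(bind_spectra, batches)
  }
  results <- whiteness_pipeline(set)

  grade_stats <- NULL
  kw <- NULL
  notice <- NULL
  if (!is.null(set$labels) && !is.null(set$labels$grade)) {
    g <- set$labels$grade
    grade_stats <- do.call(rbind, lapply(sort(unique(g)), function(lev) {
      w <- results$W10[g == lev]
      data.frame(grade = lev, n = length(w), min = min(w),
                 median = stats::median(w), max = max(w))
    }))
    if (length(unique(g)) >= 2) {
      kw <- stats::kruskal.test(results$W10, factor(g))
    } else {
      notice <- "only one grade present; across-grade test skipped"
      message(notice)
    }
  }

  reg <- NULL
  if (regression) {
    if (is.null(set$labels) || is.null(set$labels$whiteness)) {
      stop("whiteness regression requires 'whiteness' labels")
    }
    y_all <- set$labels$whiteness
    sp <- split_train_test(set, seed = seed)
    tr_idx <- setdiff(seq_len(length(set)), sp$test_idx)
    spa <- spa_select(sp$train$values, y_all[tr_idx],
                      max_size = min(spa_max_size, ncol(sp$train$values)),
                      wavelengths = as.numeric(set$grid))
    Xtr <- sp$train$values[, spa$selected_indices, drop = FALSE]
    Xte <- sp$test$values[, spa$selected_indices, drop = FALSE]
    m <- bp_scan_hidden(Xtr, y_all[tr_idx], hidden = hidden,
                        config = bp_config(seed = seed), seed = seed)
    reg <- list(spa = spa, model = m,
                metrics = model_metrics(y_all[tr_idx], bp_predict(m, Xtr),
                                        y_all[sp$test_idx], bp_predict(m, Xte)))
  }

  manifest <- list(task = "whiteness", seed = seed, n_samples = length(set),
                   regression = regression,
                   package_version = as.character(utils::packageVersion("mushspec")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "whiteness_results.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(results = results, grade_stats = grade_stats, kruskal = kw,
       notice = notice, regression = reg, manifest = manifest)
}
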
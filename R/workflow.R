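#' Experiment configuration for the end-to-end study
#'
#' @param simulation a [sim_config()] describing the synthetic dataset.
#' @param greml_models subset of `c("A","AD","AE","ADE")` to fit.
#' @param networks named list of [network_config()]s to train (names label
#'   the report rows); NULL skips the deep models.
#' @param split_mode,n_folds,n_repeats,val_fraction,n_splits passed to
#'   [make_splits()].
#' @param augment_with_vae logical; additionally train every network on the
#'   VAE-augmented training sets.
#' @param vae a [vae_config()] used when `augment_with_vae` is TRUE.
#' @param outdir output directory for report CSVs and the manifest (NULL
#'   keeps everything in memory).
#' @param seed master seed recorded in the manifest; stage seeds derive
#'   from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(simulation = sim_config(),
                              greml_models = c("A", "AD", "AE", "ADE"),
                              networks = list(
                                MLP = network_config("mlp", preset = "sire"),
                                CNN = network_config("cnn", preset = "sire")),
                              split_mode = "kfold_repeated",
                              n_folds = 10L, n_repeats = 5L,
                              val_fraction = 0.2, n_splits = 50L,
                              augment_with_vae = FALSE,
                              vae = vae_config(),
                              outdir = NULL, seed = 1L) {
  greml_models <- match.arg(greml_models, c("A", "AD", "AE", "ADE"),
                            several.ok = TRUE)
  structure(list(simulation = simulation, greml_models = greml_models,
                 networks = networks, split_mode = split_mode,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 val_fraction = val_fraction, n_splits = as.integer(n_splits),
                 augment_with_vae = augment_with_vae, vae = vae,
                 outdir = outdir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Dataset summary table
#'
#' Counts of individuals, markers before/after QC, pens and litters, and
#' mean +/- SD of the raw and pre-corrected trait.
#'
#' @param genotypes a [geno_matrix()] (pre-QC).
#' @param phenotypes phenotype/factor data.frame with column `y`.
#' @param qc_report optional `qc_report` for the marker counts after QC.
#' @param precorrected optional vector of pre-corrected phenotypes.
#' @return a two-column data.frame (quantity, value).
#' @export
summarize_dataset <- function(genotypes, phenotypes, qc_report = NULL,
                              precorrected = NULL) {
  rows <- list(
    c("Number of individuals", nrow(genotypes$X)),
    c("Total number of SNPs",
      if (is.null(qc_report)) ncol(genotypes$X) else qc_report$n_markers_in),
    c("Number of SNPs after QC",
      if (is.null(qc_report)) NA else qc_report$n_markers_out),
    c("Number of pens", length(unique(phenotypes$pen))),
    c("Number of litters", length(unique(phenotypes$litter))),
    c("Mean trait", round(mean(phenotypes$y), 4)),
    c("SD trait", round(stats::sd(phenotypes$y), 4)))
  if (!is.null(precorrected)) {
    rows <- c(rows, list(
      c("Mean pre-corrected trait", signif(mean(precorrected), 4)),
      c("SD pre-corrected trait", round(stats::sd(precorrected), 4))))
  }
  data.frame(quantity = vapply(rows, `[`, "", 1),
             value = vapply(rows, `[`, "", 2))
}

matrices_for <- function(tag, G, D, E) {
  switch(tag, A = list(G), AD = list(G, D), AE = list(G, E),
         ADE = list(G, D, E))
}

#' Run the full simulated study
#'
#' Executes simulate, QC, pre-correction/normalization, relationship
#' matrices, multi-component REML (variance-ratio table), linear BLUP
#' prediction of the test animals, deep-model training over the split
#' scheme (splits-average and averaged-predictions metrics, optionally with
#' VAE-augmented training sets), and black-box linearization of every
#' trained network (nonadditive-variance table).  All tables are returned
#' and, when `config$outdir` is set, written as CSVs together with a JSON
#' manifest of seeds and settings.
#'
#' @param config an [experiment_config()].
#' @param dl_epochs,dl_lr optional overrides of each network's epoch budget
#'   and learning rate (handy for smoke-scale runs).
#' @param verbose print stage progress.
#' @return list of class `study_report`: `summary_table`, `variance_table`,
#'   `prediction_table`, `nonadditive_table`, plus `data` (genotypes,
#'   phenotypes, truth, splits) and `manifest`.
#' @export
run_study <- function(config, dl_epochs = NULL, dl_lr = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  scfg <- config$simulation

  say("stage simulate: n=%d m=%d", scfg$n_individuals, scfg$n_markers)
  geno <- simulate_genotypes(scfg)
  sim <- simulate_phenotypes(geno, scfg)
  phen <- sim$phenotypes

  say("stage qc")
  qc <- apply_qc(geno)
  genoq <- qc$genotypes

  say("stage precorrect")
  pc <- precorrect(phen)
  y <- znormalize(pc$residuals)

  say("stage grm")
  G <- build_G(genoq)
  D <- build_D(genoq, normalize = TRUE)
  E <- build_Eaa(G)

  say("stage greml")
  var_rows <- list()
  fits <- list()
  for (tag in config$greml_models) {
    fit <- fit_reml(y, matrices_for(tag, G, D, E), tag)
    fits[[tag]] <- fit
    rat <- ratios(fit)
    grab <- function(nm) {
      if (nm %in% names(fit$components))
        sprintf("%.3f (%.3f)", fit$components[nm], fit$se[nm]) else "-"
    }
    grabr <- function(nm) {
      if (nm %in% names(rat$ratios))
        sprintf("%.3f (%.3f)", rat$ratios[nm], rat$se[nm]) else "-"
    }
    var_rows[[tag]] <- data.frame(
      model = tag, sigma2_a = grab("a"), sigma2_d = grab("d"),
      sigma2_eaa = grab("eaa"), sigma2_eps = grab("eps"),
      h2 = grabr("h2"), d2 = grabr("d2"), e2_aa = grabr("e2_aa"),
      H2 = grabr("H2"))
  }
  variance_table <- do.call(rbind, var_rows)
  rownames(variance_table) <- NULL

  say("stage splits")
  splits <- make_splits(phen, test_years = scfg$test_years,
                        mode = config$split_mode, n_folds = config$n_folds,
                        n_repeats = config$n_repeats,
                        val_fraction = config$val_fraction,
                        n_splits = config$n_splits, seed = config$seed)
  ids <- phen$id
  pool_idx <- match(splits$pool_ids, ids)
  test_idx <- match(splits$test_ids, ids)
  y_test <- y[test_idx]
  Xq <- genoq$X

  pred_rows <- list()
  say("stage linear prediction")
  for (tag in config$greml_models) {
    mats <- matrices_for(tag, G, D, E)
    fit_tr <- fit_reml(y[pool_idx],
                       lapply(mats, function(K)
                         rel_matrix(K$values[pool_idx, pool_idx],
                                    kind = K$kind)),
                       tag)
    pr <- predict_genetic_values(fit_tr, mats, y[pool_idx], pool_idx,
                                 test_idx)
    r <- stats::cor(pr$ebv, y_test)
    pred_rows[[length(pred_rows) + 1L]] <- data.frame(
      method = "Linear", dataset = "Real", approach = "Pearson correlation",
      model = tag, r = round(r, 3), spread = round(se_of_r(r, length(test_idx)), 3),
      spread_type = "SE")
  }

  nonadd_rows <- list()
  dl_preds <- list()
  run_networks <- function(dataset_label, augmented) {
    for (nm in names(config$networks)) {
      ncfg <- config$networks[[nm]]
      say("stage dl: %s (%s), %d splits", nm, dataset_label,
          length(splits$splits))
      preds <- matrix(NA_real_, length(splits$splits), length(test_idx))
      lins <- list()
      for (si in seq_along(splits$splits)) {
        sp <- splits$splits[[si]]
        tr <- match(sp$train_ids, ids)
        va <- match(sp$val_ids, ids)
        Xtr <- Xq[tr, , drop = FALSE]; ytr <- y[tr]
        if (augmented) {
          bins <- bin_phenotypes(ytr, config$vae$n_bins)
          vcfg <- config$vae
          vcfg$seed <- config$seed + si
          vae <- train_vae(Xtr, vcfg)
          batch <- generate_synthetic(vae, Xtr, bins)
          aug <- augment(Xtr, ytr, batch)
          Xtr <- aug$X; ytr <- aug$y
        }
        ncfg_i <- ncfg
        ncfg_i$seed <- ncfg$seed + si
        mdl <- build_model(ncfg_i, ncol(Xq))
        mdl <- train_model(mdl, Xtr, ytr, Xq[va, , drop = FALSE], y[va],
                           epochs = dl_epochs, learning_rate = dl_lr)
        preds[si, ] <- predict(mdl, Xq[test_idx, , drop = FALSE])
        lins[[si]] <- linearize_model(mdl, Xq[test_idx, , drop = FALSE])
      }
      sa <- splits_average(preds, y_test)
      ap <- averaged_predictions(preds, y_test)
      pred_rows[[length(pred_rows) + 1L]] <<- data.frame(
        method = "DL", dataset = dataset_label,
        approach = "Averaged-predictions", model = nm, r = round(ap, 3),
        spread = round(se_of_r(ap, length(test_idx)), 3), spread_type = "SE")
      pred_rows[[length(pred_rows) + 1L]] <<- data.frame(
        method = "DL", dataset = dataset_label, approach = "Splits-average",
        model = nm, r = round(sa$mean_r, 3), spread = round(sa$sd_r, 3),
        spread_type = "SD")
      pooled <- pooled_summary(lins, y_test)
      nonadd_rows[[length(nonadd_rows) + 1L]] <<- data.frame(
        dataset = dataset_label, model = nm, n2 = round(pooled$n2, 3),
        sigma2_na_dl = round(pooled$sigma2_na_dl, 3),
        cor_avg_ebv = round(pooled$cor_avg_ebv, 3),
        cor_avg_egv = round(pooled$cor_avg_egv, 3))
      dl_preds[[paste(dataset_label, nm)]] <<- preds
    }
  }
  if (length(config$networks)) {
    run_networks("Real", augmented = FALSE)
    if (config$augment_with_vae) run_networks("Augmented", augmented = TRUE)
  }
  prediction_table <- do.call(rbind, pred_rows)
  nonadditive_table <- if (length(nonadd_rows)) do.call(rbind, nonadd_rows)

  summary_table <- summarize_dataset(geno, phen, qc$report, y)

  manifest <- list(seed = config$seed, sim_seed = scfg$seed,
                   n_individuals = scfg$n_individuals,
                   n_markers = scfg$n_markers,
                   split_mode = config$split_mode,
                   n_splits = length(splits$splits),
                   greml_models = config$greml_models,
                   networks = names(config$networks),
                   augment_with_vae = config$augment_with_vae,
                   elapsed_sec = round(proc.time()[3] - t0, 1),
                   package_version = as.character(
                     utils::packageVersion("gpdeep")))

  report <- structure(list(summary_table = summary_table,
                           variance_table = variance_table,
                           prediction_table = prediction_table,
                           nonadditive_table = nonadditive_table,
                           data = list(genotypes = genoq, phenotypes = phen,
                                       truth = sim$truth, y = y,
                                       splits = splits,
                                       dl_predictions = dl_preds),
                           fits = fits,
                           manifest = manifest),
                      class = "study_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' Write a study report's tables and manifest to a directory
#' @param report a `study_report`.
#' @param outdir directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    if (is.null(df)) return()
    f <- file.path(outdir, name)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, f)
  }
  wt(report$summary_table, "table_summary.csv")
  wt(report$variance_table, "table_variance_components.csv")
  wt(report$prediction_table, "table_predictive_ability.csv")
  wt(report$nonadditive_table, "table_nonadditive_variance.csv")
  mf <- file.path(outdir, "manifest.json")
  # elapsed time is environment noise; keep the manifest reproducible
  m <- report$manifest
  m$elapsed_sec <- NULL
  jsonlite::write_json(m, mf, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, mf)
  invisible(paths)
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Dataset summary ==\n"); print(x$summary_table)
  cat("\n== Variance components ==\n"); print(x$variance_table)
  cat("\n== Predictive ability ==\n"); print(x$prediction_table)
  if (!is.null(x$nonadditive_table)) {
    cat("\n== Nonadditive variance captured by DL ==\n")
    print(x$nonadditive_table)
  }
  invisible(x)
}
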